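#' Single-marker LMM association scan within one environment
#'
#' Fits the marker-free mixed model
#' `y ~ N([1 S] beta, sigma2_g G + sigma2_e I)` once by REML, then holds the
#' variance ratio fixed and tests each marker by generalized least squares
#' with fixed covariates `[1 | S] + marker` (the P3D strategy: population
#' parameters previously determined). The marker effect is assessed by a
#' two-sided Wald t test with `n_obs - q` degrees of freedom, where the
#' residual scale is re-estimated per marker, so in the identity-kinship,
#' no-covariate limit the scan reduces exactly to ordinary regression.
#' Markers with missing genotypes are tested on their non-missing subset
#' (rows dropped per marker, covariance re-whitened on the subset).
#'
#' @param y response vector, aligned to the variety order of `geno` (or
#'   named by variety).
#' @param geno a `geno_matrix`.
#' @param G kinship; default [compute_grm()] of `geno`.
#' @param S structure covariates; default [pca_covariates()] with `n_pc`
#'   components.
#' @param n_pc number of principal components when `S` is not supplied
#'   (default 5; 0 disables structure correction).
#' @param exact if `TRUE`, re-estimate the variance ratio per marker
#'   (slower; default `FALSE` = P3D).
#' @return data.frame with one row per marker: `marker`, `chrom`, `pos`,
#'   `effect`, `se`, `t`, `p_value`, `neg_log10_p`, `note` (`"ok"`,
#'   `"monomorphic"`, ...). Monomorphic markers yield NA statistics.
#' @export
run_env_gwas <- function(y, geno, G = NULL, S = NULL, n_pc = 5L,
                         exact = FALSE) {
  stopifnot(inherits(geno, "geno_matrix"))
  m <- nrow(geno$codes)
  if (!is.null(names(y))) y <- y[geno$varieties]
  if (length(y) != m)
    stop("run_env_gwas: y not aligned to varieties", call. = FALSE)
  if (is.null(G)) G <- compute_grm(geno)
  Gv <- if (inherits(G, "kinship_matrix")) G$values else G
  if (is.null(S)) S <- pca_covariates(geno, n_pc)
  X0 <- cbind(`(Intercept)` = 1, S)
  est <- fit_single_kernel(y, X0, Gv, method = "REML")
  U <- est$eigen$vectors; d <- est$eigen$values
  isw <- 1 / sqrt(d + est$delta)
  yt <- crossprod(U, y) * isw
  X0t <- crossprod(U, X0) * isw
  Xt_all <- crossprod(U, replace(geno$codes, is.na(geno$codes), 0)) * isw
  q <- ncol(X0) + 1L
  p <- ncol(geno$codes)
  eff <- se <- tv <- rep(NA_real_, p)
  note <- rep("ok", p)
  for (j in seq_len(p)) {
    x <- geno$codes[, j]
    obs <- !is.na(x)
    if (sum(obs) <= q || stats::var(x[obs]) == 0) {
      note[j] <- "monomorphic"
      next
    }
    if (all(obs) && !exact) {
      fit <- stats::lm.fit(cbind(X0t, x = Xt_all[, j]), yt)
    } else {
      Xs <- cbind(X0[obs, , drop = FALSE], x = x[obs])
      Gs <- Gv[obs, obs, drop = FALSE]
      if (exact) {
        es <- fit_single_kernel(y[obs], Xs, Gs, method = "REML")
        delta_j <- es$delta
        evs <- list(vectors = es$eigen$vectors, values = es$eigen$values)
      } else {
        delta_j <- est$delta
        evs <- eigen(Gs, symmetric = TRUE)
        evs$values <- pmax(evs$values, 0)
      }
      isw_s <- 1 / sqrt(evs$values + delta_j)
      fit <- stats::lm.fit(crossprod(evs$vectors, Xs) * isw_s,
                           crossprod(evs$vectors, y[obs]) * isw_s)
    }
    if (fit$rank < ncol(fit$qr$qr) || is.na(fit$coefficients["x"])) {
      note[j] <- "aliased"
      next
    }
    df <- length(fit$residuals) - fit$rank
    s2 <- sum(fit$residuals^2) / df
    R <- qr.R(fit$qr)
    XtXi <- chol2inv(R)
    k <- match("x", colnames(R))
    eff[j] <- fit$coefficients["x"]
    se[j] <- sqrt(s2 * XtXi[k, k])
    tv[j] <- eff[j] / se[j]
  }
  pv <- 2 * stats::pt(-abs(tv), df = pmax(m - q, 1))
  # df differs for markers tested on a subset; recompute those exactly
  for (j in which(!is.na(tv) & colSums(is.na(geno$codes)) > 0)) {
    df_j <- sum(!is.na(geno$codes[, j])) - q
    pv[j] <- 2 * stats::pt(-abs(tv[j]), df = max(df_j, 1))
  }
  data.frame(marker = geno$variants$id, chrom = geno$variants$chrom,
             pos = geno$variants$pos, effect = eff, se = se, t = tv,
             p_value = pv, neg_log10_p = -log10(pv), note = note,
             stringsAsFactors = FALSE)
}

#' Bonferroni genome-wide significance threshold
#'
#' @param p_markers number of tested markers.
#' @param alpha family-wise error rate (default 0.05).
#' @return the threshold on the -log10(P) scale, `-log10(alpha/p_markers)`.
#' @export
bonferroni_threshold <- function(p_markers, alpha = 0.05) {
  stopifnot(p_markers >= 1, alpha > 0, alpha <= 1)
  -log10(alpha / p_markers)
}

#' Quantile-quantile table and genomic inflation factor
#'
#' Pairs the sorted observed -log10(P) values with their uniform-expected
#' quantiles `(i - 0.5)/n` and reports the genomic inflation factor
#' `lambda_GC = median(chisq_obs) / qchisq(0.5, 1)` computed from the
#' P values.
#'
#' @param scan a scan result data.frame with a `p_value` column (NA rows
#'   are dropped), or a numeric vector of P values.
#' @return list with `table` (data.frame `expected`, `observed`, both
#'   -log10 scale, ascending) and `lambda_gc`.
#' @export
qq_table <- function(scan) {
  pv <- if (is.data.frame(scan)) scan$p_value else scan
  pv <- pv[!is.na(pv)]
  if (!length(pv)) stop("qq_table: no finite P values", call. = FALSE)
  pv <- sort(pv)
  n <- length(pv)
  expected <- -log10((seq_len(n) - 0.5) / n)
  observed <- -log10(pv)
  lambda <- stats::median(stats::qchisq(pv, df = 1, lower.tail = FALSE)) /
    stats::qchisq(0.5, df = 1)
  list(table = data.frame(expected = rev(expected), observed = rev(observed)),
       lambda_gc = lambda)
}
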