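#' Two-kernel mixed-model covariance
#'
#' Assembles the n x n covariance of the stacked two-environment model:
#' `V = [Z_G G Z_G'] sigma2_g + ([Z_G G Z_G'] o [Z_E Z_E']) sigma2_ge
#'  + I sigma2_e`, where `o` is the Hadamard (element-wise) product. The
#' Hadamard mask `Z_E Z_E'` is 1 exactly where two records share an
#' environment, so the GxE kernel contributes kinship-structured covariance
#' within an environment and nothing across environments.
#'
#' @param G kinship (`kinship_matrix` or m x m matrix).
#' @param Z_G n x m variety incidence matrix.
#' @param Z_E n x 2 environment incidence matrix.
#' @param sigma2_g,sigma2_ge,sigma2_e variance components.
#' @return symmetric n x n covariance matrix.
#' @export
build_covariance <- function(G, Z_G, Z_E, sigma2_g, sigma2_ge, sigma2_e) {
  Gv <- if (inherits(G, "kinship_matrix")) G$values else G
  K1 <- Z_G %*% Gv %*% t(Z_G)
  K2 <- K1 * tcrossprod(Z_E)
  V <- K1 * sigma2_g + K2 * sigma2_ge + diag(sigma2_e, nrow(K1))
  (V + t(V)) / 2
}

# Profiled log-likelihood machinery shared by fit and scan. Given the
# variance ratios (gamma_g, gamma_ge) = (sigma2_g, sigma2_ge)/sigma2_e, the
# scaled covariance V* = gamma_g K1 + gamma_ge K2 + I is Cholesky-factored,
# fixed effects are profiled by GLS on whitened data, and sigma2_e is
# profiled in closed form: sigma2_e = RSS/n (ML) or RSS/(n-q) (REML, which
# additionally carries the log det(X'V^-1 X) - log det(X'X) adjustment).
gxe_profile <- function(theta, y, X, K1, K2, bounds = c(1e-6, 1e6),
                        reml = FALSE) {
  g <- pmin(pmax(exp(theta), bounds[1]), bounds[2])
  n <- length(y)
  Vs <- g[1] * K1 + g[2] * K2 + diag(1, n)
  R <- tryCatch(chol(Vs), error = function(e) NULL)
  if (is.null(R)) return(list(ll = -1e10))
  yt <- backsolve(R, y, transpose = TRUE)
  Xt <- backsolve(R, X, transpose = TRUE)
  fit <- stats::lm.fit(Xt, yt)
  rss <- sum(fit$residuals^2)
  if (reml) {
    q <- fit$rank
    s2e <- rss / (n - q)
    ldet_xvx <- determinant(crossprod(Xt), logarithm = TRUE)$modulus
    ldet_xx <- determinant(crossprod(X), logarithm = TRUE)$modulus
    ll <- -0.5 * ((n - q) * log(2 * pi * s2e) + 2 * sum(log(diag(R))) +
                    as.numeric(ldet_xvx - ldet_xx) + (n - q))
  } else {
    s2e <- rss / n
    ll <- -0.5 * (n * log(2 * pi * s2e) + 2 * sum(log(diag(R))) + n)
  }
  list(ll = ll, s2e = s2e, beta = fit$coefficients, gamma = g, R = R,
       rank = fit$rank)
}

#' Fit the two-kernel GxE mixed model
#'
#' Maximizes the full (`method = "ML"`) or restricted (`method = "REML"`)
#' multivariate-normal log-likelihood of
#' `y ~ N(X beta, sigma2_g K1 + sigma2_ge K2 + sigma2_e I)` where
#' `K1 = Z_G G Z_G'` and `K2 = K1 o Z_E Z_E'`. Fixed effects and the
#' residual variance are profiled out analytically; the two variance ratios
#' are optimized by Nelder-Mead on the log scale (bounds `[1e-6, 1e6]`)
#' seeded from a coarse profile-likelihood grid, restarting with a jitter
#' if the optimum lands on a bound. ML log-likelihoods are the ones that
#' remain comparable between the common-effect null and the
#' environment-specific alternative (their fixed effects differ), so the
#' likelihood-ratio machinery uses ML; REML is the recommended estimator
#' when the variance components themselves are the quantity of interest,
#' since ML variance estimates can collapse onto the `sigma2_e = 0`
#' boundary when the kinship spectrum is weakly informative.
#'
#' @param y n-vector of stacked phenotypes.
#' @param T n x 2 environment-mean design (from [stack_environments()]).
#' @param S m x k or n x k structure covariates (variety-level matrices are
#'   expanded through `Z_G`); may be `NULL`.
#' @param marker n x j matrix of marker fixed-effect columns: one common
#'   column `x` for the null model, two columns `pi_l o x` for the
#'   alternative, or `NULL` for the marker-free model.
#' @param G kinship matrix.
#' @param Z_G,Z_E incidence matrices (see [stack_environments()]).
#' @param kernels optional precomputed list `list(K1, K2)` to avoid
#'   rebuilding per call.
#' @param starts matrix of starting values for `(log gamma_g,
#'   log gamma_ge)`; one row per start.
#' @return an object of class `gxe_fit`: list with `t` (environment means),
#'   `s` (covariate effects), `marker_effects`, `sigma2_g`, `sigma2_ge`,
#'   `sigma2_e`, `loglik`, `convergence`, `boundary`.
#' @export
fit_gxe_model <- function(y, T, S = NULL, marker = NULL, G, Z_G, Z_E,
                          kernels = NULL, method = c("ML", "REML"),
                          starts = rbind(c(0, 0), c(1, -1), c(-2, -2))) {
  method <- match.arg(method)
  reml <- method == "REML"
  if (stats::var(y) == 0)
    stop("fit_gxe_model: constant response; fit is degenerate ",
         "(all variance estimates at the lower boundary)", call. = FALSE)
  Gv <- if (inherits(G, "kinship_matrix")) G$values else G
  if (is.null(kernels)) {
    K1 <- Z_G %*% Gv %*% t(Z_G)
    K2 <- K1 * tcrossprod(Z_E)
  } else {
    K1 <- kernels$K1; K2 <- kernels$K2
  }
  X <- T
  if (!is.null(S) && ncol(S) > 0) {
    Sn <- if (nrow(S) == length(y)) S else Z_G %*% S
    colnames(Sn) <- colnames(S)
    X <- cbind(X, Sn)
  }
  n_base <- ncol(X)
  if (!is.null(marker)) X <- cbind(X, marker)
  obj <- function(theta) -gxe_profile(theta, y, X, K1, K2, reml = reml)$ll
  lb <- log(1e-6); ub <- log(1e6)
  # coarse profile-likelihood scan picks the basin; Nelder-Mead refines
  grid <- seq(lb, ub, length.out = 7L)
  coarse <- expand.grid(grid, grid)
  cvals <- apply(coarse, 1L, obj)
  starts <- rbind(as.matrix(coarse[order(cvals)[1:3], ]), starts)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    o <- stats::optim(starts[i, ], obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 3000))
    if (is.null(best) || o$value < best$value) best <- o
  }
  # polish: a fresh simplex at the optimum guards against premature collapse
  o <- stats::optim(best$par, obj, method = "Nelder-Mead",
                    control = list(reltol = 1e-12, maxit = 3000))
  if (o$value < best$value) best <- o
  if (any(best$par <= lb + 1e-3) || any(best$par >= ub - 1e-3)) {
    o <- stats::optim(pmin(pmax(best$par, lb), ub) * 0.5 + 0.1, obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 3000))
    if (o$value < best$value) best <- o
  }
  pr <- gxe_profile(best$par, y, X, K1, K2, reml = reml)
  beta <- pr$beta
  mk <- if (!is.null(marker)) beta[seq.int(n_base + 1L, length(beta))]
        else numeric(0)
  structure(list(
    t = beta[1:2],
    s = if (n_base > 2) beta[3:n_base] else numeric(0),
    marker_effects = mk,
    sigma2_g = pr$gamma[1] * pr$s2e,
    sigma2_ge = pr$gamma[2] * pr$s2e,
    sigma2_e = pr$s2e,
    gamma = pr$gamma,
    loglik = pr$ll,
    method = method,
    convergence = best$convergence,
    boundary = any(pmin(pmax(best$par, lb), ub) %in% c(lb, ub)),
    rank = pr$rank, n = length(y)),
    class = "gxe_fit")
}

#' @export
print.gxe_fit <- function(x, ...) {
  cat(sprintf(
    "gxe_fit: logLik %.4f | sigma2_g %.4g, sigma2_ge %.4g, sigma2_e %.4g\n",
    x$loglik, x$sigma2_g, x$sigma2_ge, x$sigma2_e))
  invisible(x)
}

#' Likelihood-ratio test of environment-specific marker effects
#'
#' Compares the common-effect null fit against the environment-specific
#' alternative fit of the same marker on the same data via the deviance
#' `D = -2 (LL_null - LL_alt)`, referred to a chi-square distribution with
#' 1 degree of freedom (the alternative has one extra marker parameter).
#' Small negative deviances (within 1e-6, from optimizer tolerance) are
#' clipped to zero; larger negatives flag an optimizer failure.
#'
#' @param null,alt `gxe_fit` objects for the null and alternative models.
#' @param df test degrees of freedom (default 1).
#' @return list with `deviance`, `df`, `p_value`, `neg_log10_p`,
#'   `alpha_null`, `zeta`, `flag`.
#' @export
gxe_lrt <- function(null, alt, df = 1L) {
  stopifnot(inherits(null, "gxe_fit"), inherits(alt, "gxe_fit"))
  if (identical(null$method, "REML") || identical(alt$method, "REML"))
    warning("gxe_lrt: REML log-likelihoods are not comparable across fixed-",
            "effect structures; fit both models with method = \"ML\"",
            call. = FALSE)
  D <- -2 * (null$loglik - alt$loglik)
  flag <- "ok"
  if (D < -1e-6) flag <- "optimizer_failure"
  D <- max(D, 0)
  p <- stats::pchisq(D, df = df, lower.tail = FALSE)
  list(deviance = D, df = df, p_value = p, neg_log10_p = -log10(p),
       alpha_null = unname(null$marker_effects[1]),
       zeta = unname(alt$marker_effects), flag = flag)
}

#' Genome-wide GxE likelihood-ratio scan
#'
#' For every marker, tests whether its effect differs between the two
#' environments: the null model carries one common marker effect `alpha`,
#' the alternative one effect per environment `(zeta_1, zeta_2)`, both on
#' top of environment means, structure covariates, a kinship-structured
#' polygenic random effect and the Hadamard-product GxE random effect.
#' With the default `strategy = "p3d"` the three variance components are
#' estimated once under the marker-free model (by REML, which is stable
#' where ML variance estimates can hit the boundary) and their ratios held
#' fixed
#' for every per-marker fit (the residual scale is re-profiled per model),
#' so each marker costs two generalized-least-squares fits on whitened
#' data. `strategy = "exact"` re-optimizes the variance ratios for every
#' marker and model.
#'
#' @param pheno phenotype data.frame (`variety_id`, `environment`,
#'   `value`) or a prebuilt [stack_environments()] design list.
#' @param geno a `geno_matrix`.
#' @param G kinship; default [compute_grm()] of `geno`.
#' @param S structure covariates; default [pca_covariates()] with `n_pc`.
#' @param n_pc number of PCs when `S` is not supplied (default 5).
#' @param strategy `"p3d"` (default) or `"exact"`.
#' @return data.frame with one row per marker: `marker`, `chrom`, `pos`,
#'   `alpha_null`, `zeta_1`, `zeta_2` (effects in environment 1 and 2, in
#'   the order of the stacked design's `envs`), `deviance`, `df`,
#'   `p_value`, `neg_log10_p`, `note`. Attribute `fit0` carries the
#'   marker-free fit, `envs` the environment labels.
#' @export
run_gxe_scan <- function(pheno, geno, G = NULL, S = NULL, n_pc = 5L,
                         strategy = c("p3d", "exact")) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(geno, "geno_matrix"))
  design <- if (is.data.frame(pheno))
    stack_environments(pheno, varieties = geno$varieties) else pheno
  if (is.null(G)) G <- compute_grm(geno)
  Gv <- if (inherits(G, "kinship_matrix")) G$values else G
  if (is.null(S)) S <- pca_covariates(geno, n_pc)
  Zg <- design$Z_G; Ze <- design$Z_E
  K1 <- Zg %*% Gv %*% t(Zg)
  K2 <- K1 * tcrossprod(Ze)
  kernels <- list(K1 = K1, K2 = K2)
  y <- design$y
  n <- length(y)
  fit0 <- fit_gxe_model(y, design$T, S, marker = NULL, G = Gv,
                        Z_G = Zg, Z_E = Ze, kernels = kernels,
                        method = "REML")
  Sn <- if (!is.null(S) && ncol(S) > 0) Zg %*% S else NULL
  X0 <- if (is.null(Sn)) design$T else cbind(design$T, Sn)
  q0 <- ncol(X0)
  p <- ncol(geno$codes)
  out <- data.frame(marker = geno$variants$id, chrom = geno$variants$chrom,
                    pos = geno$variants$pos, alpha_null = NA_real_,
                    zeta_1 = NA_real_, zeta_2 = NA_real_,
                    deviance = NA_real_, df = NA_integer_,
                    p_value = NA_real_, neg_log10_p = NA_real_,
                    note = "ok", stringsAsFactors = FALSE)
  if (strategy == "p3d") {
    Vs <- fit0$gamma[1] * K1 + fit0$gamma[2] * K2 + diag(1, n)
    R <- chol(Vs)
    yt <- backsolve(R, y, transpose = TRUE)
    X0t <- backsolve(R, X0, transpose = TRUE)
    ldet <- 2 * sum(log(diag(R)))
    for (j in seq_len(p)) {
      xv <- geno$codes[, j]
      xn <- drop(Zg %*% replace(xv, is.na(xv), 0))
      miss <- is.na(xv)
      if (any(miss)) {
        res <- gxe_marker_lrt_subset(y, X0, xv, design, R = NULL,
                                     gamma = fit0$gamma, K1, K2, Zg)
      } else {
        res <- gxe_marker_lrt_whitened(yt, X0t, xn, design, R, ldet)
      }
      out[j, names(res)] <- res
    }
  } else {
    for (j in seq_len(p)) {
      xv <- geno$codes[, j]
      obs_v <- !is.na(xv)
      if (stats::var(xv[obs_v]) == 0) {
        out$note[j] <- "monomorphic"
        next
      }
      keep <- drop(Zg %*% as.numeric(obs_v)) > 0
      xn <- drop(Zg %*% replace(xv, is.na(xv), 0))
      x1 <- design$pi[[1]] * xn
      x2 <- design$pi[[2]] * xn
      sub <- function(M) M[keep, , drop = FALSE]
      K1s <- K1[keep, keep]; K2s <- K2[keep, keep]
      kern_s <- list(K1 = K1s, K2 = K2s)
      fit_n <- fit_gxe_model(y[keep], sub(X0)[, 1:2, drop = FALSE],
                             S = if (q0 > 2) sub(X0)[, -(1:2), drop = FALSE] else NULL,
                             marker = cbind(x = xn[keep]),
                             G = Gv, Z_G = sub(Zg), Z_E = sub(Ze),
                             kernels = kern_s)
      fit_a <- fit_gxe_model(y[keep], sub(X0)[, 1:2, drop = FALSE],
                             S = if (q0 > 2) sub(X0)[, -(1:2), drop = FALSE] else NULL,
                             marker = cbind(x1 = x1[keep], x2 = x2[keep]),
                             G = Gv, Z_G = sub(Zg), Z_E = sub(Ze),
                             kernels = kern_s)
      lrt <- gxe_lrt(fit_n, fit_a)
      out$alpha_null[j] <- lrt$alpha_null
      out$zeta_1[j] <- lrt$zeta[1]; out$zeta_2[j] <- lrt$zeta[2]
      out$deviance[j] <- lrt$deviance; out$df[j] <- lrt$df
      out$p_value[j] <- lrt$p_value; out$neg_log10_p[j] <- lrt$neg_log10_p
      out$note[j] <- lrt$flag
    }
  }
  attr(out, "fit0") <- fit0
  attr(out, "envs") <- design$envs
  out
}

# Fast path: marker fully observed; null and alternative are two OLS fits on
# pre-whitened data with the variance ratios fixed. D = n log(RSS0/RSS1).
gxe_marker_lrt_whitened <- function(yt, X0t, xn, design, R, ldet) {
  n <- length(yt)
  if (stats::var(xn) == 0)
    return(list(note = "monomorphic"))
  xt <- backsolve(R, xn, transpose = TRUE)
  x1 <- backsolve(R, design$pi[[1]] * xn, transpose = TRUE)
  x2 <- backsolve(R, design$pi[[2]] * xn, transpose = TRUE)
  fit0 <- stats::lm.fit(cbind(X0t, x = xt), yt)
  fit1 <- stats::lm.fit(cbind(X0t, x1 = x1, x2 = x2), yt)
  q_extra0 <- fit0$rank - qr(X0t)$rank
  df <- fit1$rank - fit0$rank
  note <- "ok"
  if (q_extra0 == 0) return(list(note = "monomorphic"))
  if (df < 1) {
    # marker monomorphic within one environment: the alternative adds no
    # parameter beyond the null; no GxE contrast is testable
    return(list(alpha_null = unname(fit0$coefficients["x"]),
                deviance = 0, df = 0L, note = "env_monomorphic"))
  }
  if (df == 1 && anyNA(fit1$coefficients[c("x1", "x2")]))
    note <- "env_monomorphic_reduced"
  rss0 <- sum(fit0$residuals^2)
  rss1 <- sum(fit1$residuals^2)
  D <- max(n * log(rss0 / rss1), 0)
  p <- stats::pchisq(D, df = df, lower.tail = FALSE)
  list(alpha_null = unname(fit0$coefficients["x"]),
       zeta_1 = unname(fit1$coefficients["x1"]),
       zeta_2 = unname(fit1$coefficients["x2"]),
       deviance = D, df = as.integer(df), p_value = p,
       neg_log10_p = -log10(p), note = note)
}

# Slow path: marker has missing calls; drop those varieties' records and
# re-whiten the fixed-ratio covariance on the subset.
gxe_marker_lrt_subset <- function(y, X0, xv, design, R, gamma, K1, K2, Zg) {
  obs_v <- !is.na(xv)
  keep <- drop(Zg %*% as.numeric(obs_v)) > 0
  if (sum(keep) < ncol(X0) + 2L || stats::var(xv[obs_v]) == 0)
    return(list(note = "monomorphic"))
  xn <- drop(Zg %*% replace(xv, is.na(xv), 0))
  n_s <- sum(keep)
  Vs <- gamma[1] * K1[keep, keep] + gamma[2] * K2[keep, keep] + diag(1, n_s)
  Rs <- chol(Vs)
  yt <- backsolve(Rs, y[keep], transpose = TRUE)
  X0t <- backsolve(Rs, X0[keep, , drop = FALSE], transpose = TRUE)
  des_s <- list(pi = lapply(design$pi, function(v) v[keep]))
  gxe_marker_lrt_whitened(yt, X0t, xn[keep], des_s, Rs,
                          2 * sum(log(diag(Rs))))
}
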