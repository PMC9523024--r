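#' Single-kernel variance-component fit (EMMA-style)
#'
#' Maximizes the restricted (default) or full likelihood of
#' `y ~ N(X beta, sigma2_g G + sigma2_e I)` by spectral decomposition of the
#' kinship matrix and a 1-D golden-section search over the variance ratio
#' `delta = sigma2_e / sigma2_g` on the log scale, with bounds
#' `[1e-6, 1e6]` and tolerance 1e-8 in log-delta. Fixed effects are profiled
#' out by generalized least squares at each ratio.
#'
#' @param y numeric response vector (one record per variety).
#' @param X fixed-effect design matrix; default intercept only.
#' @param G a `kinship_matrix` or plain PSD matrix conformable with `y`.
#' @param method `"REML"` (default, for heritability) or `"ML"` (for
#'   likelihood-ratio comparisons).
#' @return an object of class `variance_estimate`: list with `sigma2_g`,
#'   `sigma2_e`, `delta`, `beta`, `loglik`, `method`, `boundary` (logical).
#' @export
fit_single_kernel <- function(y, X = NULL, G, method = c("REML", "ML")) {
  method <- match.arg(method)
  Gv <- if (inherits(G, "kinship_matrix")) G$values else G
  n <- length(y)
  stopifnot(nrow(Gv) == n, ncol(Gv) == n)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  q <- qr(X)$rank
  if (q < ncol(X)) stop("fit_single_kernel: rank-deficient fixed-effect design",
                        call. = FALSE)
  ev <- eigen(Gv, symmetric = TRUE)
  d <- pmax(ev$values, 0)
  if (min(ev$values) < -1e-6)
    stop("fit_single_kernel: kinship matrix is not PSD", call. = FALSE)
  yt <- crossprod(ev$vectors, y)
  Xt <- crossprod(ev$vectors, X)
  ldet_xx <- determinant(crossprod(X), logarithm = TRUE)$modulus
  prof <- function(log_delta) {
    w <- d + exp(log_delta)
    sw <- 1 / sqrt(w)
    fit <- stats::lm.fit(Xt * sw, yt * sw)
    rss <- sum(fit$residuals^2)
    if (method == "ML") {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
    } else {
      s2 <- rss / (n - q)
      ldet_xvx <- determinant(crossprod(Xt * sw), logarithm = TRUE)$modulus
      ll <- -0.5 * ((n - q) * log(2 * pi * s2) + sum(log(w)) +
                      ldet_xvx - ldet_xx + (n - q))
    }
    list(ll = as.numeric(ll), s2 = s2, beta = fit$coefficients)
  }
  lo <- log(1e-6); hi <- log(1e6)
  opt <- stats::optimize(function(ld) -prof(ld)$ll, c(lo, hi), tol = 1e-8)
  best <- prof(opt$minimum)
  boundary <- opt$minimum < lo + 1e-4 || opt$minimum > hi - 1e-4
  if (boundary)
    warning("fit_single_kernel: variance ratio at search boundary; ",
            "estimates are boundary values", call. = FALSE)
  delta <- exp(opt$minimum)
  structure(list(sigma2_g = best$s2, sigma2_e = delta * best$s2,
                 delta = delta, beta = best$beta, loglik = best$ll,
                 method = method, boundary = boundary,
                 eigen = list(vectors = ev$vectors, values = d)),
            class = "variance_estimate")
}

#' @export
print.variance_estimate <- function(x, ...) {
  cat(sprintf("variance_estimate (%s): sigma2_g = %.4g, sigma2_e = %.4g, logLik = %.4f\n",
              x$method, x$sigma2_g, x$sigma2_e, x$loglik))
  invisible(x)
}

#' Narrow-sense heritability
#'
#' `h2 = sigma2_g / (sigma2_g + sigma2_e)`, the additive genetic fraction of
#' phenotypic variance under the single-kernel model.
#'
#' @param est a `variance_estimate`, or a numeric `sigma2_g` when
#'   `sigma2_e` is given separately.
#' @param sigma2_e error variance (only when `est` is numeric).
#' @return heritability in `[0, 1]`.
#' @export
heritability <- function(est, sigma2_e = NULL) {
  if (inherits(est, "variance_estimate")) {
    s2g <- est$sigma2_g; s2e <- est$sigma2_e
  } else {
    s2g <- est; s2e <- sigma2_e
  }
  if (is.null(s2e)) stop("heritability: sigma2_e missing", call. = FALSE)
  if (s2g < 0 || s2e < 0)
    stop("heritability: variances must be non-negative", call. = FALSE)
  if (s2g + s2e == 0)
    stop("heritability: both variances zero; h2 undefined", call. = FALSE)
  s2g / (s2g + s2e)
}

#' Per-environment heritability report
#'
#' Fits the single-kernel model to each environment's records separately
#' (intercept-only fixed effects) and tabulates the variance components and
#' heritability.
#'
#' @param pheno phenotype data.frame (`variety_id`, `environment`, `value`).
#' @param G a `kinship_matrix` whose variety order matches `variety_id`
#'   levels.
#' @return data.frame with columns `environment`, `sigma2_g`, `sigma2_e`,
#'   `h2`.
#' @export
heritability_by_env <- function(pheno, G) {
  stopifnot(inherits(G, "kinship_matrix"))
  envs <- sort(unique(pheno$environment))
  rows <- lapply(envs, function(e) {
    ph <- pheno[pheno$environment == e, ]
    idx <- match(ph$variety_id, G$varieties)
    if (anyNA(idx)) stop("heritability_by_env: variety not in kinship matrix",
                         call. = FALSE)
    est <- fit_single_kernel(ph$value, G = G$values[idx, idx, drop = FALSE])
    data.frame(environment = e, sigma2_g = est$sigma2_g,
               sigma2_e = est$sigma2_e, h2 = heritability(est),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
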