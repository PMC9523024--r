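make_design <- function(m, p, seed, ...) {
  cfg <- sim_config(m = m, p = p, seed = seed, ...)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  list(cfg = cfg, g = g, ph = ph, G = compute_grm(g),
       d = stack_environments(ph, varieties = g$varieties))
}

test_that("build_covariance realizes the Hadamard GxE kernel", {
  # 2 varieties x 2 environments, hand-checkable
  Zg <- rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1))
  Ze <- rbind(c(1, 0), c(0, 1), c(1, 0), c(0, 1))
  G <- matrix(c(1.0, 0.3, 0.3, 1.2), 2)
  V <- build_covariance(G, Zg, Ze, sigma2_g = 2, sigma2_ge = 0.5,
                        sigma2_e = 0.25)
  expect_equal(V, t(V))
  # diagonal: G_ii (s2g + s2ge) + s2e
  expect_equal(diag(V), c(1, 1, 1.2, 1.2) * 2.5 + 0.25, tolerance = 1e-12)
  # same variety, different environment: no GxE term
  expect_equal(V[1, 2], 1.0 * 2, tolerance = 1e-12)
  expect_equal(V[3, 4], 1.2 * 2, tolerance = 1e-12)
  # different variety, same environment: both kernels
  expect_equal(V[1, 3], 0.3 * 2.5, tolerance = 1e-12)
  # different variety and environment: polygenic only
  expect_equal(V[1, 4], 0.3 * 2, tolerance = 1e-12)
  # sigma2_ge = 0 reduces to the single-kernel covariance
  V0 <- build_covariance(G, Zg, Ze, 2, 0, 0.25)
  expect_equal(V0, Zg %*% G %*% t(Zg) * 2 + diag(0.25, 4), tolerance = 1e-12)
  # G = I: diagonal is the sum of all three components
  Vi <- build_covariance(diag(2), Zg, Ze, 1, 0.5, 0.25)
  expect_equal(diag(Vi), rep(1.75, 4), tolerance = 1e-12)
})

test_that("optimized GxE fits match a brute-force grid at n = 8", {
  sim <- make_design(4, 30, seed = 83, k = 1, fst = 0)
  d <- sim$d
  j <- which(apply(sim$g$codes, 2, stats::var) > 0)[1]
  xn <- drop(d$Z_G %*% sim$g$codes[, j])
  K1 <- d$Z_G %*% sim$G$values %*% t(d$Z_G)
  K2 <- K1 * tcrossprod(d$Z_E)
  for (marker in list(cbind(x = xn),
                      cbind(x1 = d$pi[[1]] * xn, x2 = d$pi[[2]] * xn))) {
    X <- cbind(d$T, marker)
    fit <- fit_gxe_model(d$y, d$T, marker = marker, G = sim$G,
                         Z_G = d$Z_G, Z_E = d$Z_E)
    # two-stage brute force over the bounded log-ratio plane
    stage <- function(r1, r2, k = 60) {
      best <- -Inf; arg <- c(NA, NA)
      for (a in seq(r1[1], r1[2], length.out = k))
        for (b in seq(r2[1], r2[2], length.out = k)) {
          V <- exp(a) * K1 + exp(b) * K2 + diag(1, 8)
          n <- 8
          Vi <- solve(V)
          bb <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% d$y)
          r <- d$y - X %*% bb
          s2 <- drop(t(r) %*% Vi %*% r) / n
          v <- -0.5 * (n * log(2 * pi * s2) +
                         as.numeric(determinant(V)$modulus) + n)
          if (v > best) { best <- v; arg <- c(a, b) }
        }
      list(ll = best, arg = arg, step = c(diff(r1), diff(r2)) / (k - 1))
    }
    lb <- log(1e-6); ub <- log(1e6)
    s1 <- stage(c(lb, ub), c(lb, ub))
    s2 <- stage(pmin(pmax(s1$arg[1] + c(-1, 1) * s1$step[1], lb), ub),
                pmin(pmax(s1$arg[2] + c(-1, 1) * s1$step[2], lb), ub))
    s2$ll <- max(s1$ll, s2$ll)
    expect_lt(abs(fit$loglik - s2$ll), 1e-3)
  }
})

test_that("the LRT machinery clips and converts deviances correctly", {
  f <- function(ll) structure(list(loglik = ll, marker_effects = c(x = 0.5),
                                   method = "ML"), class = "gxe_fit")
  same <- gxe_lrt(f(-10), f(-10))
  expect_identical(same$deviance, 0)
  expect_identical(same$p_value, 1)
  crit <- gxe_lrt(f(-10), f(-10 + 3.841 / 2))
  expect_equal(crit$p_value, 0.05, tolerance = 1e-3)
  tiny <- gxe_lrt(f(-10), f(-10 - 1e-8))   # within optimizer tolerance
  expect_identical(tiny$deviance, 0)
  expect_identical(tiny$flag, "ok")
  bad <- gxe_lrt(f(-10), f(-11))
  expect_identical(bad$flag, "optimizer_failure")
  expect_warning(gxe_lrt(structure(list(loglik = -1, marker_effects = 0,
                                        method = "REML"),
                                   class = "gxe_fit"), f(-1)),
                 "REML")
})

test_that("alternative-model effects agree under a common-effect truth", {
  fm <- data.frame(marker = 10L, zeta1 = 1, zeta2 = 1)
  sim <- make_design(80, 300, seed = 89, focal_markers = fm)
  scan <- run_gxe_scan(sim$ph, sim$g, G = sim$G)
  ok <- scan$note == "ok"
  # across null markers the two environment effects estimate the same thing
  expect_lt(abs(mean(scan$zeta_1[ok] - scan$zeta_2[ok])), 0.05)
  # the common-effect focal marker shows no GxE deviance signal
  expect_lt(scan$neg_log10_p[10], bonferroni_threshold(300))
  # deviances are non-negative everywhere (nested-model ordering)
  expect_true(all(scan$deviance[ok] >= 0))
})

test_that("environment-specific effects are detected and attributed", {
  fm <- data.frame(marker = 25L, zeta1 = 0, zeta2 = 2)
  sim <- make_design(100, 300, seed = 97, focal_markers = fm)
  scan <- run_gxe_scan(sim$ph, sim$g, G = sim$G)
  expect_identical(which.max(scan$neg_log10_p), 25L)
  expect_gt(scan$neg_log10_p[25], bonferroni_threshold(300))
  # fitted effects attribute the signal to the right environment
  expect_lt(abs(scan$zeta_1[25]), 0.75)
  expect_gt(scan$zeta_2[25], scan$zeta_1[25] + 1)
  # swapping environment labels for half the varieties destroys the signal
  ph2 <- sim$ph
  swap <- sim$g$varieties[seq(1, 100, by = 2)]
  sel <- ph2$variety_id %in% swap
  ph2$environment[sel] <- ifelse(ph2$environment[sel] == "15C", "30C", "15C")
  scan2 <- run_gxe_scan(ph2, sim$g, G = sim$G)
  expect_lt(scan2$neg_log10_p[25], bonferroni_threshold(300))
})

test_that("exact and P3D strategies agree on a small scan", {
  fm <- data.frame(marker = 3L, zeta1 = 0, zeta2 = 2)
  sim <- make_design(40, 12, seed = 101, focal_markers = fm)
  p3d <- run_gxe_scan(sim$ph, sim$g, G = sim$G, n_pc = 2)
  exact <- run_gxe_scan(sim$ph, sim$g, G = sim$G, n_pc = 2,
                        strategy = "exact")
  expect_identical(which.max(p3d$neg_log10_p), 3L)
  expect_identical(which.max(exact$neg_log10_p), 3L)
  ok <- p3d$note == "ok" & exact$note == "ok"
  expect_gt(stats::cor(p3d$deviance[ok], exact$deviance[ok]), 0.95)
})

test_that("markers with missing genotypes are tested on the observed subset", {
  sim <- make_design(50, 10, seed = 103)
  g <- sim$g
  set.seed(103)
  g$codes[sample(50, 10), 2] <- NA
  g$codes[, 5] <- -1
  scan <- run_gxe_scan(sim$ph, g, G = sim$G, n_pc = 2)
  expect_true(is.finite(scan$p_value[2]))
  expect_identical(scan$note[5], "monomorphic")
})

test_that("a constant response is rejected as degenerate", {
  sim <- make_design(10, 8, seed = 107)
  d <- sim$d
  expect_error(fit_gxe_model(rep(1, length(d$y)), d$T, G = sim$G,
                             Z_G = d$Z_G, Z_E = d$Z_E),
               "degenerate")
})
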