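test_that("implied covariance reduces to known closed forms", {
  nm <- paste0("V", 1:3)
  lam0 <- matrix(0, 3, 1, dimnames = list(nm, "f"))
  sp0 <- fixed_spec(lam0, psi = matrix(1, 1, 1), theta = rep(1, 3))
  expect_equal(unname(implied_covariance(sp0, numeric(0))), diag(3))

  lam1 <- matrix(1, 3, 1, dimnames = list(nm, "f"))
  sp1 <- fixed_spec(lam1, psi = matrix(1, 1, 1), theta = rep(0, 3))
  expect_equal(unname(implied_covariance(sp1, numeric(0))),
               matrix(1, 3, 3))
})

test_that("implied covariance of the fixed-links model matches the cellwise formula", {
  sp <- build_wmc_model(5)
  psi_c <- 0.0120; psi_d <- 0.0121
  th <- c(0.020, 0.028, 0.024, 0.040, 0.045)
  Sigma <- implied_covariance(sp, c(psi_c, psi_d, th))
  g <- c(0.36, 0.80, 0.99, 0.94, 0.64)
  brute <- matrix(NA_real_, 5, 5)
  for (i in 1:5) for (j in 1:5)
    brute[i, j] <- 1 * 1 * psi_c + g[i] * g[j] * psi_d +
      if (i == j) th[i] else 0
  expect_equal(unname(Sigma), brute, tolerance = 1e-12)
})

test_that("ML discrepancy has its closed-form values and zero point", {
  S <- random_one_factor_cor(1)
  expect_equal(ml_discrepancy(S, S), 0)
  expect_equal(ml_discrepancy(diag(2), diag(2, 2)), 2 * log(2) - 1)
  expect_error(ml_discrepancy(diag(2), matrix(c(1, 2, 2, 1), 2)),
               "positive definite")
})

test_that("ML discrepancy equals -2/n times the log-likelihood ratio vs saturated", {
  set.seed(42)
  n <- 12; p <- 3
  x <- matrix(rnorm(n * p), n, p) %*% matrix(c(1, .3, .2, 0, 1, .4, 0, 0, 1), 3)
  xc <- sweep(x, 2, colMeans(x))
  S <- crossprod(xc) / n                       # ML covariance
  A <- matrix(c(1, .5, .2, .5, 1.4, .3, .2, .3, 0.9), 3)  # arbitrary SPD
  # independent oracle: per-observation multivariate-normal log-densities
  ll <- function(Sigma) {
    ch <- chol(Sigma)
    z <- backsolve(ch, t(xc), transpose = TRUE)
    -n * p / 2 * log(2 * pi) - n * sum(log(diag(ch))) - sum(z^2) / 2
  }
  expect_equal(ml_discrepancy(S, A), -2 / n * (ll(A) - ll(S)),
               tolerance = 1e-10)
})

test_that("a saturated specification fits any sample matrix exactly", {
  # 2 manifests, loadings fixed to 1, free latent variance and residuals:
  # 3 free parameters = 3 moments, df = 0, so F_min = 0 and T = 0
  lam <- matrix(1, 2, 1, dimnames = list(c("V1", "V2"), "f"))
  sp <- model_spec(lam, psi = matrix(NA_real_, 1, 1))
  S <- matrix(c(1.3, 0.4, 0.4, 0.8), 2, dimnames = list(c("V1", "V2"),
                                                        c("V1", "V2")))
  f <- fl_fit(sp, sample_moments(S = S, n = 100))
  expect_identical(f$df, 0L)
  expect_lt(f$F_min, 1e-9)
  expect_lt(f$T, 1e-6)
})

test_that("one- and two-parameter fits agree with exhaustive grid search", {
  S <- matrix(c(1.2, 0.5, 0.5, 0.9), 2,
              dimnames = list(c("V1", "V2"), c("V1", "V2")))
  m <- sample_moments(S = S, n = 200)
  lam <- matrix(c(1, 1), 2, 1, dimnames = list(c("V1", "V2"), "f"))

  # one free parameter: psi, residuals fixed
  sp1 <- model_spec(lam, psi = matrix(NA_real_, 1, 1), theta = c(0.6, 0.5))
  f1 <- fl_fit(sp1, m)
  grid <- seq(0.01, 1.5, by = 1e-4)
  Fg <- vapply(grid, function(ps)
    ml_discrepancy(S, implied_covariance(sp1, ps)), numeric(1))
  expect_equal(unname(f1$theta_hat), grid[which.min(Fg)], tolerance = 1e-4)

  # two free parameters: psi and theta[V1] (theta[V2] fixed)
  sp2 <- model_spec(lam, psi = matrix(NA_real_, 1, 1),
                    theta = c(NA, 0.5))
  f2 <- fl_fit(sp2, m)
  g1 <- seq(0.2, 0.9, by = 2e-3); g2 <- seq(0.2, 1.2, by = 2e-3)
  best <- c(NA, NA); bestF <- Inf
  for (a in g1) {
    Fs <- vapply(g2, function(b)
      ml_discrepancy(S, implied_covariance(sp2, c(a, b))), numeric(1))
    if (min(Fs) < bestF) { bestF <- min(Fs); best <- c(a, g2[which.min(Fs)]) }
  }
  expect_equal(unname(f2$theta_hat), best, tolerance = 4e-3)
  expect_lte(f2$F_min, bestF + 1e-10)
})

test_that("congeneric fits agree with the independent ML factor-analysis fitter", {
  for (seed in 1:5) {
    R <- random_one_factor_cor(seed, n = 300)
    m <- sample_moments(S = R, n = 300)
    f <- fit_quietly(build_wmc_model(1), m)
    fa <- stats::factanal(covmat = R, factors = 1, n.obs = 300,
                          control = list(opt = list(factr = 100)))
    L <- as.numeric(loadings(fa))
    Sigma_fa <- tcrossprod(L); diag(Sigma_fa) <- 1
    F_fa <- ml_discrepancy(R, Sigma_fa)
    expect_equal(f$F_min, F_fa, tolerance = 1e-6)
    expect_equal(unname(f$standardized$lambda[, 1]), abs(L),
                 tolerance = 1e-4)
  }
})

test_that("test statistic scales with the configured multiplier", {
  m <- wmc_study_moments()
  f1 <- fl_fit(build_wmc_model(1), m, multiplier = "n-1")
  f2 <- fl_fit(build_wmc_model(1), m, multiplier = "n")
  expect_equal(f2$T / f1$T, 200 / 199, tolerance = 1e-9)
  expect_equal(f1$T, 199 * f1$F_min, tolerance = 1e-12)
})

test_that("rescaling a manifest variable leaves free-loading fits invariant", {
  d <- generate_wmc_data(population_model(), n = 400, seed = 11)
  wmc <- as.matrix(d[paste0("Cond", 1:5)])
  m0 <- sample_moments(raw = wmc)
  f0 <- fl_fit(build_wmc_model(1), m0)
  k <- 3.7
  wmc2 <- wmc; wmc2[, 2] <- k * wmc2[, 2]
  m2 <- sample_moments(raw = wmc2)
  f2 <- fl_fit(build_wmc_model(1), m2)
  expect_equal(f2$F_min, f0$F_min, tolerance = 1e-5)
  expect_equal(f2$T, f0$T, tolerance = 1e-5)
  expect_equal(f2$theta_hat[["lambda[Cond2~wmc]"]],
               k * f0$theta_hat[["lambda[Cond2~wmc]"]], tolerance = 1e-3)
  expect_equal(f2$theta_hat[["theta[Cond2]"]],
               k^2 * f0$theta_hat[["theta[Cond2]"]], tolerance = 1e-3)

  # deliberately violated under fixed-links loadings: the course pins the scale
  g0 <- fl_fit(build_wmc_model(5), m0)
  g2 <- fl_fit(build_wmc_model(5), m2)
  expect_gt(abs(g2$T - g0$T), 0.1)
})

test_that("standardized congeneric solution is metric-invariant", {
  d <- generate_wmc_data(population_model(), n = 400, seed = 12)
  wmc <- as.matrix(d[paste0("Cond", 1:5)])
  S <- cov(wmc)
  fS <- fl_fit(build_wmc_model(1), sample_moments(S = S, n = 400))
  fR <- fl_fit(build_wmc_model(1),
               sample_moments(S = cov2cor(S), n = 400))
  expect_equal(fS$standardized$lambda, fR$standardized$lambda,
               tolerance = 1e-6)
})

test_that("standardized variance decomposition sums to one for uncorrelated latents", {
  m <- wmc_study_moments()
  f <- fl_fit(build_wmc_model(5), m)
  tot <- rowSums(f$standardized$lambda^2) + f$standardized$theta
  expect_equal(unname(tot), rep(1, 5), tolerance = 1e-6)
})

test_that("estimates approach population values as n grows", {
  pop <- population_model()
  d <- generate_wmc_data(pop, n = 100000, seed = 13)
  m <- sample_moments(raw = as.matrix(d))
  f <- fl_fit(build_wmc_model("structural_fixedlinks"), m)
  expect_equal(f$theta_hat[["psi[constant]"]], pop$constant_variance,
               tolerance = 0.05)
  expect_equal(f$theta_hat[["psi[dynamic]"]], pop$dynamic_variance,
               tolerance = 0.05)
  expect_equal(f$standardized$beta[1, 2],
               unname(pop$reasoning_paths["constant"]), tolerance = 0.02)
  expect_equal(f$standardized$beta[1, 3],
               unname(pop$reasoning_paths["dynamic"]), tolerance = 0.02)
})

test_that("Heywood cases are reported, not hidden", {
  nm <- c("V1", "V2", "V3")
  S <- matrix(c(1, .85, .85, .85, 1, .45, .85, .45, 1), 3,
              dimnames = list(nm, nm))
  lam <- matrix(NA_real_, 3, 1, dimnames = list(nm, "f"))
  sp <- model_spec(lam, psi = matrix(1, 1, 1))
  expect_warning(f <- fl_fit(sp, sample_moments(S = S, n = 100)), "Heywood")
  expect_true(f$heywood)
  expect_true(any(f$theta_hat[paste0("theta[", nm, "]")] < 0))
})

test_that("a non-positive-definite sample matrix is rejected by name", {
  S <- matrix(1, 2, 2, dimnames = list(c("V1", "V2"), c("V1", "V2")))
  S[1, 2] <- S[2, 1] <- 1.5
  lam <- matrix(1, 2, 1, dimnames = list(c("V1", "V2"), "f"))
  sp <- model_spec(lam, psi = matrix(NA_real_, 1, 1))
  expect_error(fl_fit(sp, sample_moments(S = S, n = 50)), "`S`")
})
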