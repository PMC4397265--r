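test_that("the generator is deterministic under a fixed seed", {
  pop <- population_model()
  d1 <- generate_wmc_data(pop, n = 60, seed = 99)
  d2 <- generate_wmc_data(pop, n = 60, seed = 99)
  expect_identical(d1, d2)
  d3 <- generate_wmc_data(pop, n = 60, seed = 100)
  expect_false(identical(d1, d3))
})

test_that("default population reflects the study's calibration", {
  pop <- population_model()
  expect_equal(pop$constant_variance, 0.0120)
  expect_equal(pop$dynamic_variance, 0.0121)
  expect_equal(pop$dynamic_course, c(0.36, 0.80, 0.99, 0.94, 0.64))
  # residual SDs reconstruct the target total SDs
  g <- pop$dynamic_course
  expect_equal(sqrt(pop$wmc_residual_sds^2 + pop$constant_variance +
                      g^2 * pop$dynamic_variance),
               pop$wmc_total_sds, tolerance = 1e-12)
  # composite loadings reproduce the target inter-composite correlations
  l <- pop$composite_loadings
  expect_equal(l[["fig"]] * l[["num"]], 0.58, tolerance = 1e-12)
  expect_equal(l[["fig"]] * l[["verb"]], 0.40, tolerance = 1e-12)
  expect_equal(l[["num"]] * l[["verb"]], 0.42, tolerance = 1e-12)
})

test_that("population invariants are enforced", {
  expect_error(population_model(constant_variance = -0.01), "positive")
  expect_error(population_model(reasoning_paths = c(constant = 0.8,
                                                    dynamic = 0.7)),
               "below 1")
  expect_error(population_model(wmc_total_sds = c(0.05, 0.21, 0.19, 0.23,
                                                  0.24)),
               "too small")
  expect_error(population_model(error_family = "scaled_t", t_df = 3),
               "exceed 4")
})

test_that("sample moments converge to the implied population covariance", {
  pop <- population_model()
  Sigma <- population_implied_cov(pop)
  d <- generate_wmc_data(pop, n = 200000, seed = 41)
  S <- cov(as.matrix(d))
  expect_lt(max(abs(S - Sigma) / abs(Sigma)), 0.02)
  expect_equal(unname(colMeans(as.matrix(d))[4:8]), pop$wmc_means,
               tolerance = 0.01)
})

test_that("implied population covariance matches the structural algebra cellwise", {
  pop <- population_model()
  Sigma <- population_implied_cov(pop)
  g <- pop$dynamic_course
  psi_c <- pop$constant_variance; psi_d <- pop$dynamic_variance
  # condition block: constant + dynamic contributions
  for (i in 1:5) for (j in 1:5) {
    val <- psi_c + g[i] * g[j] * psi_d +
      if (i == j) pop$wmc_residual_sds[i]^2 else 0
    expect_equal(unname(Sigma[3 + i, 3 + j]), val, tolerance = 1e-12)
  }
  # composite block: unit variances with the target correlations
  expect_equal(unname(diag(Sigma)[1:3]), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(Sigma[1, 2]), 0.58, tolerance = 1e-12)
})

test_that("a null dynamic variance leaves nothing for the dynamic latent to absorb", {
  pop <- population_model(dynamic_variance = 1e-9)
  d <- generate_wmc_data(pop, n = 20000, seed = 42)
  f <- fit_quietly(build_wmc_model(5),
                   sample_moments(raw = as.matrix(d[paste0("Cond", 1:5)])))
  expect_lt(abs(f$theta_hat[["psi[dynamic]"]]), 0.005)
})

test_that("hit-rate clipping truncates to the unit interval", {
  pop_clip <- population_model(clip_hit_rates = TRUE)
  d <- generate_wmc_data(pop_clip, n = 5000, seed = 43)
  wmc <- as.matrix(d[paste0("Cond", 1:5)])
  expect_true(all(wmc >= 0 & wmc <= 1))
  pop_free <- population_model()
  d2 <- generate_wmc_data(pop_free, n = 5000, seed = 43)
  expect_gt(max(as.matrix(d2[paste0("Cond", 1:5)])), 1)
})

test_that("composite scoring z-standardizes and averages by content domain", {
  # three participants, worked by hand
  x <- rbind(c(2, 4, 10, 3, 1, 5),
             c(4, 6, 20, 5, 2, 6),
             c(6, 8, 30, 7, 3, 7))
  colnames(x) <- c("F1", "F2", "N1", "N2", "V1", "V2")
  out <- score_bis_composites(x)
  # every column here is a linear sequence, so each z-column is
  # (-1, 0, 1) / sd and each composite is the mean of two identical z-columns
  z <- c(-1, 0, 1)
  expect_equal(out$Figural, z / sd(c(2, 4, 6)) * 2, tolerance = 1e-12)
  expect_equal(out$Numerical, (z / sd(c(10, 20, 30)) * 10 +
                                 z / sd(c(3, 5, 7)) * 2) / 2,
               tolerance = 1e-12)
  expect_equal(colMeans(out), c(Figural = 0, Numerical = 0, Verbal = 0),
               tolerance = 1e-12)
})

test_that("composite scoring rejects degenerate input", {
  x <- matrix(1, 4, 6, dimnames = list(NULL, c("F1", "F2", "N1", "N2",
                                               "V1", "V2")))
  expect_error(score_bis_composites(x), "zero-variance")
  expect_error(score_bis_composites(matrix(rnorm(20), 4, 5)), "6 subtest")
})

test_that("column means of scored composites vanish for arbitrary input", {
  set.seed(7)
  for (r in 1:5) {
    x <- matrix(rnorm(10 * 6, mean = runif(1, -5, 5)), 10, 6)
    colnames(x) <- c("F1", "F2", "N1", "N2", "V1", "V2")
    expect_lt(max(abs(colMeans(score_bis_composites(x)))), 1e-12)
  }
})

test_that("small recovery runs are sane and track the population", {
  rec <- parameter_recovery_study(population_model(), n = 200,
                                  replications = 12, seed = 7)
  expect_identical(nrow(rec$summary), 4L)
  expect_true(all(is.finite(rec$summary$bias)))
  expect_lt(max(abs(rec$summary$bias[1:2])), 0.005)   # latent variances
  expect_identical(sum(rec$selection), 12L)
  expect_gte(rec$summary$coverage[1], 0.5)
})
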