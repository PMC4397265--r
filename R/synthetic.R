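#' Define the population model for the synthetic-data generator
#'
#' Describes the data-generating process the analysis assumes: five
#' repeated-measures hit-rate variables driven by two uncorrelated latents — a
#' constant process (loadings all 1) and a dynamic process with a fixed
#' loading course — plus three reasoning composites measuring a criterion
#' factor that is regressed on both latents. Defaults are calibrated to the
#' bundled study: latent variances .0120 / .0121, an inverted-u dynamic
#' course, condition means .88/.77/.77/.61/.55 and total SDs
#' .18/.21/.19/.23/.24 (the fifth condition's descriptives are an
#' extrapolation of the difficulty trend, overridable here), standardized
#' criterion paths .45 (constant) and .48 (dynamic), and composite loadings
#' reproducing inter-composite correlations .58/.40/.42.
#'
#' Residual variances of the conditions are derived from the target total
#' variances: `theta_i = SD_i^2 - psi_c - g_i^2 * psi_d`, erroring when a
#' target SD is too small to accommodate the latent contribution. The
#' criterion factor has unit total variance, so its disturbance is
#' `1 - .45^2 - .48^2`.
#'
#' @param constant_variance,dynamic_variance Latent variances (hit-rate
#'   metric).
#' @param dynamic_course A [loading_course()] for the dynamic latent.
#' @param wmc_means,wmc_total_sds Length-5 condition means and total SDs.
#' @param reasoning_paths Standardized paths of the criterion on the constant
#'   and dynamic latents, named `constant`, `dynamic`; their squared sum must
#'   stay below 1.
#' @param composite_cors Target correlations among the three unit-variance
#'   composites, named `fn`, `fv`, `nv` (figural-numerical, figural-verbal,
#'   numerical-verbal); converted to one-factor loadings.
#' @param error_family `"normal"` or `"scaled_t"`. The t family is an
#'   elliptical scale mixture: all of an observation's latent and residual
#'   shocks share one chi-square mixing draw, giving scaled-t marginals and
#'   untouched second moments while injecting excess kurtosis into every
#'   fourth-moment direction — the stressor the Satorra-Bentler correction
#'   responds to.
#' @param t_df Degrees of freedom for `"scaled_t"` (> 4 so fourth moments
#'   exist; default 5).
#' @param clip_hit_rates Truncate generated hit rates to `[0, 1]`. Default
#'   `FALSE` so that moment-level oracles are exact; turning it on mimics
#'   bounded data at the price of mild model misspecification.
#'
#' @return An object of class `fl_population`.
#' @examples
#' pop <- population_model()
#' round(pop$wmc_residual_sds, 3)
#' @export
population_model <- function(constant_variance = 0.0120,
                             dynamic_variance = 0.0121,
                             dynamic_course = loading_course("inverted_u"),
                             wmc_means = c(0.88, 0.77, 0.77, 0.61, 0.55),
                             wmc_total_sds = c(0.18, 0.21, 0.19, 0.23, 0.24),
                             reasoning_paths = c(constant = 0.45,
                                                 dynamic = 0.48),
                             composite_cors = c(fn = 0.58, fv = 0.40,
                                                nv = 0.42),
                             error_family = c("normal", "scaled_t"),
                             t_df = 5, clip_hit_rates = FALSE) {
  error_family <- match.arg(error_family)
  g <- as.numeric(dynamic_course)
  k <- length(g)
  stopifnot(length(wmc_means) == k, length(wmc_total_sds) == k)
  if (constant_variance <= 0 || dynamic_variance <= 0)
    stop("latent variances must be positive", call. = FALSE)
  bp <- reasoning_paths
  if (any(abs(bp) >= 1) || sum(bp^2) >= 1)
    stop("standardized criterion paths must lie in (-1, 1) with squared sum ",
         "below 1", call. = FALSE)
  if (error_family == "scaled_t" && t_df <= 4)
    stop("`t_df` must exceed 4 so that fourth moments exist", call. = FALSE)

  theta_wmc <- wmc_total_sds^2 - constant_variance - g^2 * dynamic_variance
  if (any(theta_wmc <= 0))
    stop("target total SDs too small for the latent contribution in ",
         "condition(s) ", paste(which(theta_wmc <= 0), collapse = ", "),
         call. = FALSE)

  cc <- composite_cors
  prods <- c(fig = cc[["fn"]] * cc[["fv"]] / cc[["nv"]],
             num = cc[["fn"]] * cc[["nv"]] / cc[["fv"]],
             verb = cc[["fv"]] * cc[["nv"]] / cc[["fn"]])
  if (any(prods <= 0) || any(prods >= 1))
    stop("composite correlations are not consistent with a one-factor ",
         "structure with loadings in (0, 1)", call. = FALSE)
  composite_loadings <- sqrt(prods)

  pop <- structure(
    list(constant_variance = constant_variance,
         dynamic_variance = dynamic_variance,
         dynamic_course = g,
         wmc_means = wmc_means, wmc_total_sds = wmc_total_sds,
         wmc_residual_sds = sqrt(theta_wmc),
         reasoning_paths = bp,
         composite_loadings = composite_loadings,
         disturbance_variance = 1 - sum(bp^2),
         error_family = error_family, t_df = t_df,
         clip_hit_rates = isTRUE(clip_hit_rates)),
    class = "fl_population")
  # the implied covariance must be admissible
  ev <- eigen(population_implied_cov(pop), only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("implied population covariance is not positive definite",
         call. = FALSE)
  pop
}

# fully fixed specification of the population (no free parameters), reusing
# the structural layout of build_wmc_model("structural_fixedlinks")
.population_spec <- function(pop) {
  manifest <- c(.reasoning_names(), .wmc_names())
  lam <- matrix(0, 8, 3,
                dimnames = list(manifest, c("reasoning", "constant", "dynamic")))
  lam[1:3, 1] <- pop$composite_loadings
  lam[4:8, 2] <- 1
  lam[4:8, 3] <- pop$dynamic_course
  psi <- diag(c(pop$disturbance_variance, pop$constant_variance,
                pop$dynamic_variance))
  beta <- matrix(0, 3, 3, dimnames = list(colnames(lam), colnames(lam)))
  beta[1, 2] <- pop$reasoning_paths[["constant"]] / sqrt(pop$constant_variance)
  beta[1, 3] <- pop$reasoning_paths[["dynamic"]] / sqrt(pop$dynamic_variance)
  theta <- c(1 - pop$composite_loadings^2, pop$wmc_residual_sds^2)
  model_spec(lam, psi = psi, beta = beta, theta = theta)
}

#' Implied population covariance of a population model
#'
#' The 8 x 8 covariance matrix the generator targets (composites first, then
#' conditions), obtained through the model-implied covariance algebra.
#'
#' @param pop An `fl_population`.
#' @return Symmetric 8 x 8 matrix.
#' @export
population_implied_cov <- function(pop) {
  stopifnot(inherits(pop, "fl_population"))
  implied_covariance(.population_spec(pop), numeric(0))
}

#' @export
print.fl_population <- function(x, ...) {
  cat("<fl_population> psi_c =", x$constant_variance,
      ", psi_d =", x$dynamic_variance,
      ", paths =", paste(x$reasoning_paths, collapse = "/"),
      ", errors:", x$error_family, "\n")
  invisible(x)
}

# n x k matrix of unit-variance shocks. The scaled-t family is an elliptical
# (common scale-mixture) multivariate t: all of an observation's shocks share
# one chi-square mixing draw, so marginals are scaled t_df and second moments
# match the normal family exactly, while excess kurtosis appears in every
# fourth-moment direction — including the residual directions that drive the
# Satorra-Bentler correction. Independent per-shock t draws would place all
# excess kurtosis inside the fitted model's tangent space, leaving the
# chi-square asymptotically uninflated.
.shock_matrix <- function(n, k, family, t_df) {
  Z <- matrix(stats::rnorm(n * k), n, k)
  if (family == "scaled_t") {
    u <- stats::rchisq(n, df = t_df)
    Z <- Z * sqrt((t_df - 2) / u)
  }
  Z
}

#' Generate participant-level data from a population model
#'
#' Draws latent scores (constant, dynamic, criterion disturbance) and
#' residuals from the configured error family and assembles the eight
#' manifest variables: hit rate in condition i is
#' `mean_i + 1 * xi_c + g_i * xi_d + e_i`, and each reasoning composite is
#' `l_j * eta + e_j` with the criterion `eta` regressed on both latents.
#' The same seed always yields the identical table.
#'
#' @param pop An `fl_population`.
#' @param n Sample size (>= 10).
#' @param seed Integer seed.
#' @return An n x 8 data frame: `Figural`, `Numerical`, `Verbal`,
#'   `Cond1` .. `Cond5`.
#' @examples
#' d <- generate_wmc_data(population_model(), n = 50, seed = 42)
#' colMeans(d)
#' @export
generate_wmc_data <- function(pop, n, seed = NULL) {
  stopifnot(inherits(pop, "fl_population"))
  if (n < 10) stop("`n` must be at least 10", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  Z <- .shock_matrix(n, 11L, pop$error_family, pop$t_df)
  xi_c <- sqrt(pop$constant_variance) * Z[, 1]
  xi_d <- sqrt(pop$dynamic_variance) * Z[, 2]
  zeta <- sqrt(pop$disturbance_variance) * Z[, 3]
  b_c <- pop$reasoning_paths[["constant"]] / sqrt(pop$constant_variance)
  b_d <- pop$reasoning_paths[["dynamic"]] / sqrt(pop$dynamic_variance)
  eta <- b_c * xi_c + b_d * xi_d + zeta

  comp <- sapply(seq_len(3), function(j)
    pop$composite_loadings[j] * eta +
      sqrt(1 - pop$composite_loadings[j]^2) * Z[, 3 + j])
  wmc <- sapply(seq_len(5), function(i) {
    y <- pop$wmc_means[i] + xi_c + pop$dynamic_course[i] * xi_d +
      pop$wmc_residual_sds[i] * Z[, 6 + i]
    if (pop$clip_hit_rates) pmin(pmax(y, 0), 1) else y
  })
  out <- data.frame(comp, wmc)
  names(out) <- c(.reasoning_names(), .wmc_names())
  out
}

#' Score reasoning subtests into content-domain composites
#'
#' z-standardizes each of six reasoning subtest score columns (two figural,
#' two numerical, two verbal) by its sample mean and SD, then averages the
#' two subtests per content domain.
#'
#' @param subtest_scores n x 6 table with columns ordered
#'   `F1, F2, N1, N2, V1, V2`.
#' @return n x 3 data frame `Figural`, `Numerical`, `Verbal`; each column has
#'   mean 0 by construction.
#' @examples
#' x <- matrix(rnorm(60), 10, 6)
#' colnames(x) <- c("F1", "F2", "N1", "N2", "V1", "V2")
#' colMeans(score_bis_composites(x))
#' @export
score_bis_composites <- function(subtest_scores) {
  x <- as.matrix(subtest_scores)
  if (ncol(x) != 6)
    stop("expected 6 subtest columns (F1, F2, N1, N2, V1, V2)", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("zero-variance subtest column(s): ",
         paste(which(sds == 0), collapse = ", "), call. = FALSE)
  z <- scale(x)
  out <- data.frame(Figural = (z[, 1] + z[, 2]) / 2,
                    Numerical = (z[, 3] + z[, 4]) / 2,
                    Verbal = (z[, 5] + z[, 6]) / 2)
  rownames(out) <- rownames(subtest_scores)
  out
}

#' Parameter-recovery simulation study
#'
#' Repeatedly generates data from a population model, refits the fixed-links
#' structural model, and summarizes recovery of the population values: mean
#' estimate, bias, empirical SD, and 95% Wald-interval coverage for the two
#' latent variances and the two standardized criterion paths. Each
#' replication also fits the four dynamic-course candidates (linear,
#' quadratic, logarithmic, inverted-u) to the five-condition block and
#' records which course is selected — lowest AIC among the candidates whose
#' dynamic-variance z-test is significant (no candidate significant counts as
#' "none"). Non-converged replications are tallied, not fatal.
#'
#' @param pop An `fl_population`.
#' @param n Per-replication sample size.
#' @param replications Number of replications (>= 50 recommended for stable
#'   summaries).
#' @param seed Master seed; replication r uses `seed + r`.
#' @param alpha Significance level for the variance z-tests (default .05).
#' @return An object of class `fl_recovery`: `summary` data frame (one row
#'   per tracked parameter), `selection` table of chosen courses,
#'   `z_significant` rates for the structural model's variance tests,
#'   `n_nonconverged`, plus the raw per-replication `draws`.
#' @examples
#' \donttest{
#' rec <- parameter_recovery_study(population_model(), n = 200,
#'                                 replications = 50, seed = 1)
#' rec$summary
#' }
#' @export
parameter_recovery_study <- function(pop, n = 200, replications = 200,
                                     seed = 1, alpha = 0.05) {
  stopifnot(inherits(pop, "fl_population"))
  spec <- build_wmc_model("structural_fixedlinks")
  courses <- c("linear", "quadratic", "logarithmic", "inverted_u")
  course_specs <- lapply(courses, function(cr) build_wmc_model(cr))
  names(course_specs) <- courses

  truth <- c("psi[constant]" = pop$constant_variance,
             "psi[dynamic]" = pop$dynamic_variance,
             "std_path_constant" = unname(pop$reasoning_paths["constant"]),
             "std_path_dynamic" = unname(pop$reasoning_paths["dynamic"]))

  draws <- vector("list", replications)
  selection <- character(replications)
  zsig <- matrix(NA, replications, 2,
                 dimnames = list(NULL, c("constant", "dynamic")))
  nonconv <- 0L

  for (r in seq_len(replications)) {
    d <- generate_wmc_data(pop, n, seed = seed + r)
    mom <- sample_moments(raw = as.matrix(d))
    fit <- tryCatch(
      suppressWarnings(fl_fit(spec, mom, se = TRUE)),
      error = function(e) NULL)
    if (is.null(fit) || !fit$converged) { nonconv <- nonconv + 1L }
    else {
      zc <- variance_z_test(fit, "constant")
      zd <- variance_z_test(fit, "dynamic")
      zsig[r, ] <- c(!is.na(zc$p) && zc$p < alpha,
                     !is.na(zd$p) && zd$p < alpha)
      draws[[r]] <- c(
        "psi[constant]" = unname(fit$theta_hat["psi[constant]"]),
        "psi[dynamic]" = unname(fit$theta_hat["psi[dynamic]"]),
        "se_psi[constant]" = unname(fit$se["psi[constant]"]),
        "se_psi[dynamic]" = unname(fit$se["psi[dynamic]"]),
        "std_path_constant" = fit$standardized$beta[1, 2],
        "std_path_dynamic" = fit$standardized$beta[1, 3])
    }

    # course selection on the five-condition block
    wmom <- sample_moments(raw = as.matrix(d)[, .wmc_names()])
    cand <- lapply(course_specs, function(sp) tryCatch(
      suppressWarnings(fl_fit(sp, wmom, se = TRUE)),
      error = function(e) NULL))
    ok <- !vapply(cand, is.null, logical(1))
    aic <- rep(NA_real_, length(cand))
    sig <- rep(FALSE, length(cand))
    for (i in which(ok)) {
      aic[i] <- cand[[i]]$T - 2 * cand[[i]]$df
      zp <- variance_z_test(cand[[i]], "dynamic")$p
      sig[i] <- !is.na(zp) && zp < alpha
    }
    selection[r] <- if (any(sig)) courses[which(sig)][which.min(aic[sig])]
                    else "none"
  }

  got <- !vapply(draws, is.null, logical(1))
  dm <- do.call(rbind, draws[got])
  summ <- do.call(rbind, lapply(names(truth), function(par) {
    est <- dm[, par]
    cover <- if (startsWith(par, "psi[")) {
      se <- dm[, paste0("se_", par)]
      mean(abs(est - truth[[par]]) <= 1.96 * se, na.rm = TRUE)
    } else NA_real_
    data.frame(parameter = par, true = truth[[par]], mean = mean(est),
               bias = mean(est) - truth[[par]], sd = stats::sd(est),
               coverage = cover, stringsAsFactors = FALSE)
  }))
  structure(list(summary = summ,
                 selection = table(factor(selection,
                                          levels = c(courses, "none"))),
                 z_significant = colMeans(zsig, na.rm = TRUE),
                 n_nonconverged = nonconv,
                 replications = replications, n = n, draws = dm),
            class = "fl_recovery")
}

#' @export
print.fl_recovery <- function(x, ...) {
  cat("<fl_recovery> ", x$replications, " replications at n = ", x$n,
      " (", x$n_nonconverged, " non-converged)\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 3)
  cat("variance z-test significant: constant ",
      round(x$z_significant[["constant"]], 3), ", dynamic ",
      round(x$z_significant[["dynamic"]], 3), "\n", sep = "")
  cat("dynamic-course selection:\n")
  print(x$selection)
  invisible(x)
}
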