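#' Bundled study moments: working-memory conditions and reasoning composites
#'
#' The 8 x 8 Pearson correlation matrix (n = 200) of three reasoning
#' composites (figural, numerical, verbal) and hit rates in the five
#' conditions of a figural dot-span working-memory task with set sizes 2-6,
#' shipped as a labelled CSV under `inst/extdata`. Correlations are at the
#' 2-decimal precision of the published table, which bounds how exactly
#' covariance-metric quantities can be reproduced from it.
#'
#' @return An `fl_moments` with `is_correlation = TRUE` and `n = 200`.
#' @examples
#' wmc_study_moments()
#' @export
wmc_study_moments <- function() {
  f <- system.file("extdata", "wmc_reasoning_cor.csv", package = "fixedlinks",
                   mustWork = TRUE)
  read_moments_csv(f, n = 200)
}

.warn_correlation_metric <- function(moments) {
  if (moments$is_correlation)
    warning("input is a correlation matrix: unstandardized fixed-links ",
            "quantities (latent variances) are metric-dependent and not ",
            "comparable to covariance-metric values; interpret the ",
            "standardized solution", call. = FALSE)
}

#' Fit and compare the measurement models of the study
#'
#' Fits the congeneric one-factor model and the four fixed-links models
#' (constant latent plus linear / quadratic / logarithmic / inverted-u
#' dynamic course) to the five working-memory conditions, computes fit
#' indices and per-latent variance z-tests, and applies the joint AIC / CFI
#' comparison rule with the substantive rejection rule: a fixed-links model
#' whose dynamic-variance z-test fails is rejected regardless of fit.
#'
#' @param moments An `fl_moments` covering the variables `Cond1` .. `Cond5`.
#' @param models Subset of 1:5 to fit (default all).
#' @param alpha Significance level for the variance z-tests.
#' @param robust Compute Satorra-Bentler scaled statistics (needs raw data);
#'   indices are then based on the scaled statistic.
#' @return List of class `fl_study_fragment`: `fits`, `indices`,
#'   `variance_tests`, `comparison`.
#' @examples
#' run_measurement_models(wmc_study_moments())
#' @export
run_measurement_models <- function(moments, models = 1:5, alpha = 0.05,
                                   robust = FALSE) {
  stopifnot(inherits(moments, "fl_moments"))
  if (!all(.wmc_names() %in% moments$names))
    stop("sample moments must contain the five task conditions ",
         paste(.wmc_names(), collapse = ", "), call. = FALSE)
  .warn_correlation_metric(moments)
  models <- sort(unique(as.integer(models)))
  stopifnot(all(models %in% 1:5))
  labels <- c("Congeneric", "Constant + Linear", "Constant + Quadratic",
              "Constant + Logarithmic", "Constant + Inverted-u")

  fits <- list(); indices <- list(); vtests <- list(); rejected <- character(0)
  for (k in models) {
    nm <- sprintf("Model %d (%s)", k, labels[k])
    fit <- fl_fit(build_wmc_model(k), moments, robust = robust)
    fits[[nm]] <- fit
    indices[[nm]] <- fit_indices(
      fit, statistic = if (robust) "scaled" else "plain", model = nm)
    if (k > 1) {
      vt <- list(constant = variance_z_test(fit, "constant"),
                 dynamic = variance_z_test(fit, "dynamic"))
      vtests[[nm]] <- vt
      if (is.na(vt$dynamic$p) || vt$dynamic$p >= alpha)
        rejected <- c(rejected, nm)
    }
  }
  comparison <- if (length(indices) >= 2)
    compare_models(indices, rejected = rejected) else NULL
  structure(list(fits = fits, indices = indices, variance_tests = vtests,
                 comparison = comparison),
            class = "fl_study_fragment")
}

#' Fit the structural models relating the latents to reasoning
#'
#' Fits both structural models to the 8-variable moments: the traditional-CFA
#' model (one congeneric working-memory factor predicting the reasoning
#' factor) and the fixed-links model (constant and inverted-u dynamic
#' latents, mutually uncorrelated, each predicting reasoning). Reports
#' standardized paths with p-values, the squared paths as percent shared
#' variance, and optionally a Wald test of constraining the fixed-links
#' dynamic path to a given standardized value.
#'
#' @param moments An `fl_moments` with the three composites and five
#'   conditions.
#' @param constrain_dynamic_to Optional standardized value at which to
#'   Wald-test the `reasoning~dynamic` path of the fixed-links model.
#' @param robust Compute Satorra-Bentler scaled statistics (needs raw data).
#' @return List of class `fl_study_fragment`: per-model `fits`, `indices`,
#'   `paths` (data frame of standardized paths, p-values and percent shared
#'   variance), and `wald` (or `NULL`).
#' @examples
#' run_structural_models(wmc_study_moments(), constrain_dynamic_to = 0.68)
#' @export
run_structural_models <- function(moments, constrain_dynamic_to = NULL,
                                  robust = FALSE) {
  stopifnot(inherits(moments, "fl_moments"))
  need <- c(.reasoning_names(), .wmc_names())
  if (!all(need %in% moments$names))
    stop("sample moments must contain ", paste(need, collapse = ", "),
         call. = FALSE)
  .warn_correlation_metric(moments)
  stat <- if (robust) "scaled" else "plain"

  fits <- list(
    "Traditional CFA" = fl_fit(build_wmc_model("structural_cfa"), moments,
                               robust = robust),
    "Fixed-links" = fl_fit(build_wmc_model("structural_fixedlinks"), moments,
                           robust = robust))
  indices <- Map(function(f, nm) fit_indices(f, statistic = stat, model = nm),
                 fits, names(fits))

  path_row <- function(fit, outcome, predictor, model) {
    lab <- sprintf("beta[%s~%s]", outcome, predictor)
    bfun <- .std_path_fun(fit$spec, outcome, predictor)
    b <- bfun(fit$theta_hat)
    g <- .num_grad(bfun, fit$theta_hat)
    v <- drop(t(g) %*% fit$vcov %*% g)
    z <- if (is.finite(v) && v > 0) b / sqrt(v) else NA_real_
    data.frame(model = model, path = sprintf("%s~%s", outcome, predictor),
               beta_std = b, z = z,
               p = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)),
               pct_shared_variance = 100 * b^2, stringsAsFactors = FALSE)
  }
  paths <- rbind(
    path_row(fits[[1]], "reasoning", "wmc", "Traditional CFA"),
    path_row(fits[[2]], "reasoning", "constant", "Fixed-links"),
    path_row(fits[[2]], "reasoning", "dynamic", "Fixed-links"))

  wald <- if (!is.null(constrain_dynamic_to))
    wald_constraint_test(fits[[2]], "reasoning~dynamic",
                         constrain_dynamic_to)
  else NULL

  structure(list(fits = fits, indices = indices, paths = paths, wald = wald),
            class = "fl_study_fragment")
}

#' Split-sample robustness check for a fixed-links model
#'
#' Randomly partitions the participants into `groups` folds and refits the
#' model on each leave-one-group-out subsample (a full refit: free variances
#' re-estimated with the loadings still fixed to their course). A
#' non-significant chi-square in every subsample indicates that the fixed
#' loading course does not capitalize on chance.
#'
#' @param raw n x p data table containing at least the model's manifest
#'   variables; n must allow >= 10 rows per fold.
#' @param spec Model to refit; default the constant + inverted-u model.
#' @param groups Number of folds (default 4).
#' @param seed Seed for the random partition (same seed, same partition).
#' @param threshold p-value threshold (default .05).
#' @return List with `p_values` (one per left-out group), `pass` (all above
#'   the threshold), and `assignment`.
#' @examples
#' d <- generate_wmc_data(population_model(), n = 200, seed = 3)
#' split_sample_robustness(d[paste0("Cond", 1:5)], seed = 3)$p_values
#' @export
split_sample_robustness <- function(raw, spec = build_wmc_model(5),
                                    groups = 4, seed = NULL,
                                    threshold = 0.05) {
  raw <- as.matrix(raw)
  n <- nrow(raw)
  if (n < 10 * groups)
    stop("too few rows: need at least ", 10 * groups, " for ", groups,
         " folds", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  assignment <- sample(rep_len(seq_len(groups), n))
  p_values <- vapply(seq_len(groups), function(g) {
    sub <- raw[assignment != g, spec$manifest, drop = FALSE]
    fit <- fl_fit(spec, sample_moments(raw = sub))
    stats::pchisq(fit$T, fit$df, lower.tail = FALSE)
  }, numeric(1))
  list(p_values = p_values, pass = all(p_values > threshold),
       threshold = threshold, assignment = assignment)
}

#' Reproduce the full study analysis on the bundled correlation matrix
#'
#' Runs the complete pipeline on [wmc_study_moments()]: the five measurement
#' models with fit indices, variance z-tests and the comparison rule, then
#' both structural models with standardized paths and the Wald constraint
#' test of the fixed-links dynamic path against a reference value.
#'
#' @param constrain_dynamic_to Standardized constraint for the Wald test
#'   (default .68, the traditional-CFA reference value used in the study).
#' @return An object of class `fl_study_report` combining both fragments.
#' @examples
#' reproduce_study()
#' @export
reproduce_study <- function(constrain_dynamic_to = 0.68) {
  moments <- wmc_study_moments()
  meas <- suppressWarnings(run_measurement_models(moments))
  struc <- suppressWarnings(
    run_structural_models(moments,
                          constrain_dynamic_to = constrain_dynamic_to))
  structure(list(moments = moments, measurement = meas, structural = struc),
            class = "fl_study_report")
}

#' @export
print.fl_study_report <- function(x, ...) {
  cat("== Measurement models (five task conditions) ==\n")
  write_fit_table(x$measurement$indices)
  cat("\nVariance z-tests (dynamic latent):\n")
  for (nm in names(x$measurement$variance_tests)) {
    vt <- x$measurement$variance_tests[[nm]]$dynamic
    cat(sprintf("  %s: psi_d = %.4f, z = %.2f, p = %s\n",
                nm, vt$estimate, vt$z, format_p(vt$p)))
  }
  cat("\n")
  print(x$measurement$comparison)
  cat("\n== Structural models ==\n")
  write_fit_table(x$structural$indices)
  cat("\nStandardized paths:\n")
  pd <- x$structural$paths
  for (i in seq_len(nrow(pd)))
    cat(sprintf("  %s %s: beta = %.2f, p = %s (%.2f%% shared variance)\n",
                pd$model[i], pd$path[i], pd$beta_std[i], format_p(pd$p[i]),
                pd$pct_shared_variance[i]))
  if (!is.null(x$structural$wald)) {
    w <- x$structural$wald
    cat(sprintf("\nWald test of reasoning~dynamic = %.2f: chi2(1) = %.2f, p = %s\n",
                w$value, w$W, format_p(w$p)))
  }
  invisible(x)
}
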