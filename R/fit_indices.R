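#' Independence-baseline statistic
#'
#' Fits the independence model (diagonal implied covariance, free variances),
#' the conventional baseline for incremental fit indices. Its ML solution is
#' closed-form — the fitted variances equal the sample variances — so
#' \eqn{F_b = \sum_i \ln s_{ii} - \ln|S|} and `T_b = multiplier * F_b`, with
#' `df_b = p(p-1)/2`.
#'
#' @param moments An `fl_moments`.
#' @param vars Optional subset of variable names.
#' @param multiplier `"n-1"` (default) or `"n"`.
#' @return List with `T_b`, `df_b`, `F_b`.
#' @examples
#' baseline_model(wmc_study_moments())
#' @export
baseline_model <- function(moments, vars = NULL, multiplier = c("n-1", "n")) {
  stopifnot(inherits(moments, "fl_moments"))
  multiplier <- match.arg(multiplier)
  S <- moments$S
  if (!is.null(vars)) S <- S[vars, vars, drop = FALSE]
  p <- nrow(S)
  ld <- .logdet_chol(S, "sample matrix `S`")$logdet
  F_b <- sum(log(diag(S))) - ld
  mult <- if (multiplier == "n-1") moments$n - 1 else moments$n
  list(T_b = mult * F_b, df_b = p * (p - 1) / 2, F_b = F_b)
}

#' Compute fit indices from test statistics
#'
#' The lower-level worker behind [fit_indices()]; operates directly on
#' statistics so that printed (e.g. robustly scaled) values can be fed in.
#' Formulas:
#' \itemize{
#' \item p-value: upper tail of the central chi-square at `df`;
#' \item `CFI = 1 - max(T - df, 0) / max(T_b - df_b, T - df, 0)`;
#' \item `RMSEA = sqrt(max(T - df, 0) / (df * (n - 1)))`;
#' \item `SRMR`: root mean square of the standardized residuals
#'   `(s_ij - sigma_ij) / sqrt(s_ii s_jj)` over the p(p+1)/2 non-duplicated
#'   elements (requires `S` and `Sigma`);
#' \item `AIC = T - 2 * df`, the same-data comparison convention in which
#'   lower is more parsimonious.
#' }
#' With `df = 0` the RMSEA and AIC are undefined and reported as `NA`.
#'
#' @param T Test statistic. @param df Model degrees of freedom.
#' @param T_b,df_b Baseline statistic and degrees of freedom.
#' @param n Sample size.
#' @param S,Sigma Optional sample and implied matrices for the SRMR.
#' @param model Optional label carried into the report.
#' @return An object of class `fl_indices`.
#' @examples
#' compute_indices(T = 8.6, df = 8, T_b = 300, df_b = 10, n = 200)
#' @export
compute_indices <- function(T, df, T_b, df_b, n, S = NULL, Sigma = NULL,
                            model = NULL) {
  stopifnot(T >= 0, df >= 0, df_b > 0, n > 1)
  if (df > 0) {
    p_value <- stats::pchisq(T, df, lower.tail = FALSE)
    RMSEA <- sqrt(max(T - df, 0) / (df * (n - 1)))
    AIC <- T - 2 * df
  } else {
    p_value <- NA_real_; RMSEA <- NA_real_; AIC <- NA_real_
  }
  denom <- max(T_b - df_b, T - df, 0)
  CFI <- if (denom == 0) 1 else 1 - max(T - df, 0) / denom
  SRMR <- if (!is.null(S) && !is.null(Sigma)) {
    sdp <- sqrt(diag(as.matrix(S)))
    R <- (as.matrix(S) - as.matrix(Sigma)) / outer(sdp, sdp)
    sqrt(mean(R[lower.tri(R, diag = TRUE)]^2))
  } else NA_real_
  structure(list(model = model, T = T, df = df, p_value = p_value,
                 CFI = CFI, RMSEA = RMSEA, SRMR = SRMR, AIC = AIC,
                 baseline_T = T_b, baseline_df = df_b, n = n),
            class = "fl_indices")
}

#' Fit indices for a fitted model
#'
#' Computes the chi-square p-value, CFI, RMSEA, SRMR and AIC for an
#' [fl_fit()]. By default uses the plain ML statistic; `statistic = "scaled"`
#' uses the Satorra-Bentler scaled statistic (both for the target and the
#' baseline model, which is then also scaled).
#'
#' @param fit An `fl_fit`.
#' @param statistic `"plain"` (default) or `"scaled"` (requires a robust fit).
#' @param model Optional label.
#' @return An `fl_indices` report.
#' @examples
#' fit_indices(fl_fit(build_wmc_model(5), wmc_study_moments()))
#' @export
fit_indices <- function(fit, statistic = c("plain", "scaled"), model = NULL) {
  stopifnot(inherits(fit, "fl_fit"))
  statistic <- match.arg(statistic)
  Tstat <- if (statistic == "scaled") {
    if (is.null(fit$T_scaled))
      stop("no scaled statistic in this fit; refit with robust = TRUE",
           call. = FALSE)
    fit$T_scaled
  } else fit$T
  b <- baseline_model(fit$moments, vars = fit$spec$manifest,
                      multiplier = fit$multiplier)
  compute_indices(Tstat, fit$df, b$T_b, b$df_b, fit$n,
                  S = fit$S, Sigma = fit$Sigma_hat, model = model)
}

#' @export
print.fl_indices <- function(x, ...) {
  cat(sprintf(
    "%sT = %.2f, df = %d, p = %s, CFI = %.3f, RMSEA = %.2f, SRMR = %s, AIC = %.2f\n",
    if (is.null(x$model)) "" else paste0(x$model, ": "),
    x$T, x$df, format_p(x$p_value), x$CFI, x$RMSEA,
    if (is.na(x$SRMR)) "NA" else sprintf("%.2f", x$SRMR), x$AIC))
  invisible(x)
}

#' Compare fitted models by the joint AIC / CFI rule
#'
#' Implements the model-comparison rule of the study pipeline: model A is
#' "better" than model B when its AIC is lower (higher parsimony) AND its CFI
#' exceeds B's by more than .01; otherwise the pair is "not distinguishable".
#' Models whose dynamic-variance z-test failed are additionally flagged
#' `rejected` — a latent with nonsignificant variance does not reflect a
#' meaningful process, so the model is discarded regardless of fit.
#'
#' @param reports Named list of `fl_indices` reports.
#' @param rejected Optional character vector (or named logical) of models
#'   rejected on substantive grounds (failed variance test).
#' @param delta_cfi CFI margin, default .01.
#' @return An object of class `fl_comparison`: data frame `verdicts`
#'   (model_a, model_b, verdict), character `rejected`, and `preferred` — the
#'   non-rejected models not "bettered" by any other.
#' @examples
#' m <- wmc_study_moments()
#' r <- lapply(c(2, 5), function(k)
#'   fit_indices(fl_fit(build_wmc_model(k), m), model = paste0("Model ", k)))
#' names(r) <- c("Model 2", "Model 5")
#' compare_models(r)
#' @export
compare_models <- function(reports, rejected = character(0),
                           delta_cfi = 0.01) {
  stopifnot(length(reports) >= 2)
  if (is.null(names(reports)))
    names(reports) <- paste0("model", seq_along(reports))
  if (is.logical(rejected)) rejected <- names(rejected)[rejected]
  nm <- names(reports)
  rows <- list()
  for (a in nm) for (b in nm) {
    if (a == b) next
    ra <- reports[[a]]; rb <- reports[[b]]
    verdict <- if (!is.na(ra$AIC) && !is.na(rb$AIC) &&
                   ra$AIC < rb$AIC && (ra$CFI - rb$CFI) > delta_cfi)
      "better" else "not distinguishable"
    rows[[length(rows) + 1L]] <-
      data.frame(model_a = a, model_b = b, verdict = verdict,
                 stringsAsFactors = FALSE)
  }
  verdicts <- do.call(rbind, rows)
  beaten <- unique(verdicts$model_b[verdicts$verdict == "better" &
                                      !(verdicts$model_a %in% rejected)])
  preferred <- setdiff(nm, union(beaten, rejected))
  structure(list(verdicts = verdicts, rejected = intersect(rejected, nm),
                 preferred = preferred, delta_cfi = delta_cfi),
            class = "fl_comparison")
}

#' @export
print.fl_comparison <- function(x, ...) {
  better <- x$verdicts[x$verdicts$verdict == "better", , drop = FALSE]
  if (nrow(better) == 0) cat("no pair distinguishable by the joint rule\n")
  else for (i in seq_len(nrow(better)))
    cat(sprintf("%s better than %s\n", better$model_a[i], better$model_b[i]))
  if (length(x$rejected))
    cat("rejected (nonsignificant dynamic variance):",
        paste(x$rejected, collapse = ", "), "\n")
  cat("preferred:", paste(x$preferred, collapse = ", "), "\n")
  invisible(x)
}

# p-value display convention: "< .001", "< .01", "< .05", else 2 decimals
format_p <- function(p) {
  if (is.na(p)) return("NA")
  if (p < 0.001) return("< .001")
  if (p < 0.01) return("< .01")
  if (p < 0.05) return("< .05")
  sub("^0", "", sprintf("%.2f", p))
}

#' Write a model-comparison table
#'
#' Emits the fit-statistics table (one row per model: statistic, df, p, CFI,
#' RMSEA, SRMR, AIC) as delimited text or JSON. CFI is printed to 3 decimals
#' and the other indices to 2, full precision being retained in the reports
#' themselves.
#'
#' @param reports Named list of `fl_indices`.
#' @param file Output path; `""` writes to stdout.
#' @param format `"tsv"`, `"csv"` or `"json"`.
#' @return Invisibly, the data frame written (for `"json"`, the unrounded
#'   version).
#' @export
write_fit_table <- function(reports, file = "",
                            format = c("tsv", "csv", "json")) {
  format <- match.arg(format)
  full <- do.call(rbind, lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    data.frame(model = nm, T = r$T, df = r$df, p = r$p_value, CFI = r$CFI,
               RMSEA = r$RMSEA, SRMR = r$SRMR, AIC = r$AIC,
               stringsAsFactors = FALSE)
  }))
  if (format == "json") {
    jsonlite::write_json(full, file, dataframe = "rows", auto_unbox = TRUE,
                         digits = NA, na = "null")
    return(invisible(full))
  }
  disp <- data.frame(
    model = full$model,
    T = sprintf("%.2f", full$T), df = full$df,
    p = vapply(full$p, format_p, character(1)),
    CFI = sprintf("%.3f", full$CFI), RMSEA = sprintf("%.2f", full$RMSEA),
    SRMR = sprintf("%.2f", full$SRMR), AIC = sprintf("%.2f", full$AIC),
    stringsAsFactors = FALSE)
  utils::write.table(disp, file = file, sep = if (format == "tsv") "\t" else ",",
                     quote = FALSE, row.names = FALSE)
  invisible(full)
}
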