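#' Bundle sample moments for covariance-structure fitting
#'
#' Holds the sample covariance (or correlation) matrix, the variable names and
#' the sample size, plus optionally the raw rectangular data from which the
#' matrix was computed (required only for Satorra-Bentler robust scaling,
#' which needs fourth-order moments).
#'
#' @param S p x p symmetric covariance or correlation matrix. May be omitted
#'   when `raw` is supplied, in which case it is computed from `raw`.
#' @param n Sample size. Taken from `nrow(raw)` when omitted and raw data are
#'   present.
#' @param raw Optional n x p data frame or matrix of raw observations.
#' @param is_correlation Flag; detected automatically (unit diagonal) when
#'   missing.
#' @param divisor Divisor convention used when `S` is computed from `raw`:
#'   `"unbiased"` (n - 1, the default) or `"ml"` (n). When both `S` and `raw`
#'   are supplied, the covariance of `raw` under this convention must
#'   reproduce `S` to 1e-10.
#'
#' @return An object of class `fl_moments` with elements `S`, `names`, `n`,
#'   `raw`, `is_correlation`, `divisor`.
#' @examples
#' d <- generate_wmc_data(population_model(), n = 100, seed = 1)
#' m <- sample_moments(raw = d)
#' m$n
#' @export
sample_moments <- function(S = NULL, n = NULL, raw = NULL,
                           is_correlation = NULL,
                           divisor = c("unbiased", "ml")) {
  divisor <- match.arg(divisor)
  if (!is.null(raw)) {
    raw <- as.matrix(raw)
    if (!is.numeric(raw)) stop("`raw` must be numeric", call. = FALSE)
    if (is.null(n)) n <- nrow(raw)
    Sr <- .cov_divisor(raw, divisor)
    if (is.null(S)) S <- Sr
    else if (max(abs(as.matrix(S) - Sr)) > 1e-10)
      stop("covariance of `raw` (divisor ", divisor,
           ") does not reproduce `S` within 1e-10", call. = FALSE)
  }
  if (is.null(S)) stop("supply `S` or `raw`", call. = FALSE)
  S <- as.matrix(S)
  p <- nrow(S)
  if (ncol(S) != p || max(abs(S - t(S))) > 1e-8)
    stop("`S` must be square and symmetric", call. = FALSE)
  S <- (S + t(S)) / 2
  if (is.null(n) || n < 2) stop("a positive sample size `n` is required",
                                call. = FALSE)
  if (is.null(rownames(S))) {
    nm <- if (!is.null(raw) && !is.null(colnames(raw))) colnames(raw)
          else paste0("V", seq_len(p))
    dimnames(S) <- list(nm, nm)
  }
  if (is.null(is_correlation))
    is_correlation <- all(abs(diag(S) - 1) < 1e-8)

  structure(list(S = S, names = rownames(S), n = as.integer(n),
                 raw = raw, is_correlation = isTRUE(is_correlation),
                 divisor = divisor),
            class = "fl_moments")
}

.cov_divisor <- function(x, divisor) {
  S <- stats::cov(x)
  if (divisor == "ml") S <- S * (nrow(x) - 1) / nrow(x)
  S
}

#' @export
print.fl_moments <- function(x, ...) {
  cat("<fl_moments> ", length(x$names), " variables, n = ", x$n,
      if (x$is_correlation) " (correlation matrix)" else "",
      if (!is.null(x$raw)) ", raw data attached" else "", "\n", sep = "")
  invisible(x)
}

#' Read a labelled covariance/correlation matrix from CSV
#'
#' Expects a square matrix with a header row and the variable labels in the
#' first column.
#'
#' @param file Path to the CSV file.
#' @param n Sample size the matrix is based on.
#' @param ... Passed to [sample_moments()].
#' @return An `fl_moments` object.
#' @export
read_moments_csv <- function(file, n, ...) {
  d <- utils::read.csv(file, check.names = FALSE)
  S <- as.matrix(d[, -1, drop = FALSE])
  rownames(S) <- d[[1]]
  sample_moments(S = S, n = n, ...)
}

#' Read raw rectangular data from a delimited text file
#'
#' @param file Path to a CSV/TSV file with a header row.
#' @param sep Field separator; `","` by default, use `"\t"` for TSV.
#' @param ... Passed to [sample_moments()].
#' @return An `fl_moments` object with raw data attached.
#' @export
read_raw_csv <- function(file, sep = ",", ...) {
  d <- utils::read.table(file, header = TRUE, sep = sep, check.names = FALSE)
  sample_moments(raw = as.matrix(d), ...)
}
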