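#' Construct a loading course
#'
#' A loading course is the ordered pattern of fixed unstandardized factor
#' loadings across the conditions of a repeated-measures task. It encodes a
#' hypothesis about how a latent process scales with task demand: a constant
#' course (all loadings 1) for processes untouched by the manipulation, and an
#' increasing or inverted-u course for the manipulated process.
#'
#' The named courses reproduce, at two-decimal precision, the series used in
#' five-condition working-memory designs:
#' \describe{
#'   \item{constant}{1, 1, 1, 1, 1}
#'   \item{linear}{.1, .2, .3, .4, .5 (k/10 for condition k)}
#'   \item{quadratic}{.01, .04, .09, .16, .25 (the linear course squared)}
#'   \item{logarithmic}{.30, .48, .60, .70, .78 (log10(k + 1), i.e. the
#'     logarithm of the memory set size when set sizes run 2..6)}
#'   \item{inverted_u}{.36, .80, .99, .94, .64 (f(x) = (-x^2 + 100)/100 at
#'     x = -8, -4.5, -1, 2.5, 6)}
#' }
#' Named courses are rounded to 2 decimals so that model fits are reproducible
#' against the printed series; `custom` courses are returned unrounded.
#'
#' @param name One of `"constant"`, `"linear"`, `"quadratic"`,
#'   `"logarithmic"`, `"inverted_u"`, `"custom"`.
#' @param n_conditions Number of task conditions (>= 2). The printed series
#'   correspond to `n_conditions = 5`.
#' @param x For `inverted_u`, the x-values fed to f(x) = (-x^2 + 100)/100;
#'   must lie strictly inside (-10, 10) so that all loadings are positive.
#'   Defaults to c(-8, -4.5, -1, 2.5, 6) when `n_conditions == 5`.
#' @param values For `custom`, the loading vector itself.
#'
#' @return An object of class `loading_course`: a named numeric vector with
#'   attribute `course` giving the label.
#' @examples
#' loading_course("inverted_u")
#' loading_course("custom", values = c(0.2, 0.9, 0.4, 0.1, 0.05))
#' @export
loading_course <- function(name = c("constant", "linear", "quadratic",
                                    "logarithmic", "inverted_u", "custom"),
                           n_conditions = 5L, x = NULL, values = NULL) {
  name <- match.arg(name)
  n_conditions <- as.integer(n_conditions)
  if (n_conditions < 2L)
    stop("a loading course needs at least 2 conditions", call. = FALSE)

  v <- switch(name,
    constant = rep(1, n_conditions),
    linear = seq_len(n_conditions) / 10,
    quadratic = (seq_len(n_conditions) / 10)^2,
    logarithmic = log10(seq_len(n_conditions) + 1),
    inverted_u = {
      if (is.null(x)) {
        if (n_conditions != 5L)
          stop("default inverted_u x-values exist only for 5 conditions; ",
               "supply `x`", call. = FALSE)
        x <- c(-8, -4.5, -1, 2.5, 6)
      }
      if (length(x) != n_conditions)
        stop("`x` must have length n_conditions", call. = FALSE)
      if (any(abs(x) >= 10))
        stop("inverted_u x-values must lie in (-10, 10); ",
             "f(x) = (-x^2 + 100)/100 would be nonpositive", call. = FALSE)
      (-x^2 + 100) / 100
    },
    custom = {
      if (is.null(values))
        stop("custom course requires `values`", call. = FALSE)
      if (length(values) != n_conditions)
        stop("`values` must have length n_conditions", call. = FALSE)
      as.numeric(values)
    })

  if (name != "custom") v <- round(v, 2)
  if (any(!is.finite(v)))
    stop("loading course contains non-finite values", call. = FALSE)
  if (name == "custom" && .is_proportional(v, rep(1, n_conditions)))
    stop("custom course is proportional to the constant course; ",
         "the two latents would not be separable", call. = FALSE)

  names(v) <- paste0("cond", seq_len(n_conditions))
  structure(v, course = name, class = c("loading_course", "numeric"))
}

#' @export
print.loading_course <- function(x, ...) {
  cat("<loading_course> ", attr(x, "course"), ": ",
      paste(format(unclass(x)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# proportionality up to sign, with tolerance
.is_proportional <- function(a, b, tol = 1e-10) {
  if (length(a) != length(b)) return(FALSE)
  M <- cbind(as.numeric(a), as.numeric(b))
  qr(M, tol = tol)$rank < 2L
}
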