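#' Specify a fixed-links / CFA covariance-structure model
#'
#' A model specification holds the measurement and structural pattern of a
#' latent-variable model in the all-latent formulation
#' \deqn{\Sigma(\theta) = \Lambda (I - B)^{-1} \Psi (I - B)^{-T} \Lambda^T + \Theta,}
#' where \eqn{\Lambda} are factor loadings, \eqn{B} directed structural paths
#' among latents, \eqn{\Psi} latent (co)variances / disturbances and
#' \eqn{\Theta} diagonal residual variances. Each entry is either fixed to a
#' numeric value or free; free entries are written `NA`.
#'
#' Identification follows the two scaling conventions of the model family:
#' traditional CFA fixes a latent variance (usually to 1) and frees the
#' loadings, while fixed-links scaling fixes the loadings to a
#' [loading_course()] and frees the latent variance. Every latent must be
#' identified one way or the other.
#'
#' @param lambda p x m numeric matrix of loadings; `NA` = free. Row names are
#'   the manifest variable names, column names the latent names.
#' @param psi m x m symmetric matrix of latent variances/covariances
#'   (disturbance variances for endogenous latents); `NA` = free, `0` = fixed
#'   zero. Defaults to free diagonal, zero off-diagonal.
#' @param beta m x m matrix of directed paths (rows = outcome latent,
#'   columns = predictor); `NA` = free, `0` = no path. Must be acyclic.
#'   Defaults to no structural paths.
#' @param theta length-p vector of residual variances; `NA` = free (the
#'   default).
#'
#' @return An object of class `fl_spec`.
#' @seealso [validate_spec()], [build_wmc_model()], [fl_fit()]
#' @examples
#' g <- loading_course("inverted_u")
#' lam <- cbind(constant = rep(1, 5), dynamic = as.numeric(g))
#' rownames(lam) <- paste0("Cond", 1:5)
#' model_spec(lam)
#' @export
model_spec <- function(lambda, psi = NULL, beta = NULL, theta = NULL) {
  lambda <- as.matrix(lambda)
  p <- nrow(lambda); m <- ncol(lambda)
  if (is.null(rownames(lambda))) rownames(lambda) <- paste0("V", seq_len(p))
  if (is.null(colnames(lambda))) colnames(lambda) <- paste0("F", seq_len(m))
  manifest <- rownames(lambda); latents <- colnames(lambda)

  if (is.null(psi)) {
    psi <- matrix(0, m, m); diag(psi) <- NA_real_
  }
  psi <- as.matrix(psi)
  dimnames(psi) <- list(latents, latents)
  if (!isTRUE(all.equal(is.na(psi), t(is.na(psi)))) ||
      !isTRUE(all.equal(psi[!is.na(psi)], t(psi)[!is.na(t(psi))])))
    stop("`psi` must be symmetric in both pattern and fixed values",
         call. = FALSE)

  if (is.null(beta)) beta <- matrix(0, m, m)
  beta <- as.matrix(beta)
  dimnames(beta) <- list(latents, latents)
  if (any(is.na(diag(beta))) || any(diag(beta) != 0))
    stop("`beta` must have a zero diagonal (no self-loops)", call. = FALSE)

  if (is.null(theta)) theta <- rep(NA_real_, p)
  theta <- as.numeric(theta)
  if (length(theta) != p) stop("`theta` must have length nrow(lambda)",
                               call. = FALSE)
  names(theta) <- manifest

  structure(
    list(manifest = manifest, latents = latents,
         lambda = lambda, psi = psi, beta = beta, theta = theta),
    class = "fl_spec")
}

#' Names of the free parameters of a model specification
#'
#' Parameters are ordered: loadings (column-major within \eqn{\Lambda}), latent
#' (co)variances (lower triangle of \eqn{\Psi} including the diagonal),
#' structural paths, residual variances. This ordering defines the layout of
#' the parameter vector used by [implied_covariance()] and [fl_fit()].
#'
#' @param spec An `fl_spec`.
#' @return Character vector of parameter labels.
#' @export
free_params <- function(spec) {
  stopifnot(inherits(spec, "fl_spec"))
  out <- character(0)
  lam <- spec$lambda
  for (j in seq_along(spec$latents)) for (i in seq_along(spec$manifest))
    if (is.na(lam[i, j]))
      out <- c(out, sprintf("lambda[%s~%s]", spec$manifest[i], spec$latents[j]))
  ps <- spec$psi
  for (j in seq_along(spec$latents)) for (i in j:length(spec$latents))
    if (is.na(ps[i, j]))
      out <- c(out, if (i == j) sprintf("psi[%s]", spec$latents[i])
               else sprintf("psi[%s,%s]", spec$latents[i], spec$latents[j]))
  bt <- spec$beta
  for (j in seq_along(spec$latents)) for (i in seq_along(spec$latents))
    if (is.na(bt[i, j]))
      out <- c(out, sprintf("beta[%s~%s]", spec$latents[i], spec$latents[j]))
  for (i in seq_along(spec$manifest))
    if (is.na(spec$theta[i]))
      out <- c(out, sprintf("theta[%s]", spec$manifest[i]))
  out
}

#' Model degrees of freedom
#'
#' `p(p+1)/2` non-duplicated covariance moments minus the number of free
#' parameters.
#'
#' @param spec An `fl_spec`.
#' @return Integer degrees of freedom (may be negative for over-parameterized
#'   specifications; [validate_spec()] flags that case).
#' @export
spec_df <- function(spec) {
  p <- length(spec$manifest)
  as.integer(p * (p + 1) / 2 - length(free_params(spec)))
}

#' Validate a model specification
#'
#' Checks the structural sanity of an `fl_spec`: every latent is identified
#' (fixed variance or at least one fixed nonzero loading), the structural
#' paths form a directed acyclic graph, degrees of freedom are nonnegative,
#' and no two latents load on the same manifests with proportional fully-fixed
#' loading columns (which would make them inseparable).
#'
#' @param spec An `fl_spec`.
#' @return A list of class `fl_validation` with elements `pass` (logical) and
#'   `messages` (character, one per failed check; empty when `pass`).
#' @examples
#' validate_spec(build_wmc_model(5))
#' @export
validate_spec <- function(spec) {
  stopifnot(inherits(spec, "fl_spec"))
  msgs <- character(0)
  m <- length(spec$latents)

  for (j in seq_len(m)) {
    var_fixed <- !is.na(spec$psi[j, j])
    load_fixed <- any(!is.na(spec$lambda[, j]) & spec$lambda[, j] != 0)
    if (!var_fixed && !load_fixed)
      msgs <- c(msgs, sprintf(
        "latent '%s' is not identified: fix its variance or at least one nonzero loading",
        spec$latents[j]))
  }

  # acyclicity: the reachability closure of beta must have a zero diagonal
  pat <- ifelse(is.na(spec$beta) | spec$beta != 0, 1, 0)
  reach <- pat; pw <- pat
  for (k in seq_len(m)) {
    pw <- (pw %*% pat > 0) + 0
    reach <- ((reach + pw) > 0) + 0
  }
  if (m > 0 && any(diag(reach) > 0))
    msgs <- c(msgs, "structural paths contain a cycle")

  if (spec_df(spec) < 0L)
    msgs <- c(msgs, sprintf(
      "negative degrees of freedom: %d free parameters exceed %d moments",
      length(free_params(spec)),
      length(spec$manifest) * (length(spec$manifest) + 1) / 2))

  if (m >= 2) {
    for (j1 in seq_len(m - 1)) for (j2 in (j1 + 1):m) {
      c1 <- spec$lambda[, j1]; c2 <- spec$lambda[, j2]
      if (!anyNA(c1) && !anyNA(c2) && any(c1 != 0) && any(c2 != 0) &&
          .is_proportional(c1, c2))
        msgs <- c(msgs, sprintf(
          "latents '%s' and '%s' have proportional fixed loading courses and are not separable",
          spec$latents[j1], spec$latents[j2]))
    }
  }

  structure(list(pass = length(msgs) == 0L, messages = msgs),
            class = "fl_validation")
}

#' @export
print.fl_validation <- function(x, ...) {
  cat(if (x$pass) "PASS: specification is valid\n" else "FAIL:\n")
  for (msg in x$messages) cat("  - ", msg, "\n", sep = "")
  invisible(x)
}

#' @export
print.fl_spec <- function(x, ...) {
  cat("<fl_spec> ", length(x$manifest), " manifest, ",
      length(x$latents), " latent (",
      paste(x$latents, collapse = ", "), ")\n", sep = "")
  cat("  free parameters: ", length(free_params(x)),
      "; df = ", spec_df(x), "\n", sep = "")
  invisible(x)
}

# default variable names used across the study models and fixture
.wmc_names <- function() paste0("Cond", 1:5)
.reasoning_names <- function() c("Figural", "Numerical", "Verbal")

#' Build the working-memory study models
#'
#' Constructs the model family contrasted in the bundled five-condition
#' working-memory / reasoning study:
#' \describe{
#'   \item{1, `"congeneric"`}{traditional one-factor CFA over the five task
#'     conditions: free loadings, latent variance fixed to 1 (df = 5).}
#'   \item{2--5, `"constant_linear"` .. `"constant_inverted_u"`}{fixed-links
#'     models with two uncorrelated latents over the same five conditions: a
#'     constant latent (loadings fixed to 1) plus a dynamic latent whose
#'     loadings are fixed to the linear, quadratic, logarithmic or inverted-u
#'     [loading_course()]; both latent variances free (df = 8).}
#'   \item{`"structural_cfa"`}{the congeneric WMC factor predicting a
#'     Reasoning factor measured by three composites (first composite loading
#'     fixed to 1, disturbance free; df = 19).}
#'   \item{`"structural_fixedlinks"`}{the constant and dynamic (inverted-u)
#'     latents, mutually uncorrelated, each predicting Reasoning (df = 21).}
#' }
#'
#' @param model Integer 1--5 or one of the names above (dynamic-course
#'   shorthands `"linear"`, `"quadratic"`, `"logarithmic"`, `"inverted_u"`
#'   are accepted for models 2--5).
#' @return An `fl_spec`.
#' @examples
#' build_wmc_model("congeneric")
#' build_wmc_model(5)
#' build_wmc_model("structural_fixedlinks")
#' @export
build_wmc_model <- function(model) {
  key <- if (is.numeric(model)) as.character(as.integer(model))
         else tolower(as.character(model))
  course <- switch(key,
    "2" = , "linear" = , "constant_linear" = "linear",
    "3" = , "quadratic" = , "constant_quadratic" = "quadratic",
    "4" = , "logarithmic" = , "constant_logarithmic" = "logarithmic",
    "5" = , "inverted_u" = , "constant_inverted_u" = "inverted_u",
    NULL)

  if (identical(key, "1") || identical(key, "congeneric")) {
    lam <- matrix(NA_real_, 5, 1,
                  dimnames = list(.wmc_names(), "wmc"))
    psi <- matrix(1, 1, 1)
    return(model_spec(lam, psi = psi))
  }

  if (!is.null(course)) {
    g <- loading_course(course, 5L)
    lam <- cbind(constant = rep(1, 5), dynamic = as.numeric(g))
    rownames(lam) <- .wmc_names()
    # uncorrelated latents, both variances free
    psi <- matrix(c(NA, 0, 0, NA), 2, 2)
    return(model_spec(lam, psi = psi))
  }

  if (identical(key, "structural_cfa")) {
    manifest <- c(.reasoning_names(), .wmc_names())
    lam <- matrix(0, 8, 2, dimnames = list(manifest, c("reasoning", "wmc")))
    lam[1, 1] <- 1                      # scale Reasoning by first composite
    lam[2:3, 1] <- NA
    lam[4:8, 2] <- NA
    psi <- matrix(c(NA, 0, 0, 1), 2, 2) # Reasoning disturbance free; wmc var 1
    beta <- matrix(0, 2, 2)
    beta[1, 2] <- NA                    # reasoning ~ wmc
    return(model_spec(lam, psi = psi, beta = beta))
  }

  if (identical(key, "structural_fixedlinks")) {
    manifest <- c(.reasoning_names(), .wmc_names())
    g <- loading_course("inverted_u", 5L)
    lam <- matrix(0, 8, 3,
                  dimnames = list(manifest, c("reasoning", "constant", "dynamic")))
    lam[1, 1] <- 1
    lam[2:3, 1] <- NA
    lam[4:8, 2] <- 1
    lam[4:8, 3] <- as.numeric(g)
    psi <- matrix(0, 3, 3)              # uncorrelated latents
    diag(psi) <- NA_real_               # disturbance + two latent variances free
    beta <- matrix(0, 3, 3)
    beta[1, 2] <- NA                    # reasoning ~ constant
    beta[1, 3] <- NA                    # reasoning ~ dynamic
    return(model_spec(lam, psi = psi, beta = beta))
  }

  stop("unknown model identifier: ", model, call. = FALSE)
}
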