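#' z-test for a freely estimated latent variance
#'
#' In fixed-links scaling the latent variance is the quantity of interest: a
#' latent only reflects a psychologically meaningful process when its variance
#' is statistically significant. The test is `z = psi_hat / SE(psi_hat)` with
#' a two-sided normal p-value.
#'
#' @param fit An `fl_fit`.
#' @param latent Name of the latent whose variance was freely estimated.
#' @return List with `estimate`, `se`, `z`, `p`.
#' @examples
#' f <- fl_fit(build_wmc_model(5), wmc_study_moments())
#' variance_z_test(f, "dynamic")
#' @export
variance_z_test <- function(fit, latent) {
  stopifnot(inherits(fit, "fl_fit"))
  lab <- sprintf("psi[%s]", latent)
  if (!lab %in% names(fit$theta_hat))
    stop("latent variance of '", latent,
         "' is not a free parameter of this model", call. = FALSE)
  est <- fit$theta_hat[[lab]]
  se <- fit$se[[lab]]
  z <- if (is.na(se) || se == 0) {
    if (est == 0) 0 else NA_real_
  } else est / se
  p <- if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z))
  list(latent = latent, estimate = est, se = se, z = z, p = p)
}

# standardized structural coefficient outcome ~ predictor as a function of
# the free-parameter vector (used for delta-method variances)
.std_path_fun <- function(spec, outcome, predictor) {
  io <- match(outcome, spec$latents)
  ip <- match(predictor, spec$latents)
  if (is.na(io) || is.na(ip))
    stop("unknown latent in structural path", call. = FALSE)
  function(theta) {
    mats <- .fill_spec(spec, theta)
    m <- length(spec$latents)
    IBi <- solve(diag(m) - mats$beta)
    Veta <- IBi %*% mats$psi %*% t(IBi)
    mats$beta[io, ip] * sqrt(Veta[ip, ip] / Veta[io, io])
  }
}

# numerical gradient, central differences
.num_grad <- function(f, x, h = NULL) {
  if (is.null(h)) h <- 1e-6 * (abs(x) + 1e-4)
  g <- numeric(length(x))
  for (i in seq_along(x)) {
    e <- numeric(length(x)); e[i] <- h[i]
    g[i] <- (f(x + e) - f(x - e)) / (2 * h[i])
  }
  g
}

#' Wald test of a constraint on a standardized structural path
#'
#' Tests whether the standardized coefficient of `outcome ~ predictor` differs
#' from a hypothesized `value`. The default (`method = "delta"`) refers
#' \eqn{W = (\hat\beta_{std} - value)^2 / \mathrm{Var}(\hat\beta_{std})} to
#' \eqn{\chi^2(1)}, with the variance of the standardized coefficient obtained
#' by the delta method from the fitted parameter covariance.
#' `method = "refit"` instead refits the model with the standardized path
#' constrained to `value` (by penalized optimization) and reports the
#' fit-difference statistic `T_constrained - T`.
#'
#' @param fit An `fl_fit` of a model containing the path.
#' @param path Character `"outcome~predictor"` naming the structural path.
#' @param value Constraint value for the standardized coefficient; values
#'   outside (-1, 1) trigger a warning.
#' @param method `"delta"` (default) or `"refit"`.
#' @return List with `W` (chi-square statistic, 1 df), `p`, `estimate` (the
#'   unconstrained standardized path), `value`, `method`.
#' @examples
#' f <- fl_fit(build_wmc_model("structural_fixedlinks"), wmc_study_moments())
#' wald_constraint_test(f, "reasoning~dynamic", 0.68)
#' @export
wald_constraint_test <- function(fit, path, value,
                                 method = c("delta", "refit")) {
  stopifnot(inherits(fit, "fl_fit"))
  method <- match.arg(method)
  parts <- strsplit(path, "~", fixed = TRUE)[[1]]
  if (length(parts) != 2)
    stop("`path` must have the form \"outcome~predictor\"", call. = FALSE)
  lab <- sprintf("beta[%s~%s]", parts[1], parts[2])
  if (!lab %in% names(fit$theta_hat))
    stop("structural path '", path, "' is not a free parameter", call. = FALSE)
  if (abs(value) >= 1)
    warning("constraint value outside (-1, 1) for a standardized path",
            call. = FALSE)

  spec <- fit$spec
  bfun <- .std_path_fun(spec, parts[1], parts[2])
  b_hat <- bfun(fit$theta_hat)

  if (method == "delta") {
    g <- .num_grad(bfun, fit$theta_hat)
    v <- drop(t(g) %*% fit$vcov %*% g)
    if (!is.finite(v) || v <= 0)
      stop("delta-method variance of the standardized path is not positive",
           call. = FALSE)
    W <- (b_hat - value)^2 / v
  } else {
    mult <- if (fit$multiplier == "n-1") fit$n - 1 else fit$n
    S <- fit$S
    ldS <- .logdet_chol(S, "sample matrix `S`")$logdet
    fn <- .fl_objective(spec, S, ldS)
    par <- fit$theta_hat
    for (w in c(1e3, 1e5, 1e7)) {
      pen <- function(t) {
        b <- suppressWarnings(bfun(t))
        if (!is.finite(b)) return(1e10)
        fn(t) + w * (b - value)^2
      }
      par <- stats::optim(par, pen, method = "BFGS",
                          control = list(reltol = 1e-12, maxit = 5000,
                                         ndeps = rep(1e-7, length(par))))$par
    }
    W <- max(mult * (fn(par) - fit$F_min), 0)
  }
  list(W = W, df = 1L, p = stats::pchisq(W, 1, lower.tail = FALSE),
       estimate = b_hat, value = value, method = method)
}
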