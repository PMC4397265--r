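#' Model-implied covariance matrix
#'
#' Evaluates \eqn{\Sigma(\theta) = \Lambda (I - B)^{-1} \Psi (I - B)^{-T}
#' \Lambda^T + \Theta} for a model specification at a given free-parameter
#' vector, in the ordering defined by [free_params()].
#'
#' @param spec An `fl_spec`.
#' @param theta Numeric vector supplying a value for every free parameter
#'   (may be empty for fully fixed specifications).
#' @return Symmetric p x p matrix with the manifest variable names.
#' @examples
#' sp <- build_wmc_model(5)
#' implied_covariance(sp, c(0.012, 0.012, rep(0.02, 5)))
#' @export
implied_covariance <- function(spec, theta) {
  mats <- .fill_spec(spec, theta)
  .implied_from_mats(mats)
}

.implied_from_mats <- function(mats) {
  m <- ncol(mats$lambda)
  IB <- diag(m) - mats$beta
  IBi <- tryCatch(solve(IB), error = function(e)
    stop("(I - B) is singular: structural paths form a cycle", call. = FALSE))
  Veta <- IBi %*% mats$psi %*% t(IBi)
  Sigma <- mats$lambda %*% Veta %*% t(mats$lambda)
  diag(Sigma) <- diag(Sigma) + mats$theta
  Sigma <- (Sigma + t(Sigma)) / 2
  dimnames(Sigma) <- list(rownames(mats$lambda), rownames(mats$lambda))
  Sigma
}

# substitute free-parameter values into the pattern matrices;
# ordering must mirror free_params()
.fill_spec <- function(spec, theta) {
  nfree <- length(free_params(spec))
  if (length(theta) != nfree)
    stop("`theta` must supply ", nfree, " free parameter values, got ",
         length(theta), call. = FALSE)
  k <- 0L
  lam <- spec$lambda
  idx <- which(is.na(lam))          # column-major, matches free_params
  if (length(idx)) { lam[idx] <- theta[k + seq_along(idx)]; k <- k + length(idx) }
  ps <- spec$psi
  m <- length(spec$latents)
  for (j in seq_len(m)) for (i in j:m)
    if (is.na(ps[i, j])) { k <- k + 1L; ps[i, j] <- ps[j, i] <- theta[k] }
  bt <- spec$beta
  idx <- which(is.na(bt))
  if (length(idx)) { bt[idx] <- theta[k + seq_along(idx)]; k <- k + length(idx) }
  th <- spec$theta
  idx <- which(is.na(th))
  if (length(idx)) { th[idx] <- theta[k + seq_along(idx)]; k <- k + length(idx) }
  list(lambda = lam, psi = ps, beta = bt, theta = th)
}

.logdet_chol <- function(M, label) {
  ch <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(ch))
    stop(label, " is not positive definite", call. = FALSE)
  list(logdet = 2 * sum(log(diag(ch))), chol = ch)
}

#' Maximum-likelihood discrepancy between two covariance matrices
#'
#' The normal-theory ML fit function
#' \deqn{F_{ML} = \ln|\Sigma| - \ln|S| + \mathrm{tr}(S\Sigma^{-1}) - p,}
#' nonnegative and exactly zero iff \eqn{\Sigma = S}. The test statistic of a
#' fitted model is a multiple of this quantity at its minimum.
#'
#' @param S Sample covariance matrix (symmetric positive definite).
#' @param Sigma Model-implied covariance matrix (same dimension).
#' @return Nonnegative scalar.
#' @examples
#' ml_discrepancy(diag(2), diag(2))       # 0
#' ml_discrepancy(diag(2), diag(2, 2))    # 2*log(2) - 1
#' @export
ml_discrepancy <- function(S, Sigma) {
  S <- as.matrix(S); Sigma <- as.matrix(Sigma)
  p <- nrow(S)
  if (nrow(Sigma) != p || ncol(S) != p || ncol(Sigma) != p)
    stop("`S` and `Sigma` must be square matrices of the same dimension",
         call. = FALSE)
  ldS <- .logdet_chol(S, "sample matrix `S`")
  ldSig <- .logdet_chol(Sigma, "implied matrix `Sigma`")
  tr <- sum(diag(chol2inv(ldSig$chol) %*% S))
  max(ldSig$logdet - ldS$logdet + tr - p, 0)
}

# objective used inside optimization: finite penalty outside the PD region
.fl_objective <- function(spec, S, logdetS) {
  p <- nrow(S)
  function(theta) {
    Sigma <- tryCatch(implied_covariance(spec, theta), error = function(e) NULL)
    if (is.null(Sigma) || any(!is.finite(Sigma))) return(1e10)
    ch <- tryCatch(chol(Sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10)
    2 * sum(log(diag(ch))) - logdetS + sum(diag(chol2inv(ch) %*% S)) - p
  }
}

# starting values: free loadings 0.5*sd(indicator), variances half the
# observed variance, structural paths and latent covariances 0
.start_values <- function(spec, S) {
  labs <- free_params(spec)
  sdev <- sqrt(diag(S))
  mean_var <- mean(diag(S))
  vapply(labs, function(lb) {
    if (startsWith(lb, "lambda[")) {
      man <- sub("lambda\\[(.+)~.+\\]", "\\1", lb)
      0.5 * sdev[[man]]
    } else if (startsWith(lb, "psi[")) {
      if (grepl(",", lb)) 0 else 0.5 * mean_var
    } else if (startsWith(lb, "beta[")) {
      0
    } else {                       # theta[...]
      man <- sub("theta\\[(.+)\\]", "\\1", lb)
      0.5 * sdev[[man]]^2
    }
  }, numeric(1))
}

#' Fit a model specification to sample moments by maximum likelihood
#'
#' Minimizes the [ml_discrepancy()] between the sample matrix and the
#' model-implied covariance over the free parameters with a quasi-Newton
#' (BFGS) optimizer using numerical gradients. The test statistic is
#' `T = (n - 1) * F_min` by default (the multiplier is configurable, and at
#' typical sample sizes the n vs n-1 choice is within printing precision).
#' Standard errors come from the inverse of the numerically evaluated observed
#' information of `multiplier * F / 2`. The standardized solution is computed
#' from the implied latent and manifest variances; the sign of each latent is
#' resolved by making its first nonzero loading nonnegative.
#'
#' Negative variance estimates (Heywood cases) are permitted — the
#' optimization is unbounded — and flagged via `heywood`, mirroring common
#' SEM-software behaviour so that inadmissible solutions stay visible.
#'
#' @param spec An `fl_spec`; must pass [validate_spec()].
#' @param moments An `fl_moments`.
#' @param multiplier `"n-1"` (default) or `"n"`: multiplies `F_min` to form
#'   the test statistic.
#' @param robust If `TRUE` and raw data are attached, also computes the
#'   Satorra-Bentler scaled statistic (see [satorra_bentler_scale()]).
#' @param se Compute standard errors (default `TRUE`).
#' @param start Optional named starting values overriding the defaults.
#' @param control Optimizer control: `reltol` (default 1e-10, tightened until
#'   the change in F is below 1e-8), `maxit` (default 5000 evaluations).
#'
#' @return An object of class `fl_fit` with elements `theta_hat`, `se`,
#'   `vcov`, `standardized`, `F_min`, `T`, `T_scaled`, `c`, `df`, `n`,
#'   `converged`, `heywood`, `Sigma_hat`, `spec`, `moments`.
#' @examples
#' m <- wmc_study_moments()
#' f <- fl_fit(build_wmc_model(1), m)
#' f$standardized$lambda
#' @export
fl_fit <- function(spec, moments, multiplier = c("n-1", "n"),
                   robust = FALSE, se = TRUE, start = NULL,
                   control = list()) {
  stopifnot(inherits(spec, "fl_spec"), inherits(moments, "fl_moments"))
  v <- validate_spec(spec)
  if (!v$pass)
    stop("invalid model specification:\n  ",
         paste(v$messages, collapse = "\n  "), call. = FALSE)
  multiplier <- match.arg(multiplier)
  if (!all(spec$manifest %in% moments$names))
    stop("sample moments do not cover all manifest variables of the model: ",
         paste(setdiff(spec$manifest, moments$names), collapse = ", "),
         call. = FALSE)
  S <- moments$S[spec$manifest, spec$manifest, drop = FALSE]
  n <- moments$n
  mult <- if (multiplier == "n-1") n - 1 else n
  labs <- free_params(spec)
  q <- length(labs)
  df <- spec_df(spec)

  ldS <- .logdet_chol(S, "sample matrix `S`")$logdet
  fn <- .fl_objective(spec, S, ldS)

  reltol <- control$reltol %||% 1e-10
  maxit <- control$maxit %||% 5000

  if (q == 0) {
    par <- numeric(0); F_min <- fn(par); converged <- TRUE
  } else {
    par0 <- .start_values(spec, S)
    if (!is.null(start)) par0[names(start)] <- start
    # ndeps: fine finite-difference steps; optim's 1e-3 default caps accuracy
    ctl <- list(reltol = reltol, maxit = maxit, ndeps = rep(1e-7, q))
    opt <- stats::optim(par0, fn, method = "BFGS", control = ctl)
    # polish: restart until F stabilizes below 1e-8
    for (i in 1:3) {
      opt2 <- stats::optim(opt$par, fn, method = "BFGS", control = ctl)
      if (opt$value - opt2$value < 1e-8) { opt <- opt2; break }
      opt <- opt2
    }
    par <- opt$par
    F_min <- opt$value
    converged <- opt$convergence == 0 && F_min < 1e9
    if (!converged)
      warning("optimizer did not converge (code ", opt$convergence, ")",
              call. = FALSE)
  }

  mats <- .fill_spec(spec, par)
  flip <- .fix_signs(spec, mats)
  mats <- flip$mats
  par <- .extract_theta(spec, mats)
  names(par) <- labs

  Sigma_hat <- .implied_from_mats(mats)
  Tstat <- mult * F_min

  # observed information of (mult * F)/2
  se_vec <- rep(NA_real_, q); vc <- matrix(NA_real_, q, q)
  if (se && q > 0) {
    H <- tryCatch(stats::optimHess(par, function(t) mult * fn(t) / 2),
                  error = function(e) NULL)
    if (!is.null(H)) {
      vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, q, q))
      dv <- diag(vc)
      se_vec <- ifelse(is.finite(dv) & dv > 0, sqrt(pmax(dv, 0)), NA_real_)
    }
    dimnames(vc) <- list(labs, labs)
    names(se_vec) <- labs
  }

  heywood <- .has_heywood(spec, mats)
  if (heywood)
    warning("Heywood case: negative variance estimate(s); see $theta_hat",
            call. = FALSE)

  fit <- structure(
    list(theta_hat = par, se = se_vec, vcov = vc,
         standardized = .std_solution(spec, mats, Sigma_hat),
         F_min = F_min, T = Tstat, T_scaled = NULL, c = NULL,
         df = df, n = n, multiplier = multiplier,
         converged = converged, heywood = heywood,
         Sigma_hat = Sigma_hat, S = S, spec = spec, moments = moments),
    class = "fl_fit")

  if (robust) {
    sb <- satorra_bentler_scale(fit)
    fit$c <- sb$c
    fit$T_scaled <- sb$T_scaled
  }
  fit
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# make the first nonzero loading of each latent nonnegative by flipping the
# latent's sign; latents with any fixed nonzero loading have their orientation
# pinned by the fixed course and are never flipped
.fix_signs <- function(spec, mats) {
  m <- length(spec$latents)
  flipped <- logical(m)
  for (j in seq_len(m)) {
    fixed_nz <- !is.na(spec$lambda[, j]) & spec$lambda[, j] != 0
    if (any(fixed_nz)) next
    col <- mats$lambda[, j]
    nz <- which(col != 0)
    if (length(nz) && col[nz[1]] < 0) {
      mats$lambda[, j] <- -mats$lambda[, j]
      mats$beta[j, ] <- -mats$beta[j, ]
      mats$beta[, j] <- -mats$beta[, j]
      mats$psi[j, -j] <- -mats$psi[j, -j]
      mats$psi[-j, j] <- -mats$psi[-j, j]
      flipped[j] <- TRUE
    }
  }
  list(mats = mats, flipped = flipped)
}

# read the free-parameter vector back out of filled matrices
.extract_theta <- function(spec, mats) {
  out <- numeric(0)
  out <- c(out, mats$lambda[is.na(spec$lambda)])
  m <- length(spec$latents)
  for (j in seq_len(m)) for (i in j:m)
    if (is.na(spec$psi[i, j])) out <- c(out, mats$psi[i, j])
  out <- c(out, mats$beta[is.na(spec$beta)])
  c(out, mats$theta[is.na(spec$theta)])
}

.has_heywood <- function(spec, mats) {
  any(mats$theta[is.na(spec$theta)] < 0) ||
    any(diag(mats$psi)[is.na(diag(spec$psi))] < 0)
}

# standardized solution from the implied latent and manifest variances
.std_solution <- function(spec, mats, Sigma) {
  m <- length(spec$latents)
  IBi <- solve(diag(m) - mats$beta)
  Veta <- IBi %*% mats$psi %*% t(IBi)
  sd_eta <- sqrt(pmax(diag(Veta), 0))
  sd_y <- sqrt(diag(Sigma))
  lam_std <- sweep(sweep(mats$lambda, 2, sd_eta, "*"), 1, sd_y, "/")
  beta_std <- mats$beta * outer(1 / ifelse(sd_eta > 0, sd_eta, NA_real_),
                                sd_eta)
  theta_std <- mats$theta / diag(Sigma)
  psi_std <- diag(mats$psi) / ifelse(diag(Veta) > 0, diag(Veta), NA_real_)
  latent_cov <- Veta
  dimnames(lam_std) <- dimnames(spec$lambda)
  dimnames(beta_std) <- dimnames(spec$beta)
  names(theta_std) <- spec$manifest
  names(psi_std) <- names(sd_eta) <- spec$latents
  dimnames(latent_cov) <- list(spec$latents, spec$latents)
  list(lambda = lam_std, beta = beta_std, theta = theta_std,
       psi = psi_std, latent_sd = sd_eta, latent_cov = latent_cov)
}

#' @export
print.fl_fit <- function(x, digits = 3, ...) {
  cat("<fl_fit> ", paste(x$spec$latents, collapse = " + "),
      "; n = ", x$n, "\n", sep = "")
  cat(sprintf("  F_min = %.6f, T = %.3f, df = %d%s\n", x$F_min, x$T, x$df,
              if (!is.null(x$T_scaled))
                sprintf(" (scaled T = %.3f, c = %.3f)", x$T_scaled, x$c)
              else ""))
  if (!x$converged) cat("  ** optimizer did not converge **\n")
  if (x$heywood) cat("  ** Heywood case: negative variance estimate **\n")
  est <- data.frame(estimate = round(x$theta_hat, digits),
                    se = round(x$se, digits))
  print(est)
  invisible(x)
}

#' Extract parameter estimates from a fitted model
#'
#' @param object An `fl_fit`.
#' @param ... Unused.
#' @return Named numeric vector of free-parameter estimates.
#' @export
coef.fl_fit <- function(object, ...) object$theta_hat

#' @export
vcov.fl_fit <- function(object, ...) object$vcov
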