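# duplication matrix D_p: vec(M) = D %*% vech(M) for symmetric M
.duplication <- function(p) {
  pstar <- p * (p + 1) / 2
  D <- matrix(0, p * p, pstar)
  k <- 0L
  for (j in seq_len(p)) for (i in j:p) {
    k <- k + 1L
    D[(j - 1) * p + i, k] <- 1
    D[(i - 1) * p + j, k] <- 1
  }
  D
}

.vech <- function(M) M[lower.tri(M, diag = TRUE)]

# asymptotic covariance of sqrt(n) * (vech(S) - vech(Sigma)) from
# fourth-order sample moments (ADF / distribution-free Gamma)
.gamma_adf <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x); p <- ncol(x)
  xc <- scale(x, center = TRUE, scale = FALSE)
  Sml <- crossprod(xc) / n
  idx <- which(lower.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  pstar <- nrow(idx)
  # d[obs, k] = deviation products for element k = (i, j)
  dprod <- xc[, idx[, 1], drop = FALSE] * xc[, idx[, 2], drop = FALSE]
  s <- .vech(Sml)
  dprod <- sweep(dprod, 2, s, "-")
  crossprod(dprod) / n
}

#' Satorra-Bentler scaling of the test statistic
#'
#' Rescales the ML chi-square statistic for non-normality using fourth-order
#' sample moments. The scaling factor is `c = tr(U Gamma) / df`, where `Gamma`
#' is the distribution-free asymptotic covariance matrix of the sample
#' covariances and `U` is the normal-theory residual weight matrix evaluated
#' at the estimates; the scaled statistic is `T / c`. Under multivariate
#' normality `c` tends to 1; excess kurtosis inflates `T` and gives `c > 1`.
#' Point estimates are untouched — robustness enters only through the
#' statistic.
#'
#' @param fit An `fl_fit` whose `fl_moments` carry raw data.
#' @return List with `c` (scaling factor) and `T_scaled = T / c`.
#' @examples
#' d <- generate_wmc_data(population_model(), n = 300, seed = 7)
#' m <- sample_moments(raw = d[paste0("Cond", 1:5)])
#' f <- fl_fit(build_wmc_model(5), m)
#' satorra_bentler_scale(f)$c
#' @export
satorra_bentler_scale <- function(fit) {
  stopifnot(inherits(fit, "fl_fit"))
  raw <- fit$moments$raw
  if (is.null(raw))
    stop("Satorra-Bentler scaling needs raw data in the sample moments",
         call. = FALSE)
  if (!fit$converged)
    stop("model fit did not converge", call. = FALSE)
  if (fit$df <= 0)
    stop("scaling is undefined for a saturated model (df = 0)", call. = FALSE)
  raw <- as.matrix(raw)[, fit$spec$manifest, drop = FALSE]
  n <- nrow(raw); p <- ncol(raw)
  if (n < p * (p + 1) / 2)
    warning("n < p(p+1)/2: fourth-order moments may be unstable",
            call. = FALSE)

  Gamma <- .gamma_adf(raw)
  Sigma <- fit$Sigma_hat
  D <- .duplication(p)
  Dplus <- solve(crossprod(D), t(D))
  Gamma_NT <- 2 * Dplus %*% (Sigma %x% Sigma) %*% t(Dplus)
  W <- solve(Gamma_NT)

  # Delta = d vech(Sigma(theta)) / d theta, numerically
  th <- fit$theta_hat
  q <- length(th)
  Delta <- matrix(0, p * (p + 1) / 2, q)
  h <- 1e-6 * (abs(th) + 1e-4)
  for (i in seq_len(q)) {
    e <- numeric(q); e[i] <- h[i]
    Delta[, i] <- (.vech(implied_covariance(fit$spec, th + e)) -
                   .vech(implied_covariance(fit$spec, th - e))) / (2 * h[i])
  }
  WD <- W %*% Delta
  U <- W - WD %*% solve(t(Delta) %*% WD, t(WD))
  cfac <- sum(diag(U %*% Gamma)) / fit$df
  list(c = cfac, T_scaled = fit$T / cfac)
}
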