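#' Per-observation likelihood terms for the six model families
#'
#' The package models a non-negative count response (cigarettes smoked per
#' day) with one of three count families -- Poisson, negative binomial
#' (mean/dispersion NB2 form), Conway--Maxwell--Poisson -- optionally mixed
#' with a structural-zero (non-smoker) component:
#' \deqn{P(Y = y) = \phi\, 1\{y = 0\} + (1 - \phi) f(y \mid \theta).}
#' The zero part uses a logit link, \eqn{\log(\phi/(1-\phi)) = \xi = a^T\alpha + w},
#' and the count part a log link, \eqn{\log\lambda = \eta = b^T\beta + u},
#' where `w`, `u` are cluster (city) random intercepts.
#'
#' @param family one of `"poisson"`, `"negbin"`, `"cmp"`.
#' @param eta count-part linear predictor; the count rate is `exp(eta)`
#'   (the mean for Poisson/NB, the CMP rate \eqn{\lambda}).
#' @param dispersion `r` for negbin (variance \eqn{\mu + \mu^2/r}), `nu` for
#'   cmp; must be `NULL` for poisson.
#' @name count_families
NULL

FAMILIES <- c("poisson", "negbin", "cmp")

.check_family <- function(family, dispersion) {
  family <- match.arg(family, FAMILIES)
  if (family == "poisson") {
    if (!is.null(dispersion))
      stop("poisson has no dispersion parameter", call. = FALSE)
  } else if (is.null(dispersion) || dispersion <= 0) {
    stop(sprintf("family '%s' needs a positive dispersion", family),
         call. = FALSE)
  }
  family
}

#' @describeIn count_families Linear predictors for one observation:
#'   `xi = sum(a * alpha) + w`, `eta = sum(b * beta) + u`.
#' @param a,b covariate vectors (intercept first) for the zero and count part.
#' @param alpha,beta coefficient vectors.
#' @param w,u cluster random intercepts (0 when absent).
#' @export
linear_predictors <- function(a, alpha, b, beta, w = 0, u = 0) {
  if (length(a) != length(alpha) || length(b) != length(beta))
    stop("covariate/coefficient dimension mismatch", call. = FALSE)
  list(xi = sum(a * alpha) + w, eta = sum(b * beta) + u)
}

#' @describeIn count_families Count-part log pmf at `y` given linear
#'   predictor `eta`; vectorized over `y`/`eta`.
#' @param y non-negative integer count(s).
#' @export
count_logpmf <- function(y, eta, family, dispersion = NULL) {
  family <- .check_family(family, dispersion)
  if (any(y < 0) || any(y != floor(y)))
    stop("y must be non-negative integers", call. = FALSE)
  mu <- exp(eta)
  switch(family,
    poisson = dpois(y, mu, log = TRUE),
    negbin  = dnbinom(y, size = dispersion, mu = mu, log = TRUE),
    cmp     = dcmp(y, mu, dispersion, log = TRUE))
}

#' @describeIn count_families Zero-inflated observation log-likelihood:
#'   `log(phi + (1-phi) f(0))` at zero, `log(1-phi) + log f(y)` otherwise,
#'   assembled with log-sum-exp so tiny `phi` and `f(0)` do not underflow.
#' @param phi structural-zero probability in \[0, 1\]; vectorized.
#' @export
zi_obs_loglik <- function(y, phi, eta, family, dispersion = NULL) {
  if (any(phi < 0 | phi > 1)) stop("phi must lie in [0,1]", call. = FALSE)
  n <- max(length(y), length(phi), length(eta))
  y <- rep_len(y, n); phi <- rep_len(phi, n); eta <- rep_len(eta, n)
  lf <- count_logpmf(y, eta, family, dispersion)
  out <- log1p(-phi) + lf
  z <- y == 0
  if (any(z))
    out[z] <- logsumexp2(log(phi[z]), log1p(-phi[z]) + lf[z])
  out
}

#' @describeIn count_families Fitted mean of the zero-inflated response,
#'   `(1 - phi) * E[count part]`.
#' @export
fitted_mean <- function(phi, eta, family, dispersion = NULL) {
  family <- .check_family(family, dispersion)
  mu <- exp(eta)
  ecount <- switch(family,
    poisson = mu,
    negbin  = mu,
    cmp     = cmp_moments(mu, dispersion)$mean)
  (1 - phi) * ecount
}

#' Map between NB2 (mean, dispersion) and (r, p) parameterizations
#'
#' The negative binomial is fitted as mean `mu = exp(eta)` with dispersion
#' `r` (variance `mu + mu^2/r`).  The classical (r, p) form with
#' `E[y] = r(1-p)/p` corresponds to `p = r/(r + mu)`.
#'
#' @param mu mean; @param r dispersion.
#' @return list with `r` and `p`.
#' @export
nb_mu_to_rp <- function(mu, r) list(r = r, p = r / (r + mu))
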