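#' Conway--Maxwell--Poisson distribution
#'
#' Numerically robust Conway--Maxwell--Poisson (CMP) distribution with
#' rate-like parameter `lam` (\eqn{\lambda > 0}) and dispersion `nu`
#' (\eqn{\nu \ge 0}).  The pmf is
#' \deqn{P(Y = y) = \frac{\lambda^y}{(y!)^\nu} \frac{1}{Z(\lambda,\nu)},
#'   \qquad Z(\lambda,\nu) = \sum_{i=0}^\infty \frac{\lambda^i}{(i!)^\nu}.}
#' \eqn{\nu = 1} recovers the Poisson distribution with mean \eqn{\lambda};
#' \eqn{\nu < 1} gives over-dispersion, \eqn{\nu > 1} under-dispersion.
#' \eqn{\nu = 0} is admitted only for \eqn{\lambda < 1} (geometric case);
#' otherwise the series diverges and construction fails.
#'
#' All series arithmetic is carried out in log space with a streaming
#' log-sum-exp, so neither \eqn{\lambda^i} nor \eqn{(i!)^\nu} is ever formed
#' directly.  Summation stops once terms are decreasing and the current term
#' contributes less than `rel_tol` of the running sum; a hard cap of 1e6
#' terms raises an explicit error (reachable only for extreme
#' \eqn{\lambda^{1/\nu}}).
#'
#' @param lam positive rate parameter; vectorized.
#' @param nu non-negative dispersion parameter (scalar).
#' @param rel_tol relative truncation tolerance in (0, 1e-6]; the neglected
#'   tail contributes less than this fraction of the sum.
#' @name cmp
NULL

.cmp_check <- function(lam, nu, rel_tol = 1e-12) {
  if (!all(is.finite(lam)) || !is.finite(nu))
    stop("CMP parameters must be finite", call. = FALSE)
  if (any(lam <= 0)) stop("CMP requires lam > 0", call. = FALSE)
  if (nu < 0) stop("CMP requires nu >= 0", call. = FALSE)
  if (nu == 0 && any(lam >= 1))
    stop("CMP series diverges for nu = 0 with lam >= 1", call. = FALSE)
  if (!(rel_tol > 0 && rel_tol <= 1e-6))
    stop("rel_tol must lie in (0, 1e-6]", call. = FALSE)
  invisible(TRUE)
}

# Streaming block summation of log sum_{i>=0} exp(i*log(lam) - nu*lgamma(i+1)),
# optionally with extra log-weights k*log(i) (k = 0, 1, 2) for moments.
# Returns a matrix with one column per requested power, rows follow lam.
.cmp_series <- function(lam, nu, rel_tol, powers = 0L, max_terms = 1e6L) {
  loglam <- log(lam)
  L <- length(lam)
  acc <- matrix(-Inf, L, length(powers))
  # i = 0 term contributes only to the power-0 sum (0^k = 0 for k > 0)
  acc[, powers == 0L] <- 0
  block <- 256L
  i0 <- 1L
  logtol <- log(rel_tol)
  repeat {
    idx <- i0:(i0 + block - 1L)
    logterm <- outer(loglam, as.numeric(idx)) -
      matrix(nu * lgamma(idx + 1), L, block, byrow = TRUE)
    logi <- log(idx)
    for (k in seq_along(powers)) {
      lt <- logterm + matrix(powers[k] * logi, L, block, byrow = TRUE)
      m <- pmax(acc[, k], apply(lt, 1L, max))
      acc[, k] <- m + log(exp(acc[, k] - m) + rowSums(exp(lt - m)))
    }
    last <- logterm[, block]
    decreasing <- all(last < logterm[, block - 1L])
    # largest power dominates the tail requirement
    kmax <- max(powers)
    done <- decreasing &&
      all(last + kmax * log(idx[block]) - acc[, which.max(powers)] < logtol)
    if (done) break
    i0 <- i0 + block
    if (i0 > max_terms)
      stop("CMP series truncation cap (1e6 terms) reached; ",
           "lam^(1/nu) is too large for direct summation", call. = FALSE)
  }
  acc
}

#' @describeIn cmp Log normalizing constant \eqn{\log Z(\lambda,\nu)};
#'   vectorized over `lam`.
#' @export
cmp_log_normalizer <- function(lam, nu, rel_tol = 1e-12) {
  .cmp_check(lam, nu, rel_tol)
  if (nu == 0) return(-log1p(-lam))            # geometric: Z = 1/(1-lam)
  if (length(lam) > 32L) {
    # likelihood evaluations repeat rates across rows and quadrature nodes
    ul <- unique(lam)
    return(drop(.cmp_series(ul, nu, rel_tol, powers = 0L))[match(lam, ul)])
  }
  drop(.cmp_series(lam, nu, rel_tol, powers = 0L))
}

#' @describeIn cmp Log probability mass function at non-negative integer `y`
#'   (recycled against `lam`).
#' @param y non-negative integer count(s).
#' @param log logical; return log pmf?
#' @export
dcmp <- function(y, lam, nu, log = FALSE, rel_tol = 1e-12) {
  if (any(y < 0) || any(y != floor(y)))
    stop("y must be non-negative integers", call. = FALSE)
  n <- max(length(y), length(lam))
  y <- rep_len(y, n); lam <- rep_len(lam, n)
  logZ <- cmp_log_normalizer(lam, nu, rel_tol)
  lp <- y * base::log(lam) - nu * lgamma(y + 1) - logZ
  if (log) lp else exp(lp)
}

#' @describeIn cmp Mean and variance by truncated series, as a list with
#'   elements `mean` and `variance` (vectorized over `lam`).
#' @export
cmp_moments <- function(lam, nu, rel_tol = 1e-12) {
  .cmp_check(lam, nu, rel_tol)
  if (nu == 0) {
    # geometric with success prob 1 - lam
    m <- lam / (1 - lam)
    return(list(mean = m, variance = lam / (1 - lam)^2))
  }
  s <- .cmp_series(lam, nu, rel_tol, powers = c(0L, 1L, 2L))
  mean <- exp(s[, 2L] - s[, 1L])
  ey2 <- exp(s[, 3L] - s[, 1L])
  list(mean = mean, variance = ey2 - mean^2)
}

# Smallest y such that P(Y <= y) >= 1 - eps, found by walking the pmf.
.cmp_upper <- function(lam, nu, eps = 1e-12) {
  logZ <- cmp_log_normalizer(lam, nu)
  y <- 0L
  logcdf <- -logZ
  lp <- -logZ
  while (logcdf < log1p(-eps) && y < 1e6L) {
    y <- y + 1L
    lp <- lp + log(lam) - nu * log(y)
    logcdf <- logsumexp2(logcdf, lp)
  }
  y
}

#' @describeIn cmp Cumulative distribution function.
#' @param q quantile(s).
#' @export
pcmp <- function(q, lam, nu, rel_tol = 1e-12) {
  .cmp_check(lam, nu, rel_tol)
  ymax <- max(.cmp_upper(max(lam), nu), floor(max(q)))
  stopifnot(length(lam) == 1L)
  pmf <- dcmp(0:ymax, lam, nu, rel_tol = rel_tol)
  cdf <- cumsum(pmf)
  ifelse(q < 0, 0, cdf[pmin(floor(q), ymax) + 1])
}

#' @describeIn cmp Quantile function (smallest y with cdf >= p).
#' @param p probability(ies).
#' @export
qcmp <- function(p, lam, nu, rel_tol = 1e-12) {
  .cmp_check(lam, nu, rel_tol)
  ymax <- .cmp_upper(lam, nu)
  cdf <- cumsum(dcmp(0:ymax, lam, nu, rel_tol = rel_tol))
  vapply(p, function(pp) {
    if (pp >= cdf[length(cdf)]) return(ymax)
    as.integer(which(cdf >= pp)[1] - 1L)
  }, integer(1))
}

#' @describeIn cmp Random draws by inverse-cdf over the truncated support;
#'   an identical `seed` yields an identical sequence.
#' @param n number of draws.
#' @param seed optional integer seed consumed by the draw.
#' @export
rcmp <- function(n, lam, nu, seed = NULL, rel_tol = 1e-12) {
  .cmp_check(lam, nu, rel_tol)
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  u <- runif(n)
  if (length(lam) == 1L) {
    ymax <- .cmp_upper(lam, nu)
    cdf <- cumsum(dcmp(0:ymax, lam, nu, rel_tol = rel_tol))
    return(findInterval(u, cdf) )
  }
  lam <- rep_len(lam, n)
  out <- integer(n)
  for (lv in unique(lam)) {
    sel <- lam == lv
    ymax <- .cmp_upper(lv, nu)
    cdf <- cumsum(dcmp(0:ymax, lv, nu, rel_tol = rel_tol))
    out[sel] <- findInterval(u[sel], cdf)
  }
  out
}
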