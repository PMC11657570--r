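# Independent oracles, kept deliberately naive and separate from the
# package's streaming/truncating implementations.

# Brute-force CMP log normalizer: direct log-sum-exp over a fixed number of
# series terms, sized from lam^(1/nu) so the sum has converged.
oracle_cmp_lognorm <- function(lam, nu, n_terms = NULL) {
  if (is.null(n_terms))
    n_terms <- max(10000, ceiling(5 * lam^(1 / nu)))
  i <- 0:n_terms
  lt <- i * log(lam) - nu * lgamma(i + 1)
  m <- max(lt)
  m + log(sum(exp(lt - m)))
}

oracle_cmp_moments <- function(lam, nu, n_terms = 10000) {
  i <- 0:n_terms
  p <- exp(i * log(lam) - nu * lgamma(i + 1) - oracle_cmp_lognorm(lam, nu))
  list(mean = sum(i * p), variance = sum(i^2 * p) - sum(i * p)^2)
}

# Dense-grid (trapezoid) marginal likelihood for one cluster, 1-D in u.
oracle_marginal_1d <- function(y, eta0, family, disp, sig_u,
                               npts = 20001, half_width = 8) {
  u <- seq(-half_width * sig_u, half_width * sig_u, length.out = npts)
  g <- vapply(u, function(uu)
    sum(count_logpmf(y, eta0 + uu, family, disp)) +
      dnorm(uu, 0, sig_u, log = TRUE), numeric(1))
  m <- max(g)
  h <- u[2] - u[1]
  m + log(h * (sum(exp(g - m)) - 0.5 * exp(g[1] - m) -
                 0.5 * exp(g[npts] - m)))
}

# Dense-grid marginal for a zero-inflated cluster, 2-D in (w, u).
oracle_marginal_2d <- function(y, xi0, eta0, family, disp, sig_w, sig_u,
                               npts = 601, half_width = 7) {
  w <- seq(-half_width * sig_w, half_width * sig_w, length.out = npts)
  u <- seq(-half_width * sig_u, half_width * sig_u, length.out = npts)
  g <- matrix(NA_real_, npts, npts)
  for (a in seq_len(npts)) {
    phi <- plogis(xi0 + w[a])
    for (b in seq_len(npts))
      g[a, b] <- sum(zi_obs_loglik(y, phi, eta0 + u[b], family, disp)) +
        dnorm(w[a], 0, sig_w, log = TRUE) + dnorm(u[b], 0, sig_u, log = TRUE)
  }
  m <- max(g)
  hw <- w[2] - w[1]; hu <- u[2] - u[1]
  wt <- matrix(1, npts, npts)
  wt[c(1, npts), ] <- wt[, c(1, npts)] <- 0.5
  wt[c(1, npts), c(1, npts)] <- 0.25
  m + log(hw * hu * sum(wt * exp(g - m)))
}

# Small two-level simulated dataset with a single binary covariate.
sim_two_level <- function(seed, family = "poisson", zero_inflated = TRUE,
                          alpha = c(3.0, -2.26432), beta = c(1.2, 1.17575),
                          dispersion = NULL, sigma_w = 0.2, sigma_u = 0.2,
                          cluster_sizes = zicmpreg::dscs_city_table()$n) {
  set.seed(seed)
  n <- sum(cluster_sizes)
  m <- length(cluster_sizes)
  city <- rep(seq_len(m), cluster_sizes)
  sex <- sample(c("Female", "Male"), n, TRUE, c(0.635, 0.365))
  male <- as.numeric(sex == "Male")
  w <- rnorm(m, 0, sigma_w); u <- rnorm(m, 0, sigma_u)
  eta <- beta[1] + beta[2] * male + u[city]
  struct <- if (zero_inflated)
    rbinom(n, 1, plogis(alpha[1] + alpha[2] * male + w[city])) == 1
  else rep(FALSE, n)
  y <- integer(n)
  idx <- which(!struct)
  lam <- exp(eta[idx])
  y[idx] <- switch(family,
    poisson = rpois(length(idx), lam),
    negbin = rnbinom(length(idx), size = dispersion, mu = lam),
    cmp = rcmp(length(idx), lam, dispersion))
  data.frame(y = y, city_id = city, sex = sex)
}
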