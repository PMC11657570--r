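#' Marginal maximum likelihood for two-level count models
#'
#' Respondents (level 1) are nested in cities (level 2).  City heterogeneity
#' enters as independent normal random intercepts: `u` in the count part
#' always, and `w` in the zero part for zero-inflated models.  The marginal
#' likelihood integrates the random intercepts out cluster by cluster with
#' adaptive Gauss--Hermite quadrature (nodes centered at the per-cluster
#' posterior mode and scaled by its curvature), and is maximized with a
#' quasi-Newton optimizer over unconstrained parameters (coefficients plus
#' log dispersion and log random-effect SDs).
#'
#' @name multilevel_inference
NULL

#' Gauss--Hermite quadrature rule
#'
#' @param K node count per dimension (K >= 1).
#' @return list with `nodes`, `weights` (physicists' convention, weight
#'   function `exp(-x^2)`) and `K`.
#' @export
gh_rule <- function(K = 15L) {
  stopifnot(K >= 1)
  if (K == 1L) return(list(nodes = 0, weights = sqrt(pi), K = 1L))
  gh <- pracma::gaussHermite(K)
  list(nodes = gh$x, weights = gh$w, K = as.integer(K))
}

# Internal prepared-data container ------------------------------------------

.prepare_data <- function(data, spec) {
  if (!all(c("y", "city_id") %in% names(data)))
    stop("data needs columns 'y' and 'city_id'", call. = FALSE)
  y <- data$y
  if (any(y < 0) || any(y != floor(y)))
    stop("response must be non-negative integers", call. = FALSE)
  Xc <- build_design(data, dscs_coding(spec$count_covariates))
  Xz <- if (spec$zero_inflated)
    build_design(data, dscs_coding(spec$zero_covariates)) else NULL
  cl <- factor(data$city_id)
  list(y = as.integer(y), Xc = Xc, Xz = Xz,
       cluster = split(seq_len(nrow(data)), cl),
       cluster_ids = levels(cl), n = nrow(data))
}

# Parameter packing: theta = [alpha | beta | log disp | log sig_w | log sig_u]
.theta_layout <- function(spec, pc, pz) {
  has_disp <- spec$family != "poisson"
  zi <- spec$zero_inflated
  nm <- c(if (zi) paste0("zero.", seq_len(pz)),
          paste0("count.", seq_len(pc)),
          if (has_disp) "log_disp",
          if (zi) "log_sigma_w",
          "log_sigma_u")
  list(pz = if (zi) pz else 0L, pc = pc, has_disp = has_disp, zi = zi,
       len = length(nm), names = nm)
}

.unpack <- function(theta, lay) {
  i <- 0L
  alpha <- if (lay$zi) theta[seq_len(lay$pz)] else numeric(0)
  i <- lay$pz
  beta <- theta[i + seq_len(lay$pc)]; i <- i + lay$pc
  disp <- if (lay$has_disp) exp(theta[i + 1L]) else NULL
  if (lay$has_disp) i <- i + 1L
  sig_w <- if (lay$zi) exp(theta[i + 1L]) else 0
  if (lay$zi) i <- i + 1L
  sig_u <- exp(theta[i + 1L])
  list(alpha = alpha, beta = beta, disp = disp,
       sig_w = sig_w, sig_u = sig_u)
}

# Joint log-density of one cluster's data and its random effects at (w, u).
# eta0/xi0 are the fixed-effect parts of the linear predictors.
.cluster_joint <- function(w, u, y, xi0, eta0, family, disp,
                           sig_w, sig_u, zi) {
  eta <- eta0 + u
  if (family == "cmp" && max(eta) > disp * log(5e4))
    return(-Inf)                     # series would need > ~5e4 terms
  ll <- if (zi) {
    phi <- stats::plogis(xi0 + w)
    sum(zi_obs_loglik(y, phi, eta, family, disp))
  } else {
    sum(count_logpmf(y, eta, family, disp))
  }
  ll + (if (zi) stats::dnorm(w, 0, sig_w, log = TRUE) else 0) +
    stats::dnorm(u, 0, sig_u, log = TRUE)
}

# Vectorized joint over node pairs (wv, uv vectors of equal length M).
.cluster_joint_vec <- function(wv, uv, y, xi0, eta0, family, disp,
                               sig_w, sig_u, zi) {
  M <- length(uv); nj <- length(y)
  eta <- outer(eta0, uv, "+")                       # nj x M
  if (family == "cmp" && max(eta) > disp * log(5e4)) {
    ok <- apply(eta, 2L, max) <= disp * log(5e4)
    out <- rep(-Inf, M)
    if (any(ok))
      out[ok] <- .cluster_joint_vec(wv[ok], uv[ok], y, xi0, eta0, family,
                                    disp, sig_w, sig_u, zi)
    return(out)
  }
  yv <- rep(y, M)
  if (zi) {
    phi <- stats::plogis(outer(xi0, wv, "+"))
    ll <- zi_obs_loglik(yv, as.vector(phi), as.vector(eta), family, disp)
  } else {
    ll <- count_logpmf(yv, as.vector(eta), family, disp)
  }
  colSums(matrix(ll, nj, M)) +
    (if (zi) stats::dnorm(wv, 0, sig_w, log = TRUE) else 0) +
    stats::dnorm(uv, 0, sig_u, log = TRUE)
}

# Posterior mode and curvature of the cluster random effects.
.cluster_mode <- function(y, xi0, eta0, family, disp, sig_w, sig_u, zi,
                          start = NULL) {
  d <- if (zi) 2L else 1L
  f <- if (zi) {
    function(p) -.cluster_joint(p[1], p[2], y, xi0, eta0, family, disp,
                                sig_w, sig_u, zi)
  } else {
    function(p) -.cluster_joint(0, p[1], y, xi0, eta0, family, disp,
                                sig_w, sig_u, zi)
  }
  p0 <- if (is.null(start)) rep(0, d) else start
  opt <- suppressWarnings(
    stats::optim(p0, f, method = "BFGS",
                 control = list(maxit = 200, reltol = 1e-10)))
  mode <- opt$par
  # central-difference Hessian of -joint at the mode
  h <- pmax(1e-4, abs(mode) * 1e-4)
  H <- matrix(0, d, d)
  f0 <- opt$value
  for (a in seq_len(d)) {
    ea <- replace(numeric(d), a, h[a])
    H[a, a] <- (f(mode + ea) - 2 * f0 + f(mode - ea)) / h[a]^2
    if (a < d) for (b in (a + 1L):d) {
      eb <- replace(numeric(d), b, h[b])
      H[a, b] <- H[b, a] <-
        (f(mode + ea + eb) - f(mode + ea - eb) -
           f(mode - ea + eb) + f(mode - ea - eb)) / (4 * h[a] * h[b])
    }
  }
  # guard: curvature must be positive definite; fall back to prior curvature
  ev <- eigen(H, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    H <- diag(1 / c(if (zi) sig_w^2, sig_u^2)^1, d)
  }
  list(mode = mode, H = H)
}

#' Marginal log-likelihood of one cluster
#'
#' Integrates the cluster's random intercepts out of the joint likelihood
#' with adaptive Gauss--Hermite quadrature: nodes are shifted to the
#' posterior mode of `(w, u)` and scaled by the inverse Cholesky factor of
#' the curvature there; independence of `w` and `u` makes the 2-D rule a
#' product rule.  Non-zero-inflated models integrate over `u` only.
#' `sig_w = sig_u = 0` returns the fixed-effects log-likelihood at
#' `w = u = 0` exactly.
#'
#' @param y,Xz,Xc cluster response and design matrices (Xz `NULL` when not
#'   zero-inflated).
#' @param alpha,beta,disp fixed effects and dispersion.
#' @param sig_w,sig_u random-intercept SDs.
#' @param rule a [gh_rule()].
#' @param family,zero_inflated model family flags.
#' @param start optional mode warm start.
#' @return scalar log marginal likelihood, with attribute `"mode"`.
#' @export
cluster_marginal_loglik <- function(y, Xz, Xc, alpha, beta, disp,
                                    sig_w, sig_u, rule,
                                    family, zero_inflated,
                                    start = NULL) {
  zi <- isTRUE(zero_inflated)
  xi0 <- if (zi) drop(Xz %*% alpha) else numeric(length(y))
  eta0 <- drop(Xc %*% beta)
  if ((!zi || sig_w == 0) && sig_u == 0) {
    ll <- if (zi)
      sum(zi_obs_loglik(y, stats::plogis(xi0), eta0, family, disp))
    else sum(count_logpmf(y, eta0, family, disp))
    return(structure(ll, mode = if (zi) c(0, 0) else 0))
  }
  if (zi && sig_w == 0)
    stop("zero-inflated models integrate both parts; sig_w = 0 with ",
         "sig_u > 0 is not supported", call. = FALSE)
  d <- if (zi) 2L else 1L
  ms <- .cluster_mode(y, xi0, eta0, family, disp, sig_w, sig_u, zi, start)
  R <- chol(ms$H)                                  # H = R'R
  x <- rule$nodes; lw <- log(rule$weights)
  if (d == 1L) {
    s <- sqrt(2) / sqrt(ms$H[1, 1])
    uv <- ms$mode + s * x
    g <- .cluster_joint_vec(numeric(length(uv)), uv, y, xi0, eta0, family,
                            disp, sig_w, sig_u, zi)
    val <- logsumexp(lw + x^2 + g) + log(s)
  } else {
    grid <- as.matrix(expand.grid(x, x))
    zmat <- sqrt(2) * t(backsolve(R, t(grid)))     # R^{-1} z
    wv <- ms$mode[1] + zmat[, 1]; uv <- ms$mode[2] + zmat[, 2]
    g <- .cluster_joint_vec(wv, uv, y, xi0, eta0, family, disp,
                            sig_w, sig_u, zi)
    lwg <- lw[rep(seq_along(x), times = length(x))] +
      lw[rep(seq_along(x), each = length(x))]
    val <- logsumexp(lwg + rowSums(grid^2) + g) +
      log(2) / 2 * 2 - sum(log(diag(R)))
  }
  if (!is.finite(val))
    stop("non-finite cluster marginal likelihood", call. = FALSE)
  structure(val, mode = ms$mode)
}

#' Total marginal log-likelihood over all clusters
#'
#' Evaluates the same adaptive Gauss--Hermite integral as
#' [cluster_marginal_loglik()] but with the per-cluster posterior-mode
#' Newton search and the node evaluation vectorized across all clusters at
#' once, which is what makes survey-sized replicate batteries affordable.
#'
#' @param prep internal prepared data (or a data frame, with `spec`).
#' @param theta packed parameter vector; see [fit_model()].
#' @param spec a [model_spec()].
#' @param rule a [gh_rule()].
#' @param modes optional environment caching per-cluster mode warm starts.
#' @return scalar log-likelihood.
#' @export
total_loglik <- function(prep, theta, spec, rule = gh_rule(15L),
                         modes = NULL) {
  if (is.data.frame(prep)) prep <- .prepare_data(prep, spec)
  lay <- .theta_layout(spec, ncol(prep$Xc),
                       if (spec$zero_inflated) ncol(prep$Xz) else 0L)
  par <- .unpack(theta, lay)
  zi <- lay$zi
  family <- spec$family
  y <- prep$y
  n <- prep$n
  m <- length(prep$cluster)
  cl <- integer(n)
  for (k in seq_along(prep$cluster)) cl[prep$cluster[[k]]] <- k
  eta0 <- drop(prep$Xc %*% par$beta)
  xi0 <- if (zi) drop(prep$Xz %*% par$alpha) else numeric(n)
  cap <- if (family == "cmp") par$disp * log(5e4) else Inf

  # per-row log-likelihood at expanded random effects (vectors or matrices
  # conformable with eta0 recycled column-wise)
  row_ll <- function(eta, phi) {
    pen <- 0
    if (is.finite(cap)) {
      excess <- pmax(eta - cap, 0)
      pen <- -1e4 * excess^2          # smooth barrier keeps search finite
      eta <- pmin(eta, cap)
    }
    ll <- if (zi) zi_obs_loglik(y, as.vector(phi), as.vector(eta),
                                family, par$disp)
    else count_logpmf(y, as.vector(eta), family, par$disp)
    ll + as.vector(pen)
  }
  # cluster-level joint log-density at (w, u) (m-vectors)
  g_all <- function(w, u) {
    eta <- eta0 + u[cl]
    phi <- if (zi) stats::plogis(xi0 + w[cl]) else NULL
    drop(rowsum(row_ll(eta, phi), cl)) +
      (if (zi) stats::dnorm(w, 0, par$sig_w, log = TRUE) else 0) +
      stats::dnorm(u, 0, par$sig_u, log = TRUE)
  }

  # degenerate random effects: fixed-effects likelihood at w = u = 0
  if ((!zi || par$sig_w == 0) && par$sig_u == 0)
    return(sum(row_ll(eta0, if (zi) stats::plogis(xi0))))
  if (zi && (par$sig_w == 0) != (par$sig_u == 0))
    stop("zero-inflated models integrate both parts; a single zero SD ",
         "is not supported", call. = FALSE)

  # --- vectorized damped-Newton mode search ---------------------------------
  if (!is.null(modes) && !is.null(modes$w)) {
    w <- modes$w; u <- modes$u
  } else {
    w <- numeric(m); u <- numeric(m)
  }
  if (!zi) w <- numeric(m)
  h <- 1e-4
  H11 <- H22 <- H12 <- NULL
  g0 <- g_all(w, u)
  for (it in 1:12) {
    if (zi) {
      gwp <- g_all(w + h, u); gwm <- g_all(w - h, u)
      gup <- g_all(w, u + h); gum <- g_all(w, u - h)
      gpp <- g_all(w + h, u + h); gmm <- g_all(w - h, u - h)
      gpm <- g_all(w + h, u - h); gmp <- g_all(w - h, u + h)
      dw <- (gwp - gwm) / (2 * h); du <- (gup - gum) / (2 * h)
      H11 <- -(gwp - 2 * g0 + gwm) / h^2
      H22 <- -(gup - 2 * g0 + gum) / h^2
      H12 <- -(gpp - gpm - gmp + gmm) / (4 * h^2)
      bad <- !(H11 > 0 & H11 * H22 - H12^2 > 0) | !is.finite(H11 + H22 + H12)
      if (any(bad)) {
        H11[bad] <- 1 / par$sig_w^2; H22[bad] <- 1 / par$sig_u^2
        H12[bad] <- 0
      }
      det <- H11 * H22 - H12^2
      sw <- (H22 * dw - H12 * du) / det
      su <- (H11 * du - H12 * dw) / det
    } else {
      gup <- g_all(w, u + h); gum <- g_all(w, u - h)
      du <- (gup - gum) / (2 * h)
      H22 <- -(gup - 2 * g0 + gum) / h^2
      bad <- !(H22 > 0) | !is.finite(H22)
      H22[bad] <- 1 / par$sig_u^2
      sw <- numeric(m); su <- du / H22
    }
    nrm <- sqrt(sw^2 + su^2)
    shrink <- pmin(1, 3 / pmax(nrm, 1e-12))
    sw <- sw * shrink; su <- su * shrink
    # damped acceptance per cluster
    scl <- rep(1, m)
    for (dmp in 1:4) {
      g1 <- g_all(w + scl * sw, u + scl * su)
      worse <- g1 < g0 - 1e-9
      if (!any(worse)) break
      scl[worse] <- scl[worse] / 2
    }
    keep <- g1 >= g0
    w <- w + ifelse(keep, scl * sw, 0)
    u <- u + ifelse(keep, scl * su, 0)
    g0 <- ifelse(keep, g1, g0)
    if (max(abs(c(scl * sw, scl * su))) < 1e-7) break
  }
  if (!is.null(modes)) { modes$w <- w; modes$u <- u }

  # --- adaptive product-rule quadrature -------------------------------------
  x <- rule$nodes; lwt <- log(rule$weights)
  if (zi) {
    R11 <- sqrt(H11); R12 <- H12 / R11
    R22 <- sqrt(pmax(H22 - R12^2, 1e-12))
    Kn <- length(x)
    X1 <- rep(x, times = Kn); X2 <- rep(x, each = Kn)
    lw2 <- lwt[rep(seq_len(Kn), times = Kn)] +
      lwt[rep(seq_len(Kn), each = Kn)] + X1^2 + X2^2
    z2 <- (1 / R22) %o% X2
    z1 <- (matrix(X1, m, Kn * Kn, byrow = TRUE) - R12 * z2) / R11
    wn <- w + sqrt(2) * z1; un <- u + sqrt(2) * z2
    eta <- eta0 + un[cl, , drop = FALSE]
    phi <- stats::plogis(xi0 + wn[cl, , drop = FALSE])
    llm <- matrix(row_ll(eta, phi), n)
    gn <- rowsum(llm, cl) + stats::dnorm(wn, 0, par$sig_w, log = TRUE) +
      stats::dnorm(un, 0, par$sig_u, log = TRUE)
    A <- sweep(gn, 2L, lw2, "+")
    mx <- apply(A, 1L, max)
    marg <- mx + log(rowSums(exp(A - mx))) + log(2) -
      log(R11) - log(R22)
  } else {
    s <- sqrt(2 / H22)
    un <- u + s %o% x
    eta <- eta0 + un[cl, , drop = FALSE]
    llm <- matrix(row_ll(eta, NULL), n)
    gn <- rowsum(llm, cl) + stats::dnorm(un, 0, par$sig_u, log = TRUE)
    A <- sweep(gn, 2L, lwt + x^2, "+")
    mx <- apply(A, 1L, max)
    marg <- mx + log(rowSums(exp(A - mx))) + log(s)
  }
  if (!all(is.finite(marg)))
    stop("non-finite cluster marginal likelihood (cluster ",
         paste(which(!is.finite(marg)), collapse = ", "), ")",
         call. = FALSE)
  sum(marg)
}

.start_values <- function(prep, spec) {
  y <- prep$y
  if (spec$zero_inflated) {
    z <- as.numeric(y == 0)
    a0 <- tryCatch(
      coef(glm.fit(prep$Xz, z, family = binomial())),
      error = function(e) c(stats::qlogis(max(mean(z), 1e-3)),
                            rep(0, ncol(prep$Xz) - 1L)))
    pos <- y > 0
    b0 <- tryCatch(
      coef(glm.fit(prep$Xc[pos, , drop = FALSE], y[pos],
                   family = poisson())),
      error = function(e) c(log(max(mean(y[pos]), 0.5)),
                            rep(0, ncol(prep$Xc) - 1L)))
  } else {
    a0 <- NULL
    b0 <- tryCatch(coef(glm.fit(prep$Xc, y, family = poisson())),
                   error = function(e) c(log(max(mean(y), 1e-3)),
                                         rep(0, ncol(prep$Xc) - 1L)))
  }
  b0[!is.finite(b0)] <- 0
  if (!is.null(a0)) a0[!is.finite(a0)] <- 0
  ldisp <- switch(spec$family, poisson = NULL, negbin = log(1), cmp = log(1))
  c(a0, b0, ldisp,
    if (spec$zero_inflated) log(0.1), log(0.1))
}

#' Fit a two-level count model by marginal maximum likelihood
#'
#' Two-stage start (fixed-effects GLM fits ignoring clustering, then
#' random-effect SDs at 0.1), quasi-Newton (`nlminb`) maximization over the
#' unconstrained parameter vector, optional extra jittered starts with
#' tie-break by highest log-likelihood.  Dispersion and SDs are optimized on
#' the log scale; SDs may collapse towards 0, which is reported as a
#' boundary, not refitted.
#'
#' @param data data frame with `y`, `city_id` and covariate columns.
#' @param spec a [model_spec()].
#' @param K quadrature nodes per dimension (default 15).
#' @param max_iter optimizer iteration cap.
#' @param tol relative log-likelihood convergence tolerance (gradient
#'   max-norm is checked at `1e-4 * max(1, |LL|)` scale).
#' @param starts number of optimizer starts (first from the GLM stage,
#'   others jittered).
#' @param seed seed for jittered starts.
#' @param verbose print progress?
#' @return `tl_fit` object: estimates, SDs, log-likelihood, vcov (filled by
#'   [standard_errors()]), per-cluster empirical-Bayes modes, convergence
#'   flag.
#' @export
fit_model <- function(data, spec, K = 15L, max_iter = 500L, tol = 1e-6,
                      starts = 1L, seed = 1L, verbose = FALSE) {
  stopifnot(inherits(spec, "model_spec"), nrow(data) > 0)
  prep <- .prepare_data(data, spec)
  if (length(prep$cluster) < 2L)
    stop("need at least 2 clusters for random-effect estimation",
         call. = FALSE)
  rule <- gh_rule(K)
  lay <- .theta_layout(spec, ncol(prep$Xc),
                       if (spec$zero_inflated) ncol(prep$Xz) else 0L)
  modes <- new.env()
  negll <- function(theta) {
    v <- tryCatch(-total_loglik(prep, theta, spec, rule, modes),
                  error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  theta0 <- .start_values(prep, spec)
  set.seed(seed)
  cands <- list(theta0)
  if (starts > 1L)
    for (s in seq_len(starts - 1L))
      cands[[s + 1L]] <- theta0 + rnorm(length(theta0), 0, 0.25)
  best <- NULL
  for (th0 in cands) {
    opt <- suppressWarnings(
      nlminb(th0, negll,
             control = list(iter.max = max_iter, eval.max = 4L * max_iter,
                            rel.tol = tol)))
    if (is.null(best) || opt$objective < best$objective) best <- opt
    if (verbose) message("start done, -LL = ", round(opt$objective, 4))
  }
  theta <- best$par
  ll <- -best$objective
  par <- .unpack(theta, lay)
  # gradient check for the convergence flag
  gr <- tryCatch(pracma::grad(negll, theta, heps = 1e-5),
                 error = function(e) rep(NA_real_, length(theta)))
  gnorm <- max(abs(gr))
  converged <- is.finite(ll) && best$convergence == 0 &&
    is.finite(gnorm) && gnorm < 1e-4 * max(1, abs(ll)) * 10
  # empirical-Bayes modes at the optimum
  negll(theta)
  mcl <- length(prep$cluster)
  eb <- cbind(
    w = if (!is.null(modes$w) && lay$zi) modes$w else rep(NA_real_, mcl),
    u = if (!is.null(modes$u)) modes$u else rep(NA_real_, mcl))
  rownames(eb) <- prep$cluster_ids
  n_params <- lay$len
  names(theta) <- c(
    if (lay$zi) paste0("zero.", colnames(prep$Xz)),
    paste0("count.", colnames(prep$Xc)),
    if (lay$has_disp) "log_disp",
    if (lay$zi) "log_sigma_w", "log_sigma_u")
  sep <- if (lay$zi && any(abs(par$alpha) > 10))
    "possible separation in the zero part (|coef| > 10)" else NULL
  if (!is.null(sep)) warning(sep, call. = FALSE)
  structure(list(
    spec = spec, theta = theta, layout = lay,
    alpha = par$alpha, beta = par$beta, dispersion = par$disp,
    sigma_w = if (lay$zi) par$sig_w else 0, sigma_u = par$sig_u,
    loglik = ll, n_params = n_params, n = prep$n,
    K = K, converged = converged, grad_norm = gnorm,
    eb_modes = eb, prep = prep, notes = sep),
    class = "tl_fit")
}

#' @export
print.tl_fit <- function(x, ...) {
  cat(format(x$spec), " fit: LL = ", sprintf("%.3f", x$loglik),
      ", P = ", x$n_params, ", n = ", x$n,
      if (!x$converged) "  [NOT converged]", "\n", sep = "")
  if (!is.null(x$dispersion))
    cat("dispersion:", signif(x$dispersion, 4), "\n")
  cat("sigma_w:", signif(x$sigma_w, 4), " sigma_u:",
      signif(x$sigma_u, 4), "\n")
  invisible(x)
}

#' Free-parameter count of a model specification
#'
#' Fixed effects per part (intercept plus one dummy per non-reference
#' level), one dispersion for negbin/cmp, and one random-intercept variance
#' per active model part (count part always; zero part only when
#' zero-inflated).  With all twelve survey covariates this gives
#' 25/26/26/50/51/51 for TL-P/NB/CMP/ZIP/ZINB/ZICMP.
#'
#' @param spec a [model_spec()].
#' @return integer parameter count.
#' @export
count_params <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  pcols <- function(covs)
    1L + sum(vapply(dscs_coding(covs), function(l) length(l) - 1L,
                    integer(1)))
  pc <- pcols(spec$count_covariates)
  pz <- if (spec$zero_inflated) pcols(spec$zero_covariates) else 0L
  pc + pz + (spec$family != "poisson") + 1L + spec$zero_inflated
}

#' @export
logLik.tl_fit <- function(object, ...) {
  structure(object$loglik, df = object$n_params, nobs = object$n,
            class = "logLik")
}

#' @export
coef.tl_fit <- function(object, ...) object$theta

#' Wald standard errors, z statistics and significance tiers
#'
#' Numerical observed information (Hessian of the negative marginal
#' log-likelihood at the optimum, symmetrized); SEs are the square roots of
#' the inverse-information diagonal.  Log-scale parameters (dispersion,
#' random-effect SDs) are delta-method transformed back to their natural
#' scale.  A singular information matrix (typical when an SD has collapsed
#' to the boundary) yields `NA` SEs for the affected rows and a warning.
#'
#' @param fit a [fit_model()] result.
#' @param K quadrature nodes used in the Hessian evaluation (defaults to
#'   the fit's).
#' @return data frame: parameter, estimate (natural scale), se, z, p, and
#'   significance tier (`***` < 0.001, `**` < 0.01, `*` < 0.05).
#' @export
standard_errors <- function(fit, K = fit$K) {
  stopifnot(inherits(fit, "tl_fit"))
  prep <- fit$prep; spec <- fit$spec
  rule <- gh_rule(K)
  modes <- new.env()
  negll <- function(theta) {
    v <- tryCatch(-total_loglik(prep, theta, spec, rule, modes),
                  error = function(e) NA_real_)
    if (!is.finite(v)) 1e10 else v
  }
  H <- pracma::hessian(negll, fit$theta, h = 1e-4)
  H <- (H + t(H)) / 2
  V <- tryCatch(solve(H), error = function(e) NULL)
  p <- length(fit$theta)
  if (is.null(V)) {
    # drop boundary rows (near-zero curvature) and invert the rest
    keep <- abs(diag(H)) > 1e-6
    V <- matrix(NA_real_, p, p)
    if (any(keep)) {
      Vk <- tryCatch(solve(H[keep, keep, drop = FALSE]),
                     error = function(e) NULL)
      if (!is.null(Vk)) V[keep, keep] <- Vk
    }
    warning("singular information matrix; SEs at the boundary are NA",
            call. = FALSE)
  }
  se_theta <- sqrt(pmax(diag(V), 0))
  est <- fit$theta
  se <- se_theta
  logscale <- grepl("^log_", names(fit$theta))
  est[logscale] <- exp(fit$theta[logscale])
  se[logscale] <- est[logscale] * se_theta[logscale]   # delta method
  z <- fit$theta / se_theta
  z[logscale] <- NA                                    # boundary-prone
  pv <- 2 * pnorm(-abs(z))
  tier <- ifelse(is.na(pv), "", ifelse(pv < 0.001, "***",
           ifelse(pv < 0.01, "**", ifelse(pv < 0.05, "*", ""))))
  out <- data.frame(parameter = names(fit$theta), estimate = est, se = se,
                    z = z, p = pv, sig = tier, row.names = NULL)
  attr(out, "vcov") <- V
  out
}
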