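test_that("degenerate random effects recover the fixed-effects likelihood exactly", {
  y <- c(0L, 2L, 5L)
  Xc <- cbind(1, c(0, 1, 1))
  Xz <- cbind(1, c(1, 0, 1))
  alpha <- c(0.5, -1); beta <- c(0.3, 0.6)
  ll <- cluster_marginal_loglik(y, Xz, Xc, alpha, beta, NULL, 0, 0,
                                gh_rule(15), "poisson", TRUE)
  want <- sum(zi_obs_loglik(y, plogis(drop(Xz %*% alpha)),
                            drop(Xc %*% beta), "poisson"))
  expect_equal(as.numeric(ll), want, tolerance = 1e-12)
})

test_that("1-D marginal likelihood matches dense-grid integration", {
  y <- c(0L, 2L, 4L)
  Xc <- cbind(1, c(0, 1, 0))
  beta <- c(0.4, 0.5)
  for (K in c(10, 15)) {
    ll <- cluster_marginal_loglik(y, NULL, Xc, numeric(0), beta, NULL,
                                  0, 0.5, gh_rule(K), "poisson", FALSE)
    want <- oracle_marginal_1d(y, drop(Xc %*% beta), "poisson", NULL, 0.5)
    expect_equal(as.numeric(ll), want, tolerance = 1e-6)
  }
})

test_that("2-D zero-inflated marginal likelihood matches dense-grid integration", {
  y <- c(0L, 0L, 3L, 1L)
  Xc <- cbind(1, c(0, 1, 1, 0)); Xz <- Xc
  alpha <- c(1.0, -1.5); beta <- c(0.2, 0.8)
  ll <- cluster_marginal_loglik(y, Xz, Xc, alpha, beta, NULL, 0.4, 0.5,
                                gh_rule(15), "poisson", TRUE)
  want <- oracle_marginal_2d(y, drop(Xz %*% alpha), drop(Xc %*% beta),
                             "poisson", NULL, 0.4, 0.5)
  expect_equal(as.numeric(ll), want, tolerance = 1e-6)
})

test_that("adaptive quadrature has converged by K = 15", {
  set.seed(3)
  y <- rpois(8, 3)
  Xc <- cbind(1, rbinom(8, 1, 0.4))
  beta <- c(0.9, 0.3)
  l15 <- cluster_marginal_loglik(y, NULL, Xc, numeric(0), beta, NULL,
                                 0, 0.4, gh_rule(15), "poisson", FALSE)
  l30 <- cluster_marginal_loglik(y, NULL, Xc, numeric(0), beta, NULL,
                                 0, 0.4, gh_rule(30), "poisson", FALSE)
  expect_lt(abs(as.numeric(l15) - as.numeric(l30)), 1e-8)
})

test_that("vectorized total likelihood equals the per-cluster reference path", {
  d <- sim_two_level(19, cluster_sizes = c(5, 12, 30, 8))
  spec <- model_spec("poisson", TRUE, count_covariates = "sex")
  th <- c(2.8, -2.0, 1.1, 1.0, log(0.3), log(0.25))
  tot <- total_loglik(d, th, spec, gh_rule(15))
  Xc <- build_design(d, dscs_coding("sex"))
  ref <- 0
  for (k in sort(unique(d$city_id))) {
    i <- d$city_id == k
    ref <- ref + as.numeric(cluster_marginal_loglik(
      d$y[i], Xc[i, , drop = FALSE], Xc[i, , drop = FALSE],
      th[1:2], th[3:4], NULL, exp(th[5]), exp(th[6]),
      gh_rule(15), "poisson", TRUE))
  }
  expect_equal(tot, ref, tolerance = 1e-7)
})

test_that("total log-likelihood is continuous as the SDs vanish", {
  d <- sim_two_level(91, zero_inflated = TRUE,
                     cluster_sizes = rep(12, 6))
  spec <- model_spec("poisson", TRUE, count_covariates = "sex")
  th_free <- c(3.0, -2.3, 1.2, 1.2)
  ll_tiny <- total_loglik(d, c(th_free, log(1e-6), log(1e-6)), spec,
                          gh_rule(15))
  prep_ll <- total_loglik(d, c(th_free, log(1e-12), log(1e-12)), spec,
                          gh_rule(15))
  expect_equal(ll_tiny, prep_ll, tolerance = 1e-5)
})

test_that("Poisson parameter recovery: estimates within 3 SE of truth", {
  set.seed(17)
  sizes <- rep(69, 29)                 # n = 2001 across 29 clusters
  city <- rep(seq_len(29), sizes)
  n <- sum(sizes)
  sex <- sample(c("Female", "Male"), n, TRUE, c(0.5, 0.5))
  u <- rnorm(29, 0, 0.3)
  beta_true <- c(0.5, 0.8)
  y <- rpois(n, exp(beta_true[1] + beta_true[2] * (sex == "Male") + u[city]))
  d <- data.frame(y = y, city_id = city, sex = sex)
  fit <- fit_model(d, model_spec("poisson", FALSE, count_covariates = "sex"),
                   K = 11)
  expect_true(fit$converged)
  se <- standard_errors(fit)
  for (k in 1:2) {
    expect_lt(abs(fit$beta[k] - beta_true[k]), 3 * se$se[k])
  }
  expect_lt(abs(fit$sigma_u - 0.3), 0.2)
})

test_that("zero-inflated fit agrees with an independent TMB-based fit", {
  skip_if_not_installed("glmmTMB")
  d <- sim_two_level(23, cluster_sizes = rep(40, 12))
  fit <- fit_model(d, model_spec("poisson", TRUE, count_covariates = "sex"),
                   K = 9)
  g <- glmmTMB::glmmTMB(y ~ sex + (1 | city_id),
                        ziformula = ~ sex + (1 | city_id),
                        family = poisson, data = d)
  expect_equal(unname(fit$beta),
               unname(glmmTMB::fixef(g)$cond), tolerance = 0.02)
  expect_equal(unname(fit$alpha),
               unname(glmmTMB::fixef(g)$zi), tolerance = 0.02)
  # AGQ marginal likelihood should not fall below the Laplace value by more
  # than numerical noise
  expect_gt(fit$loglik, as.numeric(logLik(g)) - 0.1)
})

test_that("the zero-inflated model dominates its base family in likelihood", {
  d <- sim_two_level(31, cluster_sizes = rep(30, 10))
  base <- fit_model(d, model_spec("poisson", FALSE, count_covariates = "sex"),
                    K = 7)
  zi <- fit_model(d, model_spec("poisson", TRUE, count_covariates = "sex"),
                  K = 7)
  expect_gte(zi$loglik, base$loglik - 1e-3)
})

test_that("degenerate mixture: ZI fit on phi = 0 data still recovers count part", {
  set.seed(41)
  sizes <- rep(50, 12)
  city <- rep(seq_along(sizes), sizes)
  n <- sum(sizes)
  sex <- sample(c("Female", "Male"), n, TRUE)
  u <- rnorm(12, 0, 0.2)
  beta_true <- c(1.0, 0.5)
  y <- rpois(n, exp(beta_true[1] + beta_true[2] * (sex == "Male") + u[city]))
  d <- data.frame(y = y, city_id = city, sex = sex)
  fit <- fit_model(d, model_spec("poisson", TRUE, count_covariates = "sex"),
                   K = 7)
  # mixing probability near the boundary
  expect_lt(plogis(fit$alpha[1]), 0.05)
  se <- standard_errors(fit)
  bsel <- match(paste0("count.", c("(Intercept)", "sexMale")), se$parameter)
  for (k in 1:2)
    expect_lt(abs(fit$beta[k] - beta_true[k]),
              3 * max(se$se[bsel[k]], 0.05))
})

test_that("single-parameter Poisson SE matches the analytic information", {
  set.seed(8)
  y <- rpois(4000, 2.4)
  d <- data.frame(y = y, city_id = rep(1:8, each = 500))
  fit <- fit_model(d, model_spec("poisson", FALSE,
                                 count_covariates = character(0)), K = 7)
  se <- standard_errors(fit)
  muhat <- exp(fit$beta[1])
  closed <- sqrt(1 / (4000 * muhat))
  # iid data: the cluster SD collapses, leaving the analytic i.i.d. SE up
  # to the (tiny) contribution of the boundary variance parameter
  expect_equal(unname(se$se[se$parameter == "count.(Intercept)"]),
               unname(closed), tolerance = 2e-2)
  expect_lt(fit$sigma_u, 0.05)
})

test_that("parameter counts follow the part structure of the model", {
  specs <- list(model_spec("poisson"), model_spec("negbin"),
                model_spec("cmp"), model_spec("poisson", TRUE),
                model_spec("negbin", TRUE), model_spec("cmp", TRUE))
  expect_identical(vapply(specs, count_params, integer(1)),
                   c(25L, 26L, 26L, 50L, 51L, 51L))
  expect_identical(
    count_params(model_spec("cmp", TRUE, count_covariates = "sex")),
    2L + 2L + 1L + 2L)
})

test_that("a fitted object's n_params matches count_params", {
  d <- sim_two_level(55, cluster_sizes = rep(25, 8))
  spec <- model_spec("poisson", TRUE, count_covariates = "sex")
  fit <- fit_model(d, spec, K = 5)
  expect_identical(fit$n_params, as.integer(count_params(spec)))
})
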