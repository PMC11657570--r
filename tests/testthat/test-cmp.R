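test_that("log normalizer has closed forms at the Poisson and Bernoulli limits", {
  # nu = 1: Z = e^lam
  expect_equal(cmp_log_normalizer(1, 1), 1.0, tolerance = 1e-12)
  expect_equal(cmp_log_normalizer(7.3, 1), 7.3, tolerance = 1e-12)
  # nu large: only i = 0, 1 survive, Z -> 1 + lam
  expect_equal(cmp_log_normalizer(0.5, 50), log(1.5), tolerance = 1e-10)
  # nu = 0, lam < 1: geometric, Z = 1/(1 - lam)
  expect_equal(cmp_log_normalizer(0.5, 0), -log(0.5), tolerance = 1e-12)
})

test_that("log normalizer matches the brute-force series oracle on a grid", {
  for (lam in c(0.1, 1, 2, 5, 20))
    for (nu in c(0.3, 0.38, 0.5, 1, 1.75, 3)) {
      got <- cmp_log_normalizer(lam, nu)
      want <- oracle_cmp_lognorm(lam, nu)
      expect_lt(abs(got - want) / max(abs(want), 1e-12), 1e-9,
                label = sprintf("relerr at lam=%g nu=%g", lam, nu))
    }
})

test_that("invalid parameters are rejected and divergence is explicit", {
  expect_error(cmp_log_normalizer(-1, 1), "lam > 0")
  expect_error(cmp_log_normalizer(2, -0.1), "nu >= 0")
  expect_error(cmp_log_normalizer(1.5, 0), "diverges")
  expect_error(cmp_log_normalizer(Inf, 1), "finite")
  expect_error(cmp_log_normalizer(2, 0.5, rel_tol = 1e-3), "rel_tol")
  # the 1e6-term cap errors rather than spinning (lam^(1/nu) ~ 1e40)
  expect_error(cmp_log_normalizer(1e4, 0.1), "cap")
})

test_that("pmf normalizes, reduces to Poisson at nu = 1, and decays eventually", {
  for (lam in c(0.1, 1, 5, 20))
    for (nu in c(0.3, 0.38, 1, 1.75, 3)) {
      ymax <- max(200, ceiling(5 * lam^(1 / nu)) + 50)
      p <- dcmp(0:ymax, lam, nu)
      expect_equal(sum(p), 1, tolerance = 1e-8,
                   label = sprintf("sum at lam=%g nu=%g", lam, nu))
      # eventually decreasing beyond the mode
      mode <- which.max(p)
      expect_true(all(diff(p[mode:length(p)]) <= 1e-15))
    }
  y <- 0:60
  expect_lt(max(abs(dcmp(y, 3.7, 1, log = TRUE) -
                      dpois(y, 3.7, log = TRUE))), 1e-10)
})

test_that("log pmf values match the series oracle", {
  expect_equal(dcmp(0, 1, 1, log = TRUE), -1.0, tolerance = 1e-12)
  want <- 3 * log(2) - 0.5 * lgamma(4) - oracle_cmp_lognorm(2, 0.5)
  expect_equal(dcmp(3, 2, 0.5, log = TRUE), want, tolerance = 1e-10)
})

test_that("moments: Poisson case exact, dispersion direction correct, oracle agreement", {
  m <- cmp_moments(3, 1)
  expect_equal(m$mean, 3, tolerance = 1e-8)
  expect_equal(m$variance, 3, tolerance = 1e-8)
  under <- cmp_moments(2, 2)
  expect_lt(under$variance, under$mean)
  over <- cmp_moments(2, 0.5)
  expect_gt(over$variance, over$mean)
  want <- oracle_cmp_moments(2, 0.5)
  expect_equal(over$mean, want$mean, tolerance = 1e-8)
  expect_equal(over$variance, want$variance, tolerance = 1e-6)
})

test_that("sampling is seed-reproducible and distributionally correct", {
  expect_identical(rcmp(500, 2, 0.5, seed = 11), rcmp(500, 2, 0.5, seed = 11))
  x <- rcmp(1e5, 1, 1, seed = 5)
  expect_lt(abs(mean(x) - 1), 3 / sqrt(1e5))   # Poisson(1): SE = 1/sqrt(n)
  y <- rcmp(4e5, 2, 0.5, seed = 6)
  ymax <- max(y)
  emp <- tabulate(y + 1L, ymax + 1L) / length(y)
  tv <- 0.5 * (sum(abs(emp - dcmp(0:ymax, 2, 0.5))) +
                 (1 - pcmp(ymax, 2, 0.5)))
  expect_lt(tv, 0.005)
})

test_that("cdf/quantile are consistent inverse pairs", {
  for (p in c(0.05, 0.5, 0.9, 0.99)) {
    q <- qcmp(p, 2, 0.5)
    expect_gte(pcmp(q, 2, 0.5), p)
    if (q > 0) expect_lt(pcmp(q - 1, 2, 0.5), p)
  }
})

test_that("geometric special case (nu = 0) matches stats::dgeom", {
  expect_equal(dcmp(0:20, 0.4, 0), dgeom(0:20, 0.6), tolerance = 1e-12)
  m <- cmp_moments(0.4, 0)
  expect_equal(m$mean, 0.4 / 0.6, tolerance = 1e-12)
})
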