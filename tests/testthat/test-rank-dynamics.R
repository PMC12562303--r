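test_that("stationary distribution counts patterns correctly", {
  expect_identical(estimate_stationary(fake_symbols(rep(1L, 50))),
                   c(1, 0, 0, 0, 0, 0))
  alt <- fake_symbols(rep(c(1L, 6L), 50))
  expect_identical(estimate_stationary(alt), c(0.5, 0, 0, 0, 0, 0.5))

  set.seed(7)
  iid <- fake_symbols(sample.int(6, 1e5, replace = TRUE))
  expect_true(all(abs(estimate_stationary(iid) - 1 / 6) < 0.01))
})

test_that("transition estimates at lag m count pairs", {
  alt <- fake_symbols(rep(c(1L, 6L), 50))
  t1 <- estimate_transition(alt, 1)
  expect_equal(t1$joint[1, 6], 50 / 99)
  expect_equal(t1$joint[6, 1], 49 / 99)
  expect_equal(sum(t1$joint), 1, tolerance = 1e-12)
  expect_equal(t1$conditional[1, 6], 1)
  expect_equal(t1$conditional[6, 1], 1)

  t2 <- estimate_transition(alt, 2)
  expect_equal(t2$joint[1, 1], 0.5)
  expect_equal(t2$joint[6, 6], 0.5)

  set.seed(11)
  rnd <- fake_symbols(sample.int(6, 500, replace = TRUE))
  for (m in c(1, 3, 10)) {
    expect_equal(sum(estimate_transition(rnd, m)$joint), 1,
                 tolerance = 1e-12)
  }
  expect_error(estimate_transition(rnd, 0), "1..")
  expect_error(estimate_transition(rnd, 500), "1..")
})

test_that("alternating sequence reproduces the hand-computed autocovariance", {
  alt <- fake_symbols(rep(c(1L, 6L), 50))
  rc <- rank_autocovariance(alt, n_lags = 3, method = "direct",
                            normalization = "unbiased")
  expect_equal(rc$mean_rank, 3.5)
  expect_equal(rc$variance, 6.25)
  expect_equal(rc$cov[1], 6.25)
  # lag 1: 50 pairs (1,6), 49 pairs (6,1) -> 6 - 3.5^2 = -6.25 exactly
  expect_equal(rc$cov[2], -6.25)
  expect_equal(rc$cov[3], 6.25)
})

test_that("Cov(0) equals Var(S) exactly for both estimators", {
  set.seed(3)
  for (gen in list(function() sample.int(6, 400, replace = TRUE),
                   function() rep(c(1L, 3L, 6L), 100))) {
    sym <- fake_symbols(gen())
    for (meth in c("markov", "direct")) {
      rc <- rank_autocovariance(sym, n_lags = 16, method = meth)
      expect_identical(rc$cov[1], rc$variance)
      expect_equal(rc$variance,
                   mean(as.numeric(sym$codes)^2) - mean(sym$codes)^2,
                   tolerance = 1e-12)
    }
  }
})

test_that("direct estimator equals the naive sample-autocovariance oracle", {
  set.seed(5)
  cases <- list(
    sample.int(6, 200, replace = TRUE),
    rep(c(1L, 6L), 30),
    suppressWarnings(symbolize(logistic_map(r = 4, T = 300, seed = 1),
                               D = 3, tau = 1))$codes
  )
  for (codes in cases) {
    sym <- fake_symbols(codes)
    for (norm in c("unbiased", "biased")) {
      rc <- rank_autocovariance(sym, n_lags = 20, method = "direct",
                                normalization = norm)
      for (m in c(0, 1, 2, 5, 19)) {
        expect_equal(rc$cov[m + 1],
                     direct_autocov_oracle(codes, m, norm),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("constant and iid sequences have degenerate/vanishing covariance", {
  rc <- rank_autocovariance(fake_symbols(rep(4L, 80)), n_lags = 10,
                            method = "direct")
  expect_true(all(abs(rc$cov) < 1e-9))  # zero up to FFT roundoff

  set.seed(9)
  iid <- fake_symbols(sample.int(6, 1e5, replace = TRUE))
  rc <- rank_autocovariance(iid, n_lags = 51, method = "direct")
  expect_true(all(abs(rc$cov[-1]) < 0.1))
})

test_that("markov covariance decays for an ergodic aperiodic chain", {
  sym <- symbolize(logistic_map(r = 4, T = 2000, seed = 2), D = 3, tau = 1)
  rc <- rank_autocovariance(sym, n_lags = 200, method = "markov")
  # geometric decay at the chain's spectral gap down to the small
  # plug-in bias floor of the literal equation
  expect_true(all(abs(rc$cov[100:200]) < 1e-3))
  expect_lt(max(abs(rc$cov[100:200])), max(abs(rc$cov[2:10])) / 100)
  expect_gt(abs(rc$cov[2]), 0.1)
})

test_that("markov and direct estimators agree at small lags on long data", {
  sym <- symbolize(logistic_map(r = 4, T = 20000, seed = 4), D = 3, tau = 1)
  a <- rank_autocovariance(sym, n_lags = 3, method = "markov")
  b <- rank_autocovariance(sym, n_lags = 3, method = "direct",
                           normalization = "unbiased")
  expect_equal(a$cov[2], b$cov[2], tolerance = 5e-3)
})

test_that("transition matrices are row-stochastic on occupied rows", {
  sym <- symbolize(logistic_map(r = 3.8, T = 1000, seed = 6), D = 3, tau = 1)
  tr <- estimate_transition(sym, 1)
  rs <- rowSums(tr$conditional[tr$occupied, , drop = FALSE])
  expect_true(all(abs(rs - 1) < 1e-12))
})

test_that("the first-order diagnostic flags higher-order structure", {
  # ordinal sequences are not exactly first order: powered vs counted
  # matrices differ measurably at lag 2
  sym <- symbolize(logistic_map(r = 4, T = 5000, seed = 8), D = 3, tau = 1)
  d <- markov_order_diagnostic(sym, 2)
  expect_true(is.finite(d$max_abs_diff))
  # but for a genuinely 2-state alternation they agree exactly
  alt <- fake_symbols(rep(c(1L, 6L), 100))
  expect_lt(markov_order_diagnostic(alt, 2)$max_abs_diff, 1e-12)
})
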