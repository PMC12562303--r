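# helpers to fabricate spectra/ensembles with known z-scores
fake_spectrum <- function(values, freq = NULL) {
  n <- length(values)
  if (is.null(freq)) freq <- (seq_len(n) - 1) / (2 * (n - 1))
  structure(list(freq = freq, values = values, n_lags = 8L,
                 n_freq = n, taper = "none", D = 3L, tau = 1L,
                 method = "markov", normalization = NA),
            class = "ordinal_spectrum")
}
fake_ensemble <- function(mean, sd, freq = NULL, spectra = NULL) {
  n <- length(mean)
  if (is.null(freq)) freq <- (seq_len(n) - 1) / (2 * (n - 1))
  structure(list(freq = freq, mean = mean, sd = sd,
                 lower = mean - 2 * sd, upper = mean + 2 * sd,
                 n_surrogates = if (is.null(spectra)) 100L else ncol(spectra),
                 n_failed = 0L, D = 3L, tau = 1L, n_lags = 8L,
                 n_freq = n, method = "markov", normalization = "biased",
                 spectra = spectra),
            class = "os_ensemble")
}

test_that("a spectrum equal to the surrogate mean is never significant", {
  mu <- c(3, 2, 1, 2, 3)
  rep <- significance(fake_spectrum(mu), fake_ensemble(mu, rep(1, 5)))
  expect_true(all(rep$z == 0))
  expect_true(all(rep$p == 1))
  expect_identical(rep$verdict, "null_not_rejected")
  expect_identical(nrow(rep$bands), 0L)
})

test_that("BH adjustment matches the hand-computed example", {
  # choose spectrum values whose two-sided normal p-values are exactly
  # 0.01, 0.02, 0.20
  p_target <- c(0.01, 0.02, 0.20)
  os <- fake_spectrum(qnorm(1 - p_target / 2))
  rep <- significance(os, fake_ensemble(rep(0, 3), rep(1, 3)))
  expect_equal(rep$p, p_target, tolerance = 1e-12)
  expect_equal(rep$q, c(0.03, 0.03, 0.20), tolerance = 1e-12)
  expect_equal(rep$q, bh_oracle(rep$p), tolerance = 1e-12)
  expect_true(all(rep$q >= rep$p))
})

test_that("significant bands are maximal runs of adjacent frequencies", {
  z <- c(0, 5, 6, 0, 0, 7, 0, 8)
  rep <- significance(fake_spectrum(z), fake_ensemble(rep(0, 8), rep(1, 8)))
  expect_identical(rep$verdict, "null_rejected")
  expect_identical(rep$bands$idx_lo, c(2L, 6L, 8L))
  expect_identical(rep$bands$idx_hi, c(3L, 6L, 8L))
  expect_equal(rep$bands$f_lo, rep$freq[c(2, 6, 8)])
})

test_that("degenerate ensembles and mismatched grids error", {
  os <- fake_spectrum(1:4)
  expect_error(significance(os, fake_ensemble(rep(0, 4), c(1, 0, 1, 1))),
               "degenerate")
  bad <- fake_ensemble(rep(0, 4), rep(1, 4), freq = c(0, 0.1, 0.2, 0.3))
  expect_error(significance(os, bad), "frequency grid")
})

test_that("rank-based p-values agree in order with normal p-values", {
  set.seed(31)
  spectra <- matrix(rnorm(64 * 200, mean = 5), 64, 200)
  ens <- fake_ensemble(rowMeans(spectra), apply(spectra, 1, sd),
                       spectra = spectra)
  os <- fake_spectrum(c(rep(5, 60), 9, 9, 5, 5)[1:64])
  a <- significance(os, ens, p_method = "normal")
  b <- significance(os, ens, p_method = "rank")
  # data above every surrogate: rank p sits at its resolution floor
  expect_equal(b$p[61], 2 / 201, tolerance = 1e-12)
  expect_true(all(b$p >= 2 / 201))
  expect_identical(a$verdict, "null_rejected")
  # the two p-value variants agree on which frequencies stand out
  expect_setequal(order(a$p)[1:2], order(b$p)[1:2])
})

test_that("ensembles aggregate surrogate spectra on one grid", {
  x <- gaussian_noise(400, seed = 17)
  ens <- build_ensemble(x, D = 3, tau = 1, n_surrogates = 30, seed = 17,
                        n_freq = 64)
  expect_identical(ens$n_surrogates, 30L)
  expect_identical(dim(ens$spectra), c(64L, 30L))
  expect_true(all(ens$sd > 0))
  # for Gaussian noise the data spectrum sits inside the ensemble spread
  sym <- symbolize(x, 3, 1)
  os <- ordinal_spectrum(rank_autocovariance(sym), n_freq = 64)
  expect_true(all(abs(os$values - ens$mean) < 6 * ens$sd))
  expect_error(build_ensemble(x, 3, 1, n_surrogates = 1), "at least 2")
})

test_that("the end-to-end test is deterministic given a seed", {
  x <- logistic_map(r = 3.8, T = 600, seed = 23)
  a <- ordinal_spectrum_test(x, D = 3, tau = 1, n_surrogates = 40, seed = 11)
  b <- ordinal_spectrum_test(x, D = 3, tau = 1, n_surrogates = 40, seed = 11)
  expect_identical(a$report$q, b$report$q)
  expect_identical(a$verdict, b$verdict)
  expect_identical(a$config$T, 600L)
  expect_identical(a$config$n_lags, min(600L - 2L, 512L))
})

test_that("tau = 'auto' wires the ACF delay into the pipeline", {
  x <- sin(2 * pi * (1:800) / 40) + gaussian_noise(800, seed = 3) * 0.01
  tst <- ordinal_spectrum_test(x, D = 3, tau = "auto", n_surrogates = 20,
                               seed = 2)
  expect_identical(tst$config$tau, select_delay(x))
})

test_that("unsupported embeddings are rejected up front", {
  x <- gaussian_noise(300, seed = 1)
  expect_error(ordinal_spectrum_test(x, D = 8, tau = 1), "2..7")
  expect_error(ordinal_spectrum_test(x, D = 3, tau = 0), "positive")
})
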