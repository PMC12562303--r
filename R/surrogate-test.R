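# Surrogate ensemble, per-frequency z-test, FDR correction, and the
# end-to-end ordinal-spectrum test.

#' Ensemble of ordinal spectra from IAAFT surrogates
#'
#' Draws `n_surrogates` IAAFT surrogates of the series and pushes each
#' through the same pipeline as the data (symbolize with identical `D`,
#' `tau`, rank autocovariance, ordinal spectrum), then summarizes the
#' ensemble per frequency.
#'
#' @param x Numeric time series.
#' @param D,tau Embedding parameters, matching those used for the data.
#' @param n_surrogates Ensemble size (default 500), at least 2.
#' @param n_freq,n_lags,method,normalization,tie_rule Pipeline options,
#'   see [rank_autocovariance()] and [ordinal_spectrum()].
#' @param max_iter IAAFT iteration cap.
#' @param seed Optional integer seed; surrogate b gets a child seed
#'   derived deterministically from it.
#' @param keep_spectra Keep the full `n_freq x n_surrogates` matrix
#'   (default `TRUE`; needed for rank-based p-values).
#' @return Object of class `"os_ensemble"`: list with `freq`, `mean`,
#'   `sd`, `lower`/`upper` (5th/95th percentiles), `n_surrogates`,
#'   pipeline metadata, and optionally `spectra`.
#' @export
build_ensemble <- function(x, D, tau, n_surrogates = 500L, n_freq = 256L,
                           n_lags = NULL, method = "markov",
                           normalization = "biased",
                           tie_rule = "stable", max_iter = 100L,
                           seed = NULL, keep_spectra = TRUE) {
  check_series(x, min_len = 8L, what = "time series")
  check_embedding(D, tau)
  if (n_surrogates < 2L) stop("n_surrogates must be at least 2", call. = FALSE)
  L <- length(x) - (D - 1L) * tau
  if (is.null(n_lags)) n_lags <- min(L, 512L)
  seeds <- derive_seeds(seed, n_surrogates)
  spectra <- matrix(NA_real_, n_freq, n_surrogates)
  failed <- 0L
  for (b in seq_len(n_surrogates)) {
    ok <- tryCatch({
      xs <- iaaft(x, max_iter = max_iter, seed = seeds[[b]])
      sym <- suppressWarnings(
        symbolize(xs, D = D, tau = tau, tie_rule = tie_rule,
                  seed = seeds[[b]]))
      rc <- rank_autocovariance(sym, n_lags = n_lags, method = method,
                                normalization = normalization)
      spectra[, b] <- ordinal_spectrum(rc, n_freq = n_freq)$values
      TRUE
    }, error = function(e) FALSE)
    if (!ok) failed <- failed + 1L
  }
  if (failed > 0.1 * n_surrogates) {
    stop(failed, " of ", n_surrogates, " surrogates failed", call. = FALSE)
  }
  if (failed > 0L) spectra <- spectra[, !is.na(spectra[1L, ]), drop = FALSE]
  structure(
    list(freq = os_cosine_basis(n_lags, n_freq)$freq,
         mean = rowMeans(spectra),
         sd = apply(spectra, 1, stats::sd),
         lower = apply(spectra, 1, stats::quantile, probs = 0.05),
         upper = apply(spectra, 1, stats::quantile, probs = 0.95),
         n_surrogates = ncol(spectra), n_failed = failed,
         D = as.integer(D), tau = as.integer(tau), n_lags = n_lags,
         n_freq = as.integer(n_freq), method = method,
         normalization = normalization,
         spectra = if (keep_spectra) spectra),
    class = "os_ensemble"
  )
}

#' @export
print.os_ensemble <- function(x, ...) {
  cat("IAAFT surrogate ensemble:", x$n_surrogates, "spectra on",
      x$n_freq, "frequencies\n")
  invisible(x)
}

# maximal runs of TRUE in `mask` -> data.frame of frequency intervals
significant_bands <- function(freq, mask) {
  if (!any(mask)) {
    return(data.frame(f_lo = numeric(0), f_hi = numeric(0),
                      idx_lo = integer(0), idx_hi = integer(0)))
  }
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(f_lo = freq[starts[keep]], f_hi = freq[ends[keep]],
             idx_lo = starts[keep], idx_hi = ends[keep])
}

#' Per-frequency significance of an ordinal spectrum
#'
#' Compares the data's ordinal spectrum against the surrogate ensemble
#' with a z-score per frequency, `z(f) = (OS(f) - mu_s(f)) / sigma_s(f)`,
#' two-sided p-values, and Benjamini-Hochberg false-discovery-rate
#' adjustment across the frequency grid.  The null hypothesis -- the
#' series is a static transform of a linearly correlated stochastic
#' process -- is rejected when any adjusted p-value falls below `alpha`.
#'
#' @param os An `"ordinal_spectrum"` of the data.
#' @param ens An `"os_ensemble"` on the same frequency grid.
#' @param alpha FDR level (default 0.05).
#' @param p_method `"normal"` (default): two-sided Gaussian p-values from
#'   the z-scores.  `"rank"`: two-sided ensemble-percentile p-values,
#'   robust when surrogate spectra are visibly non-Gaussian (requires
#'   the ensemble to have kept its spectra).
#' @return Object of class `"os_significance"`: list with `freq`, `z`,
#'   `p`, `q`, `significant` (logical, `q < alpha`), `bands` (maximal
#'   runs of significant adjacent frequencies), `verdict`
#'   (`"null_rejected"` or `"null_not_rejected"`) and `alpha`.
#' @export
significance <- function(os, ens, alpha = 0.05,
                         p_method = c("normal", "rank")) {
  stopifnot(inherits(os, "ordinal_spectrum"), inherits(ens, "os_ensemble"))
  p_method <- match.arg(p_method)
  if (length(os$freq) != length(ens$freq) ||
      max(abs(os$freq - ens$freq)) > 1e-12) {
    stop("spectrum and ensemble must share one frequency grid", call. = FALSE)
  }
  if (any(ens$sd <= 0)) {
    stop("degenerate surrogate ensemble: zero spectral variance at some ",
         "frequencies", call. = FALSE)
  }
  z <- (os$values - ens$mean) / ens$sd
  p <- switch(p_method,
    normal = 2 * stats::pnorm(-abs(z)),
    rank = {
      if (is.null(ens$spectra)) {
        stop("rank p-values need an ensemble built with keep_spectra = TRUE",
             call. = FALSE)
      }
      ns <- ncol(ens$spectra)
      lo <- rowSums(ens$spectra <= os$values)  # surrogates at or below data
      hi <- rowSums(ens$spectra >= os$values)
      pmin(1, 2 * (pmin(lo, hi) + 1) / (ns + 1))
    })
  q <- stats::p.adjust(p, method = "BH")
  sig <- q < alpha
  structure(
    list(freq = os$freq, z = z, p = p, q = q, significant = sig,
         bands = significant_bands(os$freq, sig),
         verdict = if (any(sig)) "null_rejected" else "null_not_rejected",
         alpha = alpha, p_method = p_method),
    class = "os_significance"
  )
}

#' @export
print.os_significance <- function(x, ...) {
  cat("Ordinal-spectrum surrogate test:", x$verdict, "\n")
  cat("  min FDR-adjusted p =", format(min(x$q), digits = 3),
      " (alpha =", x$alpha, ",", x$p_method, "p-values )\n")
  if (nrow(x$bands)) {
    cat("  significant frequency bands:\n")
    for (i in seq_len(nrow(x$bands))) {
      cat(sprintf("    [%.4f, %.4f]\n", x$bands$f_lo[i], x$bands$f_hi[i]))
    }
  }
  invisible(x)
}

#' Ordinal-spectrum surrogate test, end to end
#'
#' Runs the whole procedure: (1-2) symbolize the series with embedding
#' `(D, tau)`; (3-4) estimate the rank autocovariance of the integer
#' pattern codes; (5) transform it into the ordinal spectrum; (6) build
#' an IAAFT surrogate ensemble, z-test every frequency and control the
#' false discovery rate.  Rejection localizes frequency bands whose
#' ordinal structure cannot be explained by a linearly correlated
#' stochastic process, the signature used to flag chaotic dynamics.
#'
#' @param x Numeric time series.
#' @param D Embedding dimension (default 3).
#' @param tau Embedding delay in samples, or `"auto"` to pick it from the
#'   autocorrelation function via [select_delay()].
#' @param n_surrogates IAAFT ensemble size (default 500).
#' @param alpha FDR level (default 0.05).
#' @param n_freq,n_lags,method,normalization,tie_rule,max_iter,p_method
#'   Passed through to the pipeline stages.
#' @param seed Optional integer seed controlling surrogate generation
#'   (and jitter, if used).
#' @return Object of class `"os_test"`: list with `report` (the
#'   `"os_significance"`), `verdict`, `symbols`, `autocov`, `spectrum`,
#'   `ensemble` (spectra matrix dropped), `shuffled` = NULL placeholder
#'   and `config` echoing every parameter.
#' @examples
#' \donttest{
#' x <- logistic_map(r = 4, T = 2000, seed = 7)
#' tst <- ordinal_spectrum_test(x, D = 3, tau = 1, n_surrogates = 100,
#'                              seed = 7)
#' print(tst)
#' }
#' @export
ordinal_spectrum_test <- function(x, D = 3L, tau = 1L, n_surrogates = 500L,
                                  alpha = 0.05, n_freq = 256L, n_lags = NULL,
                                  method = "markov",
                                  normalization = "biased",
                                  tie_rule = "stable", max_iter = 100L,
                                  p_method = "normal", seed = NULL) {
  check_series(x, min_len = 8L, what = "time series")
  if (identical(tau, "auto")) tau <- select_delay(x)
  check_embedding(D, tau)
  sym <- symbolize(x, D = D, tau = tau, tie_rule = tie_rule, seed = seed)
  if (is.null(n_lags)) n_lags <- min(sym$L, 512L)
  rc <- rank_autocovariance(sym, n_lags = n_lags, method = method,
                            normalization = normalization)
  os <- ordinal_spectrum(rc, n_freq = n_freq)
  ens <- build_ensemble(x, D = D, tau = tau, n_surrogates = n_surrogates,
                        n_freq = n_freq, n_lags = n_lags, method = method,
                        normalization = normalization, tie_rule = tie_rule,
                        max_iter = max_iter, seed = seed,
                        keep_spectra = identical(p_method, "rank"))
  rep <- significance(os, ens, alpha = alpha, p_method = p_method)
  ens$spectra <- NULL
  structure(
    list(report = rep, verdict = rep$verdict, symbols = sym, autocov = rc,
         spectrum = os, ensemble = ens,
         config = list(T = length(x), D = as.integer(D),
                       tau = as.integer(tau),
                       n_surrogates = as.integer(n_surrogates),
                       alpha = alpha, n_freq = as.integer(n_freq),
                       n_lags = as.integer(n_lags), method = method,
                       normalization = normalization, tie_rule = tie_rule,
                       max_iter = as.integer(max_iter),
                       p_method = p_method,
                       seed = if (is.null(seed)) NA_integer_
                              else as.integer(seed))),
    class = "os_test"
  )
}

#' @export
print.os_test <- function(x, ...) {
  cat("Ordinal spectrum test (T =", x$config$T, ", D =", x$config$D,
      ", tau =", x$config$tau, ",", x$config$n_surrogates,
      "IAAFT surrogates)\n")
  print(x$report)
  invisible(x)
}
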