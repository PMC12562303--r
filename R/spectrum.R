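# Ordinal spectrum: cosine transform of the rank autocovariance.

# Cosine basis for evaluating the spectrum on a uniform grid in [0, 0.5].
# Returns list(freq, C) with C of dimension n_freq x (n_lags - 1), so
# OS = cov[1] + 2 * C %*% cov[-1].
os_cosine_basis <- function(n_lags, n_freq) {
  freq <- (seq_len(n_freq) - 1) / (2 * (n_freq - 1))
  m <- seq_len(max(n_lags - 1L, 0L))
  C <- if (length(m)) cos(2 * pi * outer(freq, m)) else
    matrix(0, n_freq, 0)
  list(freq = freq, C = C)
}

#' Ordinal spectrum from a rank autocovariance
#'
#' Evaluates `OS(f) = sum_{m=-(N-1)}^{N-1} Cov(m) exp(-i 2 pi f m)` on a
#' uniform grid of normalized frequencies in `[0, 0.5]` (cycles per
#' symbol).  Because `Cov(-m) = Cov(m)` for a stationary sequence, the
#' transform collapses to the exactly real cosine series
#' `Cov(0) + 2 sum_{m>=1} Cov(m) cos(2 pi f m)`.
#'
#' @param cov A `"rank_autocov"` from [rank_autocovariance()].
#' @param n_freq Number of grid points (default 256), `f_k =
#'   k / (2 (n_freq - 1))`, `k = 0, ..., n_freq - 1`.
#' @param taper `"none"` (default; the plain transform) or `"bartlett"`
#'   to downweight high lags (`w_m = 1 - m/N`) for variance reduction.
#' @return Object of class `"ordinal_spectrum"`: list with `freq`,
#'   `values`, `n_lags`, `n_freq`, `taper` plus the embedding metadata
#'   carried over from `cov`.
#' @examples
#' s <- symbolize(logistic_map(r = 4, T = 1000, seed = 1), D = 3, tau = 1)
#' os <- ordinal_spectrum(rank_autocovariance(s))
#' plot(os$freq, os$values, type = "l", xlab = "normalized frequency")
#' @export
ordinal_spectrum <- function(cov, n_freq = 256L,
                             taper = c("none", "bartlett")) {
  stopifnot(inherits(cov, "rank_autocov"))
  taper <- match.arg(taper)
  if (n_freq < 2L) stop("n_freq must be at least 2", call. = FALSE)
  if (!all(is.finite(cov$cov))) {
    stop("non-finite values in the autocovariance", call. = FALSE)
  }
  cv <- cov$cov
  if (taper == "bartlett" && cov$n_lags > 1L) {
    m <- 0:(cov$n_lags - 1L)
    cv <- cv * (1 - m / cov$n_lags)
  }
  basis <- os_cosine_basis(cov$n_lags, n_freq)
  values <- cv[1L] + if (cov$n_lags > 1L) 2 * drop(basis$C %*% cv[-1L]) else 0
  structure(
    list(freq = basis$freq, values = values, n_lags = cov$n_lags,
         n_freq = as.integer(n_freq), taper = taper,
         D = cov$D, tau = cov$tau, method = cov$method,
         normalization = cov$normalization),
    class = "ordinal_spectrum"
  )
}

#' @export
print.ordinal_spectrum <- function(x, ...) {
  cat("Ordinal spectrum on", x$n_freq, "frequencies in [0, 0.5] (N =",
      x$n_lags, "lags)\n")
  pk <- which.max(x$values)
  cat("  peak", format(x$values[pk], digits = 4), "at f =",
      format(x$freq[pk], digits = 4), "\n")
  invisible(x)
}

#' Reference spectrum from shuffled symbol sequences
#'
#' Randomly permutes the symbol codes (destroying all temporal order
#' while keeping the pattern histogram) and averages the resulting
#' ordinal spectra.  A shuffled sequence is decorrelated, so its mean
#' spectrum is flat at the level of the rank variance regardless of the
#' original dynamics -- a useful visual baseline, but not a substitute
#' for the surrogate test.
#'
#' @param sym A `"symbol_sequence"`.
#' @param n_shuffles Number of random permutations (default 200).
#' @param n_freq,n_lags,method,normalization Passed to the spectrum
#'   pipeline.
#' @param seed Optional integer seed for reproducible shuffles.
#' @return List with `freq`, `mean`, `lower`, `upper` (5th/95th
#'   percentile envelope) and `n_shuffles`.
#' @export
shuffled_symbol_spectrum <- function(sym, n_shuffles = 200L, n_freq = 256L,
                                     n_lags = NULL, method = "markov",
                                     normalization = "biased",
                                     seed = NULL) {
  stopifnot(inherits(sym, "symbol_sequence"))
  if (n_shuffles < 1L) stop("n_shuffles must be at least 1", call. = FALSE)
  if (is.null(n_lags)) n_lags <- min(sym$L, 512L)
  spectra <- with_seed(seed, {
    out <- matrix(NA_real_, n_freq, n_shuffles)
    for (b in seq_len(n_shuffles)) {
      sh <- sym
      sh$codes <- sample(sym$codes)
      rc <- rank_autocovariance(sh, n_lags = n_lags, method = method,
                                normalization = normalization)
      out[, b] <- ordinal_spectrum(rc, n_freq = n_freq)$values
    }
    out
  })
  freq <- os_cosine_basis(n_lags, n_freq)$freq
  list(freq = freq,
       mean = rowMeans(spectra),
       lower = apply(spectra, 1, stats::quantile, probs = 0.05),
       upper = apply(spectra, 1, stats::quantile, probs = 0.95),
       n_shuffles = as.integer(n_shuffles))
}
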