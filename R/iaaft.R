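# Iterative Amplitude Adjusted Fourier Transform surrogates.

#' IAAFT surrogate of a time series
#'
#' Generates one surrogate that keeps the amplitude distribution of the
#' original series exactly (its values are a permutation of the
#' original's) and matches its periodogram iteratively, while all
#' higher-order temporal structure is destroyed.  These are the draws
#' from the null hypothesis of a monotonically transformed linear
#' stochastic process used by [ordinal_spectrum_test()].
#'
#' Starting from a random permutation, each iteration (a) imposes the
#' original Fourier amplitudes while keeping the current phases, then
#' (b) rank-orders the result back onto the original values.  Iteration
#' stops when the rank ordering reaches a fixed point or after
#' `max_iter` iterations; the final step is always the amplitude
#' adjustment, so the value multiset matches exactly.
#'
#' @param x Numeric time series, length at least 8.
#' @param max_iter Iteration cap (default 100).
#' @param seed Optional integer seed; same seed, same surrogate.
#' @return Numeric vector of the same length as `x`.  A constant series
#'   is returned unchanged with a warning.
#' @references Schreiber T., Schmitz A. (1996) Improved surrogate data
#'   for nonlinearity tests. Physical Review Letters 77, 635.
#' @export
iaaft <- function(x, max_iter = 100L, seed = NULL) {
  check_series(x, min_len = 8L, what = "time series")
  if (max_iter < 1L) stop("max_iter must be at least 1", call. = FALSE)
  n <- length(x)
  if (diff(range(x)) == 0) {
    warning("constant series: surrogate equals the original", call. = FALSE)
    return(x)
  }
  amp_sorted <- sort(x)
  target_amp <- Mod(stats::fft(x))
  s <- with_seed(seed, sample(x))
  prev_ord <- NULL
  for (it in seq_len(max_iter)) {
    # spectrum adjustment: rescale Fourier amplitudes to the target
    # while keeping the current phases
    sp <- stats::fft(s)
    s2 <- Re(stats::fft(sp * (target_amp / pmax(Mod(sp), 1e-300)),
                        inverse = TRUE))
    # amplitude adjustment: rank-order back onto the original values
    o <- order(s2)
    s[o] <- amp_sorted
    if (!is.null(prev_ord) && identical(o, prev_ord)) break
    prev_ord <- o
  }
  s
}
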