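# Ordinal-pattern (Bandt-Pompe) symbolization.
#
# A window (x_t, x_{t+tau}, ..., x_{t+(D-1)tau}) is mapped to the
# permutation pi of (0, ..., D-1) that sorts it ascending, and pi to its
# 1-based lexicographic rank among all D! permutations (via the Lehmer
# code).  The all-ascending window gets code 1 and the all-descending
# window code D!, so the two monotone patterns sit at the extremes of the
# integer coding -- the property the rank autocovariance relies on.

# Cache of per-D lookup tables: rank-vector key -> lexicographic code.
.ord_cache <- new.env(parent = emptyenv())

# All permutations of 0..(D-1) in lexicographic order, as a D! x D matrix.
perms_lex <- function(D) {
  if (D == 1L) return(matrix(0L, 1L, 1L))
  sub <- perms_lex(D - 1L)
  out <- matrix(0L, nrow(sub) * D, D)
  row <- 0L
  for (first in 0L:(D - 1L)) {
    rest <- setdiff(0L:(D - 1L), first)
    blk <- matrix(rest[sub + 1L], nrow(sub), D - 1L)
    out[row + seq_len(nrow(sub)), ] <- cbind(first, blk)
    row <- row + nrow(sub)
  }
  out
}

# Lookup table translating the within-window rank vector (r_1..r_D, each
# in 1..D, encoded in base D) to the lexicographic code of the sorting
# permutation.  Size D^D integers; D <= 7 keeps this below 1 MB x 8.
ord_lut <- function(D) {
  key <- paste0("D", D)
  if (!is.null(.ord_cache[[key]])) return(.ord_cache[[key]])
  P <- perms_lex(D)
  pow <- D^(0:(D - 1))
  lut <- integer(D^D)
  for (j in seq_len(nrow(P))) {
    o <- P[j, ] + 1L            # order vector: o[i] = index of i-th smallest
    r <- integer(D); r[o] <- seq_len(D)   # rank vector = inverse permutation
    lut[sum((r - 1L) * pow) + 1L] <- j
  }
  .ord_cache[[key]] <- list(lut = lut, pow = pow)
  .ord_cache[[key]]
}

# Rank vector of each row of the window matrix W (L x D).  Ties are
# broken by temporal index, earlier sample first ("stable" rule).
window_ranks <- function(W) {
  D <- ncol(W)
  R <- matrix(1L, nrow(W), D)
  for (k in seq_len(D)) {
    for (j in seq_len(D)) {
      if (j == k) next
      R[, k] <- R[, k] + if (j < k) (W[, j] <= W[, k]) else (W[, j] < W[, k])
    }
  }
  R
}

#' Ordinal-pattern code of a single window
#'
#' Returns the 1-based lexicographic rank of the permutation that sorts
#' `window` into ascending order.  A strictly increasing window maps to
#' code 1 and a strictly decreasing one to code `factorial(D)`.
#'
#' @param window Numeric vector of length `D` (2 to 7), all values finite.
#' @param tie_rule `"stable"` (equal values keep temporal order, default)
#'   or `"jitter"` (break ties by adding seeded uniform noise of magnitude
#'   `1e-12 * diff(range(window))`).
#' @param seed Optional integer seed, used only by `tie_rule = "jitter"`.
#' @return Integer code in `1..factorial(D)`.
#' @examples
#' rank_permutation(c(1, 2, 3))  # 1
#' rank_permutation(c(3, 2, 1))  # 6
#' @seealso [symbolize()] for whole series.
#' @export
rank_permutation <- function(window, tie_rule = c("stable", "jitter"),
                             seed = NULL) {
  tie_rule <- match.arg(tie_rule)
  D <- length(window)
  if (D < 2 || D > 7) stop("window length (D) must be in 2..7", call. = FALSE)
  if (!is.numeric(window) || !all(is.finite(window))) {
    stop("window must contain only finite numeric values", call. = FALSE)
  }
  if (tie_rule == "jitter" && anyDuplicated(window)) {
    rng <- diff(range(window))
    amp <- 1e-12 * if (rng > 0) rng else 1
    window <- window + with_seed(seed, stats::runif(D, -amp, amp))
  }
  tab <- ord_lut(D)
  r <- window_ranks(matrix(window, 1L, D))
  tab$lut[sum((r - 1L) * tab$pow) + 1L]
}

#' Symbolize a time series into ordinal-pattern codes
#'
#' Slides a window of `D` samples spaced `tau` apart along the series and
#' encodes each window with [rank_permutation()].  The result is the
#' symbol sequence on which all downstream ordinal-spectrum quantities
#' are computed.  Symbolization is invariant under strictly increasing
#' transformations of the data.
#'
#' @param x Numeric vector, the time series (finite values, length
#'   at least `(D-1)*tau + 2`).
#' @param D Embedding dimension (pattern length), integer in 2..7.
#' @param tau Embedding delay in samples, positive integer.
#' @param tie_rule,seed See [rank_permutation()].  Under `"jitter"` the
#'   noise amplitude is scaled by the range of the full series.
#' @return An object of class `"symbol_sequence"`: a list with `codes`
#'   (integer vector of length `L = length(x) - (D-1)*tau`), `D`, `tau`,
#'   `L` and `tie_rule`.
#' @details A warning is emitted when `length(x) < factorial(D + 1)`,
#'   the customary minimum for estimating the pattern distribution
#'   reliably; the sequence is still produced.
#' @examples
#' s <- symbolize(sin(1:200 / 5), D = 3, tau = 1)
#' table(s$codes)
#' @export
symbolize <- function(x, D = 3L, tau = 1L, tie_rule = c("stable", "jitter"),
                      seed = NULL) {
  tie_rule <- match.arg(tie_rule)
  check_embedding(D, tau)
  D <- as.integer(D); tau <- as.integer(tau)
  check_series(x, min_len = (D - 1L) * tau + 2L, what = "time series")
  T <- length(x)
  if (!check_length(T, D)) {
    warning("series length ", T, " is below the recommended minimum (D+1)! = ",
            factorial(D + 1), " for D = ", D, call. = FALSE)
  }
  if (tie_rule == "jitter") {
    rng <- diff(range(x))
    amp <- 1e-12 * if (rng > 0) rng else 1
    x <- x + with_seed(seed, stats::runif(T, -amp, amp))
  }
  L <- T - (D - 1L) * tau
  W <- matrix(0, L, D)
  for (k in seq_len(D)) W[, k] <- x[seq_len(L) + (k - 1L) * tau]
  tab <- ord_lut(D)
  key <- as.integer((window_ranks(W) - 1L) %*% tab$pow)
  structure(
    list(codes = tab$lut[key + 1L], D = D, tau = tau, L = L,
         tie_rule = tie_rule),
    class = "symbol_sequence"
  )
}

#' @export
print.symbol_sequence <- function(x, ...) {
  cat("Ordinal symbol sequence: L =", x$L, " (D =", x$D, ", tau =", x$tau,
      ")\n")
  cat("  distinct patterns observed:", length(unique(x$codes)), "of",
      factorial(x$D), "\n")
  invisible(x)
}

#' Minimum-length rule for ordinal analysis
#'
#' Checks the customary sample-size condition `T >= (D+1)!` for a stable
#' estimate of the ordinal-pattern distribution.
#'
#' @param T Series length.
#' @param D Embedding dimension.
#' @return `TRUE` when the condition holds.
#' @export
check_length <- function(T, D) {
  T >= factorial(D + 1)
}

#' Select the embedding delay from the autocorrelation function
#'
#' Picks `tau` as the smaller of the first local minimum and the first
#' zero crossing of the sample autocorrelation function; when the ACF
#' decreases monotonically and stays positive over the inspected lags,
#' the folding time (first lag with `rho <= 1/e`) is used instead.
#'
#' @param x Numeric time series.
#' @param max_lag Largest lag to inspect; must be below `length(x)/2`.
#'   Default `min(floor(length(x)/2) - 1, 100)`.
#' @return Integer delay, at least 1.  If no criterion is met within
#'   `max_lag`, returns `max_lag` with a warning.
#' @details A zero crossing between consecutive lags is attributed to the
#'   lag whose `|rho|` is smaller, so e.g. a sinusoid of period P yields
#'   `tau = P/4` even when the sample ACF at that lag is marginally
#'   positive.
#' @export
select_delay <- function(x, max_lag = NULL) {
  check_series(x, what = "time series")
  T <- length(x)
  if (is.null(max_lag)) max_lag <- max(1L, min(floor(T / 2) - 1L, 100L))
  if (max_lag >= T / 2) stop("max_lag must be below length(x)/2", call. = FALSE)
  rho <- stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  # rho[1] is lag 0 == 1
  lag_of <- function(i) i - 1L  # index into rho -> lag

  # first zero crossing: first sign change relative to rho(0) = 1
  zc <- NA_integer_
  for (i in 2:(max_lag + 1L)) {
    if (rho[i] <= 0) {
      # crossing happened between lags i-2 and i-1; attribute to the
      # endpoint with smaller |rho| (never lag 0)
      zc <- if (i > 2L && abs(rho[i - 1L]) < abs(rho[i])) lag_of(i - 1L)
            else lag_of(i)
      break
    }
  }

  # first local minimum: rho(m) <= rho(m-1) and rho(m) < rho(m+1)
  lm <- NA_integer_
  if (max_lag >= 2L) {
    for (i in 2:max_lag) {
      if (rho[i] <= rho[i - 1L] && rho[i] < rho[i + 1L]) {
        lm <- lag_of(i)
        break
      }
    }
  }

  if (!is.na(zc) || !is.na(lm)) {
    # smaller lag wins; ties go to the zero crossing
    return(max(1L, min(zc, lm, na.rm = TRUE)))
  }

  # monotone, positive ACF: folding time rho <= 1/e (ceiling to integer lag)
  if (all(rho[-1] > 0) && !is.unsorted(rev(rho))) {
    fold <- which(rho[-1] <= exp(-1))
    if (length(fold)) return(max(1L, fold[1L]))
  }
  warning("no delay-selection criterion met within max_lag = ", max_lag,
          "; returning max_lag", call. = FALSE)
  as.integer(max_lag)
}
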