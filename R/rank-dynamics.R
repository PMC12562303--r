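# Markov-chain description of the symbol sequence and the rank
# variance / autocovariance of the integer-coded patterns.

# fast pair-count matrix at lag m: n x n counts of (s_t, s_{t+m})
pair_counts <- function(codes, n, m) {
  L <- length(codes)
  from <- codes[seq_len(L - m)]
  to <- codes[seq_len(L - m) + m]
  matrix(tabulate(from + n * (to - 1L), nbins = n * n), n, n)
}

#' Stationary distribution of the ordinal patterns
#'
#' Empirical occupation probabilities of the `D!` pattern states,
#' estimated as relative frequencies over the whole symbol sequence.
#' Patterns never observed get probability 0.
#'
#' @param sym A `"symbol_sequence"` from [symbolize()].
#' @return Numeric probability vector of length `factorial(D)`.
#' @export
estimate_stationary <- function(sym) {
  stopifnot(inherits(sym, "symbol_sequence"))
  if (sym$L < 1L) stop("empty symbol sequence", call. = FALSE)
  tabulate(sym$codes, nbins = factorial(sym$D)) / sym$L
}

#' Joint and conditional pattern probabilities at lag m
#'
#' Estimates the m-step structure of the symbolic Markov chain by direct
#' pair counting: the joint probability of seeing pattern `i` at time `t`
#' and pattern `j` at time `t + m`, normalized by the `L - m` available
#' pairs, and the conditional (row-normalized) transition matrix.
#'
#' @param sym A `"symbol_sequence"`.
#' @param m Lag, integer in `1..(L-1)`.
#' @return List with `joint` (`D! x D!` matrix summing to 1),
#'   `conditional` (row-stochastic on occupied rows, `NA` rows where the
#'   source pattern never occurs at the usable positions) and `occupied`
#'   (logical vector flagging rows with positive mass).
#' @export
estimate_transition <- function(sym, m) {
  stopifnot(inherits(sym, "symbol_sequence"))
  L <- sym$L
  if (length(m) != 1L || m != round(m) || m < 1L || m > L - 1L) {
    stop("lag m must be an integer in 1..(L-1)", call. = FALSE)
  }
  n <- factorial(sym$D)
  joint <- pair_counts(sym$codes, n, as.integer(m)) / (L - m)
  rs <- rowSums(joint)
  occupied <- rs > 0
  conditional <- joint / ifelse(rs > 0, rs, NA_real_)
  list(joint = joint, conditional = conditional, occupied = occupied)
}

#' Rank autocovariance of the symbol sequence
#'
#' Treats the ordinal-pattern codes as an integer-valued stationary
#' process and computes its mean rank `E{S} = sum_i i p_i`, rank
#' variance `Var(S) = sum_i i^2 p_i - E{S}^2` and rank autocovariance
#' `Cov(m) = sum_ij i j p(i, j; m) - E{S}^2` over lags
#' `m = 0, ..., N-1`.
#'
#' Two estimators of the m-step joint probabilities `p(i, j; m)` are
#' available.  The default, `method = "markov"`, models the symbol
#' sequence as a first-order Markov chain: the one-step transition
#' matrix `P1` is counted from consecutive symbols and
#' `p(i, j; m) = p_i (P1^m)_ij`.  All lags then derive from the
#' well-estimated `P1`, so `Cov(m)` is smooth in `m` and, for an
#' ergodic chain, decays geometrically; this is what gives the
#' surrogate test its sensitivity.  `method = "direct"` instead counts
#' pattern pairs separately at every lag, making `Cov(m)` a genuine
#' sample autocovariance of the coded sequence (useful as a
#' model-free check, but each lag carries independent sampling noise).
#'
#' @param sym A `"symbol_sequence"`.
#' @param n_lags Number of lags `N`; `cov` holds `Cov(0), ..., Cov(N-1)`.
#'   Default `min(L, 512)`.
#' @param method `"markov"` (default) or `"direct"`, see Details above.
#' @param normalization For `method = "direct"` only: `"biased"`
#'   (default) scales `Cov(m)` by `(L-m)/L`, taming the noisy high-lag
#'   estimates; `"unbiased"` divides pair sums by `L - m`.
#' @return Object of class `"rank_autocov"`: list with `cov` (length
#'   `n_lags`), `variance`, `mean_rank`, `n_lags`, `L`, `D`, `tau`,
#'   `method`, `normalization`.
#' @examples
#' s <- symbolize(logistic_map(r = 4, T = 1000, seed = 1), D = 3, tau = 1)
#' rc <- rank_autocovariance(s, n_lags = 64)
#' rc$variance == rc$cov[1]
#' @export
rank_autocovariance <- function(sym, n_lags = NULL,
                                method = c("markov", "direct"),
                                normalization = c("biased", "unbiased")) {
  stopifnot(inherits(sym, "symbol_sequence"))
  method <- match.arg(method)
  normalization <- match.arg(normalization)
  L <- sym$L
  if (is.null(n_lags)) n_lags <- min(L, 512L)
  if (n_lags < 1L || n_lags > L) {
    stop("n_lags must be in 1..L", call. = FALSE)
  }
  s <- as.numeric(sym$codes)
  Ebar <- mean(s)
  variance <- mean(s^2) - Ebar^2

  cov <- numeric(n_lags)
  cov[1L] <- variance
  if (n_lags > 1L) {
    if (method == "markov") {
      n <- factorial(sym$D)
      p <- tabulate(sym$codes, nbins = n) / L
      P <- pair_counts(sym$codes, n, 1L)
      rs <- rowSums(P)
      P <- P / ifelse(rs > 0, rs, 1)
      diag(P)[rs == 0] <- 1  # self-loop on unvisited rows, keeps P stochastic
      w <- seq_len(n)
      u <- w * p            # row vector i * p_i, propagated through P^m
      for (m in seq_len(n_lags - 1L)) {
        u <- as.numeric(u %*% P)
        cov[m + 1L] <- sum(u * w) - Ebar^2
      }
    } else {
      # raw lagged sums sum_t s_t s_{t+m} for all m at once via FFT
      nfft <- stats::nextn(2L * L)
      sp <- stats::fft(c(s, numeric(nfft - L)))
      cc <- Re(stats::fft(sp * Conj(sp), inverse = TRUE)) / nfft
      m <- seq_len(n_lags - 1L)
      raw <- cc[m + 1L]
      cov[-1L] <- switch(normalization,
        unbiased = raw / (L - m) - Ebar^2,
        biased   = raw / L - (L - m) / L * Ebar^2
      )
    }
  }
  structure(
    list(cov = cov, variance = variance, mean_rank = Ebar,
         n_lags = as.integer(n_lags), L = L, D = sym$D, tau = sym$tau,
         method = method,
         normalization = if (method == "direct") normalization else NA),
    class = "rank_autocov"
  )
}

#' @export
print.rank_autocov <- function(x, ...) {
  cat("Rank autocovariance:", x$n_lags, "lags (", x$method, "estimator )\n")
  cat("  mean rank", format(x$mean_rank, digits = 4),
      " variance", format(x$variance, digits = 4), "\n")
  invisible(x)
}

#' Diagnostic: is the symbol sequence first-order Markov?
#'
#' Compares the directly counted m-step transition matrix against the
#' m-th power of the one-step matrix.  For an exactly first-order chain
#' the two coincide up to sampling error; ordinal symbol sequences are
#' only approximately first order because consecutive patterns share
#' `D - 1` samples.  The discrepancy quantifies how much the
#' `method = "markov"` autocovariance model smooths over.
#'
#' @param sym A `"symbol_sequence"`.
#' @param m Lag at which to compare, `m >= 2`.
#' @return List with `counted` and `powered` conditional matrices and
#'   `max_abs_diff`, the largest entrywise discrepancy over rows occupied
#'   in both.
#' @export
markov_order_diagnostic <- function(sym, m) {
  if (m < 2L) stop("diagnostic needs m >= 2", call. = FALSE)
  one <- estimate_transition(sym, 1L)
  direct <- estimate_transition(sym, m)
  P1 <- one$conditional
  P1[!one$occupied, ] <- 0
  Pm <- P1
  for (i in seq_len(m - 1L)) Pm <- Pm %*% P1
  ok <- one$occupied & direct$occupied
  list(counted = direct$conditional, powered = Pm,
       max_abs_diff = max(abs(direct$conditional[ok, , drop = FALSE] -
                              Pm[ok, , drop = FALSE])))
}
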