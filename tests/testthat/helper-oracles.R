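# Independent oracles used to freeze expected values.  These
# deliberately use different algorithms from the package internals.

# All permutations of 1..D by exhaustive tuple filtering (clearly
# correct, if wasteful: D^D candidate tuples).  Rows in no particular
# order.
all_perms <- function(D) {
  grid <- as.matrix(expand.grid(rep(list(seq_len(D)), D)))
  colnames(grid) <- NULL
  grid[apply(grid, 1L, function(r) length(unique(r)) == D), , drop = FALSE]
}

# Brute-force ordinal code: enumerate all D! permutations, sort them
# lexicographically, and locate the (stable) sorting permutation of the
# window.
perm_rank_oracle <- function(window) {
  D <- length(window)
  P <- all_perms(D)
  lex <- P[do.call(order, as.data.frame(P)), , drop = FALSE]
  pi <- order(window)  # stable: ties keep temporal order
  which(apply(lex, 1L, function(row) all(row == pi)))
}

# Naive direct sample autocovariance of an integer code sequence with
# the global-mean convention (matching the definition via empirical
# joint pattern probabilities).
direct_autocov_oracle <- function(codes, m, normalization = "unbiased") {
  s <- as.numeric(codes)
  L <- length(s)
  sbar <- mean(s)
  if (m == 0L) return(mean(s^2) - sbar^2)
  tot <- 0
  for (t in seq_len(L - m)) tot <- tot + s[t] * s[t + m]
  cu <- tot / (L - m) - sbar^2
  if (normalization == "biased") cu * (L - m) / L else cu
}

# Benjamini-Hochberg by its textbook definition: q_(i) = min_{j >= i}
# p_(j) * n / j, mapped back to the original order.
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(sort(p) * n / seq_len(n)))))
  q <- numeric(n)
  q[o] <- q_sorted
  q
}

# Wrap an arbitrary code vector as a symbol_sequence for unit tests.
fake_symbols <- function(codes, D = 3L, tau = 1L) {
  structure(list(codes = as.integer(codes), D = as.integer(D),
                 tau = as.integer(tau), L = length(codes),
                 tie_rule = "stable"),
            class = "symbol_sequence")
}

# Log-log periodogram slope with logarithmic band averaging.
periodogram_slope <- function(x, n_bands = 20) {
  sp <- stats::spec.pgram(x - mean(x), plot = FALSE, detrend = FALSE,
                          taper = 0)
  lf <- log10(sp$freq)
  bins <- cut(lf, breaks = seq(min(lf), max(lf), length.out = n_bands + 1),
              include.lowest = TRUE)
  mf <- tapply(lf, bins, mean)
  ms <- tapply(log10(sp$spec), bins, mean)
  unname(stats::coef(stats::lm(ms ~ mf))[2])
}
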