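# Internal helpers: seed scoping and argument checks.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the
# caller's RNG state is restored afterwards.  seed = NULL runs unseeded.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1) # materialize a RNG state so it can be saved
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Deterministic stream of child seeds from a parent seed, kept within
# the 32-bit signed integer range R requires.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  as.list((as.numeric(seed) * 48271 + 7919 * seq_len(n)) %% 2147483647)
}

check_series <- function(x, min_len = 2L, what = "series") {
  if (!is.numeric(x)) stop(what, " must be a numeric vector", call. = FALSE)
  if (length(x) < min_len) {
    stop(what, " must have at least ", min_len, " observations", call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop(what, " contains non-finite values", call. = FALSE)
  }
  invisible(x)
}

check_embedding <- function(D, tau) {
  if (length(D) != 1L || D != round(D) || D < 2 || D > 7) {
    stop("embedding dimension D must be an integer in 2..7", call. = FALSE)
  }
  if (length(tau) != 1L || tau != round(tau) || tau < 1) {
    stop("embedding delay tau must be a positive integer", call. = FALSE)
  }
  invisible(NULL)
}
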