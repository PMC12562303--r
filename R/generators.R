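# Synthetic benchmark systems: deterministic maps/flows with known
# periodic and chaotic regimes, and stochastic controls that a chaos
# test must *not* flag.

#' Logistic map
#'
#' Iterates `x_{n+1} = r x_n (1 - x_n)` and returns `T` samples after a
#' burn-in.  The map runs through period-doubling cascades and reaches
#' chaos near `r = 3.56995`; periodic windows persist above that
#' (e.g. the period-5 window containing `r = 3.739`), while `r = 3.8`
#' and `r = 4` are chaotic.
#'
#' @param r Bifurcation parameter in (0, 4].
#' @param T Number of samples returned (default 2000).
#' @param burn_in Iterations discarded first (default 1000).
#' @param x0 Initial condition in (0, 1); default: seeded uniform draw in
#'   (0.01, 0.99), avoiding the unstable fixed points.
#' @param seed Optional integer seed (used only for the default `x0`).
#' @return Numeric vector of length `T`.
#' @export
logistic_map <- function(r, T = 2000L, burn_in = 1000L, x0 = NULL,
                         seed = NULL) {
  if (r <= 0 || r > 4) stop("r must be in (0, 4]", call. = FALSE)
  if (T < 1L || burn_in < 0L) stop("bad T or burn_in", call. = FALSE)
  if (is.null(x0)) x0 <- with_seed(seed, stats::runif(1, 0.01, 0.99))
  if (x0 <= 0 || x0 >= 1) stop("x0 must be in (0, 1)", call. = FALSE)
  n <- burn_in + T
  x <- numeric(n)
  x[1] <- x0
  for (i in seq_len(n - 1L)) x[i + 1L] <- r * x[i] * (1 - x[i])
  if (any(x < 0 | x > 1)) stop("orbit escaped [0, 1]", call. = FALSE)
  x[(burn_in + 1L):n]
}

#' x-component of the Roessler system
#'
#' Integrates `dx = -y - z; dy = x + a y; dz = 2 + z (x - 4)` with a
#' fixed-step fourth-order Runge-Kutta scheme and returns the sampled
#' x-component after a burn-in.  The attractor is periodic for small `a`
#' (e.g. 0.30) and chaotic beyond `a ~ 0.385` (e.g. 0.42, 0.54), with
#' embedded periodic windows.
#'
#' @param a Control parameter in `[0.25, 0.55]`.
#' @param T Number of samples returned (default 10000).
#' @param burn_in Samples discarded first (default 1000).
#' @param dt Integration step = sampling interval (default 0.05 time
#'   units; the fundamental cycle then spans roughly 120 samples).
#' @param init Initial state `(x, y, z)`, default `c(1, 1, 0)`.
#' @param seed Optional integer seed; when given, `init` is perturbed by
#'   a seeded uniform jitter of magnitude 1e-3 so replicate calls sample
#'   different stretches of the attractor.
#' @return Numeric vector of length `T`.
#' @export
rossler_x <- function(a, T = 10000L, burn_in = 1000L, dt = 0.05,
                      init = c(1, 1, 0), seed = NULL) {
  if (a < 0.25 || a > 0.55) stop("a must be in [0.25, 0.55]", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (!is.null(seed)) {
    init <- init + with_seed(seed, stats::runif(3, -1e-3, 1e-3))
  }
  n <- burn_in + T
  deriv <- function(t, s, p) {
    list(c(-s[2] - s[3], s[1] + a * s[2], 2 + s[3] * (s[1] - 4)))
  }
  times <- seq(0, by = dt, length.out = n)
  sol <- deSolve::rk4(y = c(x = init[1], y = init[2], z = init[3]),
                      times = times, func = deriv, parms = NULL)
  x <- sol[, "x"]
  if (!all(is.finite(x)) || max(abs(x)) > 1e6) {
    stop("trajectory diverged", call. = FALSE)
  }
  unname(x[(burn_in + 1L):n])
}

#' Gaussian white noise
#'
#' @param T Length.
#' @param seed Optional integer seed.
#' @return `T` iid draws from N(0, 1).
#' @export
gaussian_noise <- function(T = 2000L, seed = NULL) {
  if (T < 2L) stop("T must be at least 2", call. = FALSE)
  with_seed(seed, stats::rnorm(T))
}

#' Power-law (1/f^alpha) noise by spectral synthesis
#'
#' Builds a Gaussian process with power spectrum `S(f) ~ f^-alpha`:
#' Fourier amplitudes proportional to `f^(-alpha/2)`, iid uniform
#' phases, inverse transform, then standardized to zero mean and unit
#' variance.  `alpha = 0` recovers white noise; `alpha = 1` is pink
#' noise.
#'
#' @param alpha Spectral exponent, `>= 0` (default 1).
#' @param T Length (default 2000).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `T`.
#' @export
powerlaw_noise <- function(alpha = 1, T = 2000L, seed = NULL) {
  if (T < 2L) stop("T must be at least 2", call. = FALSE)
  if (alpha < 0) stop("alpha must be nonnegative", call. = FALSE)
  nhalf <- floor(T / 2)
  f <- (1:nhalf) / T
  amp <- f^(-alpha / 2)
  with_seed(seed, {
    phases <- stats::runif(nhalf, 0, 2 * pi)
    spec <- complex(length.out = T)
    spec[2:(nhalf + 1L)] <- amp * exp(1i * phases)
    # Hermitian symmetry for a real series; Nyquist bin forced real
    if (T %% 2L == 0L) spec[nhalf + 1L] <- amp[nhalf]
    k <- if (T %% 2L == 0L) 2:nhalf else 2:(nhalf + 1L)
    spec[T + 2L - k] <- Conj(spec[k])
    x <- Re(stats::fft(spec, inverse = TRUE))
    as.numeric(scale(x))
  })
}

# inverse-CDF sampler for the Laplace(mu, b) distribution
rlaplace <- function(n, mu = 0, b = 1) {
  u <- stats::runif(n) - 0.5
  mu - b * sign(u) * log(1 - 2 * abs(u))
}

#' Nonlinear stochastic system driven by Laplacian noise
#'
#' Simulates the two-equation model
#' `x_t = 0.5 x_{t-1} - 0.3 x_{t-2} + 0.1 y_{t-2} + 0.1 x_{t-2}^2 +
#'  0.4 y_{t-1}^2 + 0.0025 eta'_t` with
#' `y_t = sin(4 pi t) + sin(6 pi t) + 0.0025 eta''_t`, where both noises
#' are iid Laplace(0, 1).  Despite the quadratic terms and heavy-tailed
#' noise this is a stochastic process, and the surrogate test should not
#' flag it as chaotic.  Time in the sinusoidal forcing advances by
#' `dt_index` per step (default 0.01) so the forcing actually
#' oscillates; on an integer time grid both sines would vanish
#' identically.
#'
#' @param T Number of samples returned (default 2000).
#' @param burn_in Samples discarded first (default 1000).
#' @param dt_index Time increment per step in the forcing (default 0.01).
#' @param noise_gain Amplitude of both noise terms (default 0.0025).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `T`.
#' @export
nonlinear_nongaussian <- function(T = 2000L, burn_in = 1000L,
                                  dt_index = 0.01, noise_gain = 0.0025,
                                  seed = NULL) {
  if (T < 3L) stop("T must be at least 3", call. = FALSE)
  n <- burn_in + T + 2L
  with_seed(seed, {
    e1 <- rlaplace(n)
    e2 <- rlaplace(n)
    tt <- (seq_len(n)) * dt_index
    y <- sin(4 * pi * tt) + sin(6 * pi * tt) + noise_gain * e2
    x <- numeric(n)
    for (i in 3:n) {
      x[i] <- 0.5 * x[i - 1L] - 0.3 * x[i - 2L] + 0.1 * y[i - 2L] +
        0.1 * x[i - 2L]^2 + 0.4 * y[i - 1L]^2 + noise_gain * e1[i]
      if (abs(x[i]) > 1e6) stop("recursion diverged", call. = FALSE)
    }
    x[(burn_in + 3L):(burn_in + 2L + T)]
  })
}

#' Non-monotonic transform of a linear non-Gaussian AR process
#'
#' Simulates `y_t = 0.4 y_{t-3} - 0.3 y_{t-2} + 0.2 y_{t-1} + e_t`,
#' where `e_t = U^2` with `U ~ Uniform(-0.5, 0.5)` (a skewed,
#' non-Gaussian innovation), and returns the static non-monotonic
#' transform `x_t = tanh(y_t)^2`.  The underlying dynamics are linear
#' and stochastic; a sound chaos test must not reject the null here.
#'
#' @param T Number of samples returned (default 2000).
#' @param burn_in Samples discarded first (default 1000).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `T`, all values in `[0, 1)`.
#' @export
tanh2_ar <- function(T = 2000L, burn_in = 1000L, seed = NULL) {
  if (T < 4L) stop("T must be at least 4", call. = FALSE)
  n <- burn_in + T + 3L
  with_seed(seed, {
    e <- stats::runif(n, -0.5, 0.5)^2
    y <- numeric(n)
    for (i in 4:n) {
      y[i] <- 0.4 * y[i - 3L] - 0.3 * y[i - 2L] + 0.2 * y[i - 1L] + e[i]
      if (abs(y[i]) > 1e6) stop("recursion diverged", call. = FALSE)
    }
    tanh(y[(burn_in + 4L):(burn_in + 3L + T)])^2
  })
}

#' Dominant oscillation period from the periodogram
#'
#' Estimates the fundamental cycle length of a (quasi-)oscillatory
#' series as the inverse of the frequency of the largest periodogram
#' ordinate.  Used, e.g., to express a Roessler series length in numbers
#' of fundamental cycles.
#'
#' @param x Numeric series.
#' @return Period in samples (numeric).
#' @export
fundamental_period <- function(x) {
  check_series(x, min_len = 8L)
  sp <- stats::spec.pgram(x - mean(x), plot = FALSE, detrend = FALSE,
                          taper = 0)
  1 / sp$freq[which.max(sp$spec)]
}
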