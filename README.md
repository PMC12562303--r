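# ordspec — ordinal spectrum analysis of time series

`ordspec` detects nonlinear (e.g. chaotic) temporal structure in a
univariate time series and localizes it in frequency.  It is aimed at
analysts of biomedical, ecological, astronomical and other complex
signals — EEG, epidemic case counts, sunspot numbers — where the
practical question is: *is this irregular oscillation a linearly
filtered (possibly transformed) noise, or does it carry genuine
nonlinear dynamics, and at which time scales?*

Classical power spectra cannot answer that question: the spectrum of a
chaotic system can be reproduced exactly by a static transform of
linear noise.  `ordspec` instead works on the series' **ordinal
patterns** (Bandt–Pompe symbols): each window
(X_t, X_{t+τ}, …, X_{t+(D−1)τ}) is encoded by the lexicographic rank of
the permutation that sorts it, ascending = 1, descending = D!.  The
symbol sequence S_t is modelled as a finite-state Markov chain with
stationary distribution p\*_i and one-step transition matrix P₁, giving
the **rank autocovariance**

    E{S}   = Σ_i i p*_i
    Var(S) = Σ_i i² p*_i − E{S}²
    Cov(m) = Σ_ij i · j · p*_i (P₁^m)_ij − E{S}²

and its Fourier transform, the **ordinal spectrum**

    OS(f) = Cov(0) + 2 Σ_{m=1}^{N−1} Cov(m) cos(2π f m),   f ∈ [0, 0.5].

Significance is assessed against IAAFT surrogates — series with exactly
the same amplitude distribution and (to convergence) the same
periodogram, but no higher-order structure: per-frequency z-scores
z(f) = (OS(f) − μ_s(f)) / σ_s(f), two-sided p-values, and
Benjamini–Hochberg FDR control across the frequency grid.  Rejection
anywhere falsifies the null hypothesis of a monotonically-transformed
linear stochastic process; the maximal runs of significant frequencies
are reported as bands.

## Worked example

Chaotic logistic map versus Gaussian noise, at the benchmark settings:

```r
library(ordspec)

x <- logistic_map(r = 4, T = 2000, seed = 1)       # chaotic regime
tst <- ordinal_spectrum_test(x, D = 3, tau = 1, n_surrogates = 500,
                             seed = 1)
print(tst)
#> Ordinal spectrum test (T = 2000 , D = 3 , tau = 1 , 500 IAAFT surrogates)
#> Ordinal-spectrum surrogate test: null_rejected
#>   min FDR-adjusted p = 1.05e-23  (alpha = 0.05 , normal p-values )
#>   significant frequency bands:
#>     [0.0020, 0.1412]
#>     [0.1824, 0.2765]
#>     [0.2961, 0.5000]

g <- gaussian_noise(2000, seed = 1)                # linear null control
print(ordinal_spectrum_test(g, D = 4, tau = 1, n_surrogates = 500,
                            seed = 1))
#> Ordinal spectrum test (T = 2000 , D = 4 , tau = 1 , 500 IAAFT surrogates)
#> Ordinal-spectrum surrogate test: null_not_rejected
#>   min FDR-adjusted p = 0.547  (alpha = 0.05 , normal p-values )
```

The chaotic map is rejected decisively, with most of the frequency
axis flagged; the noise control is nowhere near significance.  The
returned object carries every intermediate (symbol sequence, rank
autocovariance, spectrum, surrogate ensemble summaries, per-frequency
z/p/q arrays) and serializes with `write_os_report()`.

Lower-level pieces are exported individually — `symbolize()`,
`select_delay()`, `rank_autocovariance()`, `ordinal_spectrum()`,
`iaaft()`, `build_ensemble()`, `significance()` — as are generators
for the benchmark systems (`logistic_map()`, `rossler_x()`,
`gaussian_noise()`, `powerlaw_noise()`, `nonlinear_nongaussian()`,
`tanh2_ar()`).

A thin command-line interface wraps the same functions:

```sh
Rscript $(Rscript -e 'cat(system.file("cli/ordspec.R", package="ordspec"))') \
    generate --system logistic --r 4 --T 2000 --seed 1 --out series.txt
Rscript .../ordspec.R analyze --input series.txt --D 3 --tau 1 \
    --n-surrogates 500 --seed 1 --out-dir results/
```

`analyze` writes a JSON report (config echo, verdict, bands,
per-frequency table) and a TSV; exit status 2 flags validation errors.

See the vignette (`vignettes/ordinal-spectrum.Rmd`) for the model, the
estimator choices, and the limits of what the synthetic benchmarks
demonstrate.

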