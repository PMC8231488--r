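# mcdecode

Robust estimation of low-dimensional movement intention from noisy
high-dimensional neural recordings, built around a **nonlinear maximum
correntropy information filter (NMCIF)**.

## The problem and the method

Brain–machine interfaces decode a 2-D movement state $x_k$ from tens of
channels of binned spike counts $y_k$ under a state–observation model
$x_k = F x_{k-1} + q_{k-1}$, $y_k = H(x_k) + \zeta_k$. The classical Kalman
filter struggles on such data three ways: the neuron–state map is nonlinear
and channels are correlated; the decoder's initial state is unknown; and the
noise is heavy-tailed (occasional large recording artefacts).

`mcdecode` implements a filter that addresses all three:

* a trained single-hidden-layer network compresses lagged firing into a
  *pseudo-observation* $g(y_k) = x_k + r_k$ with identity observation
  matrix (`train_observer()`);
* the recursion propagates the **information matrix** $\chi_k$ (inverse
  covariance), so total initial ignorance is just $\hat\chi_0 = 10^{-6}I$;
* the measurement update maximises a **correntropy** cost
  $J(x) = \tfrac{1}{2n}\sum_i G_\sigma(d_i - m_i x)$,
  $G_\sigma(e) = e^{-e^2/2\sigma^2}$, over the whitened stacked regression
  $D_k = M_k x_k + e_k$ of prior and pseudo-observation, solved by
  fixed-point (IRLS) iteration
  $\hat x^{(t)} = (M^\top C^{(t-1)} M)^{-1} M^\top C^{(t-1)} D$.
  Residuals far beyond the bandwidth $\sigma$ get exponentially small
  weights, so outliers are ignored; as $\sigma \to \infty$ the update
  reduces to the (least-squares) nonlinear information filter.

Baselines — the covariance-form Kalman filter on raw firing, the nonlinear
information filter (NIF), and the raw network decoder — plus a synthetic
two-lever-task generator (sigmoid-smoothed 2-D states, 32 channels of
linear–nonlinear–Poisson spike counts, optional 3.3 % shot-noise
contamination) and evaluation tooling round out the package. Everything is
tidyverse-shaped: data frames in, tibbles out, `tidy()`/`glance()` methods,
`autoplot()` figures.

## Worked example

```r
library(mcdecode)

suite <- make_benchmark_suite(seed = 1, n_train_trials = 20,
                              n_segments = 10, trials_per_segment = 3)
run_experiment("clean", suite,
               decoders = c("kf", "nn", "nif", "nmcif_b"), sigma = 2)
#> <experiment_report> clean
#>   decoder condition n_segments      mean         sd
#> 1      kf     clean         10 0.5282719 0.09891347
#> 2      nn     clean         10 0.3154190 0.03921734
#> 3     nif     clean         10 0.1566354 0.03015189
#> 4 nmcif_b     clean         10 0.1686584 0.02614205

run_experiment("contaminated", suite, decoders = c("nif", "nmcif_b"),
               sigma = 2)
#> <experiment_report> contaminated
#>   decoder    condition n_segments      mean         sd
#> 1     nif contaminated         10 0.4802302 0.36958277
#> 2 nmcif_b contaminated         10 0.1711960 0.02740257
```

Each row is the mean ± sd of the 2-D mean squared error
($\tfrac1T\sum_k\|\hat x_k - x_k\|^2$) over 10 held-out test segments. On
clean data the correntropy filter matches the least-squares information
filter (both far below the KF baseline, which must work from raw counts
through a linear tuning model); under 3.3 % shot-noise contamination the
least-squares update roughly triples its error while the correntropy
filter is nearly unaffected. `run_experiment("bandwidth_sweep", ...)`
tabulates error and fixed-point iteration counts against the bandwidth,
and `autoplot()` on any decoding result draws estimate-vs-truth
trajectories.

A command-line wrapper over the same functions (subcommands `simulate`,
`fit`, `decode`, `evaluate`, `experiment`) ships at
`inst/cli/mcdecode-cli.R`.

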