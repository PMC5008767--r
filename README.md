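# levyflux

Langevin modelling of brain-network activity fluctuations with
alpha-stable (Lévy) noise.

## The problem

Resting-state fMRI networks fluctuate in strikingly different ways: some
traces stay confined to a band of small, evenly spread variations, while
others show long quiet stretches punctuated by occasional huge jumps.
`levyflux` quantifies that difference with a single generative model. A
network's activity `x(t)` is treated as a random motion obeying a
discrete Langevin equation,

    δx(t) = g(x(t)) + ξ(t),        δx(t) = x(t+1) − x(t),

with a linear relaxation drift `g(x) = −k (x − x*)` (activity decays
towards an equilibrium `x*` with characteristic time `τ = 1/k`) and
i.i.d. alpha-stable innovations `ξ ~ f(x; α, β, γ, δ)`. The
characteristic exponent `α ∈ (0, 2]` places each network on a spectrum:
`α = 2` is Gaussian (Brownian) dynamics; `α < 2` gives power-law tails
`P(|ξ| > u) ~ u^−α` and Lévy-flight dynamics in which large activity
jumps are far more likely. The package recovers the drift from binned
conditional increments, fits the four stable parameters by regression on
the empirical characteristic function (quantile initialisation followed
by iterated ECF regressions), checks the survival-function tail slope
(`log F̄` vs `log |ξ|` is linear with slope `−α` for a stable law), and
validates every fit with two-sample Kolmogorov–Smirnov and
Anderson–Darling tests plus Monte Carlo power assessment.

It is aimed at researchers analysing 1-D physiological or neural time
series who want a principled heavy-tail characterisation rather than a
variance summary — and at anyone needing dependable alpha-stable
numerics (characteristic function, Chambers–Mallows–Stuck sampling,
density/CDF by characteristic-function inversion with proper tail
handling) in base R.

## Worked example

Simulate a cohort with known ground truth — three networks spanning the
spectrum (`α = 1.1, 1.5, 2.0`, all with `k = 0.3`), 10 subjects, 850
samples each — then run the full per-network analysis:

```r
library(levyflux)

spec <- cohort_spec(list(
  list(network_id = "basal_ganglia", drift = drift_model(k = 0.3, x_star = 1),
       noise = stable_params(alpha = 1.1, beta = 0, gamma = 1, delta = 0)),
  list(network_id = "visual", drift = drift_model(k = 0.3, x_star = -1),
       noise = stable_params(alpha = 1.5, beta = 0, gamma = 1, delta = 0)),
  list(network_id = "cerebellum", drift = drift_model(k = 0.3, x_star = 2),
       noise = stable_params(alpha = 2.0, beta = 0, gamma = 1, delta = 0))),
  n_subjects = 10, n_timepoints = 850)
cohort <- generate_cohort(spec, seed = 1)

reports <- run_pipeline(cohort, pipeline_config(seed = 1))
for (r in reports) print(r)
#> network basal_ganglia: alpha = 1.091 (rank 1), k = 0.281, x* = 0.081, K-S p = 0.960, A-D p = 0.914
#> network visual: alpha = 1.498 (rank 2), k = 0.306, x* = -0.006, K-S p = 0.289, A-D p = 0.245
#> network cerebellum: alpha = 1.995 (rank 3), k = 0.308, x* = 0.008, K-S p = 0.326, A-D p = 0.440
```

Each injected exponent is recovered within a few hundredths (1.091,
1.498, 1.995 against 1.1, 1.5, 2.0), the heaviest-tailed network is
ranked 1, the relaxation rate comes back near the true 0.3 (`x*` is near
0 because per-subject detrending re-centres the traces), and no network
is rejected by either goodness-of-fit test at the 0.05 level — the
fitted laws are statistically indistinguishable from the residuals they
were fit to. Drilling into one report:

```r
print(reports$basal_ganglia$stable)
#> alpha-stable law [S1]: alpha = 1.091, beta = 0.01993, gamma = 1.056, delta = 0.1561
print(reports$basal_ganglia$drift)
#> drift model: g(x) = -0.2813 (x - 0.08054), tau = 3.555 steps
round(reports$basal_ganglia$stable_ci$alpha, 3)   # bootstrap 95% CI
#> 1.059 1.121
```

`write_report(reports, "out", dataset = cohort, config = ...)` emits one
JSON per network, a summary CSV, plot-ready drift-curve and
survival-curve CSVs, and a manifest with every seed. Real data enters
the same way through `read_series_table()` (long CSV/TSV with columns
`subject, network, t, x`). A thin command-line front end with
`simulate` / `fit` / `gof` / `power` subcommands lives in
`inst/cli/levyflux`.

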