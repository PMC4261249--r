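# dpcrsim

Digital PCR (dPCR) quantifies a target nucleic acid absolutely: the
reaction is split into thousands of partitions, amplified, and the
fraction of partitions void of target estimates the concentration
through Poisson statistics,

    p = P(X = 0) = exp(-lambda),
    lambda_hat  = -ln(K / n_r),            [copies per partition]
    Var(lambda_hat) = (exp(lambda_hat) - 1) / n_r,
    theta_hat   = lambda_hat / v.          [copies per nanoliter]

The textbook interval built from this variance is honest only in a world
without technical variation.  Real experiments add pipette error,
unequal partition volumes, random partition loss and endpoint
misclassification — and the pooled-partition interval then becomes
drastically overconfident.  `dpcrsim` is for practitioners and
methodologists who want to (a) analyse dPCR counts with uncertainty
that survives those variance components, (b) simulate the full
data-generating process with each component switchable, and (c) plan
experiments: optimal dilution, replicate number, threshold-induced bias
and its correction.

What's inside:

* **Estimators** — `estimate_lambda()`, `pooled_estimate()`,
  `replicate_based_estimate()` (empirical mean ± t-interval over
  technical replicates; keeps nominal coverage under pipette error),
  `to_concentration()`.
* **Simulator** — `sim_config()` + `simulate_experiment()`: pipette
  factor → lognormal partition sizes (mean 1) → Poisson copy seeding →
  MCAR partition loss → Bernoulli misclassification; plus a two-cluster
  fluorescence stand-in with "rain" and `apply_threshold()` for
  realized false rates.  An aggregated binomial fast path makes
  thousand-run sweeps take seconds.
* **Design analytics** — `optimal_lambda()` (root of
  `lambda = 2(1 - exp(-lambda))`, ≈ 1.59 copies/partition),
  `loss_precision_factor()`, `relative_ci_width_table()`,
  `misclassification_bias()`, `unbiased_ratio()`, `corrected_lambda()`,
  `size_variation_bias()`, `volume_bias()`,
  `theoretical_relative_ci_limits()`.
* **Scenario engine** — `run_scenario()`,
  `sequential_components_report()`, `rmse_minimizer()`: coverage, bias
  and relative-RMSE summaries over concentration grids.
* **I/O + CLI** — CSV counts tables (`read_counts_table()`,
  `estimate_from_file()`), JSON run manifests, and a thin command-line
  front end at `inst/cli/dpcr.R` with `estimate`, `simulate`,
  `scenario` and `design` subcommands.

## Worked example

Simulate 8 technical replicates at 1.25 copies/partition with 5%
pipette error and ~30% droplet loss, then compare the two ways of
combining replicates:

```r
library(dpcrsim)
cfg <- sim_config(lambda_true = 1.25, pipette_cv = 0.05,
                  loss_mean = 14000, loss_sd = 1800, seed = 11)
reps <- simulate_experiment(cfg)

pooled_estimate(reps)
#> dPCR concentration estimate (pooled method)
#>   lambda_hat: 1.2351 copies/partition (se 0.0049)
#>   95% CI: [1.2255, 1.2447]

replicate_based_estimate(reps)
#> dPCR concentration estimate (replicate_based method)
#>   lambda_hat: 1.2347 copies/partition (se 0.0263)
#>   95% CI: [1.1726, 1.2969]

to_concentration(replicate_based_estimate(reps), volume_spec(0.89))
#> dPCR concentration estimate (replicate_based method)
#>   lambda_hat: 1.2347 copies/partition (se 0.0263)
#>   95% CI: [1.1726, 1.2969]
#>   theta_hat: 1.3873 copies/nL (v = 0.890 nL)
```

Both point estimates agree, but the pooled interval is five times
narrower than the replicate-based one — not because it is better, but
because it cannot see the between-replicate variation the pipette
introduced.  Across many such experiments the pooled 95% interval
covers the truth far less than half the time, while the replicate-based
interval stays at ~95% (the test suite measures both).

Design questions have closed-form answers:

```r
round(optimal_lambda(), 2)          # most precise dilution
#> [1] 1.59
relative_ci_width_table(c(2, 4, 8)) # diminishing returns of replicates
#>   m      width improvement_pct
#> 1 2 1.00000000              NA
#> 2 4 0.17710476       35.944648
#> 3 8 0.09304998        9.604286
```

So aim near 1.6 copies per partition, and use at least 4 technical
replicates — the interval width falls steeply up to there and only
marginally beyond 8.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes, from scratch at run time: the optimal concentration by
root-finding on the relative-variance derivative; the asymptotic
relative bias magnitude at 5 copies/partition under 10% partition-size
variation by quadrature; and the concentration minimising the relative
RMSE of the replicate-based estimator in a simulated scenario with
partition loss and unequal sizes (200 experiments of 8 replicates per
grid point).  Results are written as JSON keyed by target id.

## Command line

```sh
Rscript inst/cli/dpcr.R simulate --lambda 1.25 --pipette-cv 0.05 --seed 4 --out counts.csv
Rscript inst/cli/dpcr.R estimate --counts counts.csv --volume 0.89
Rscript inst/cli/dpcr.R design --lambda 1.59 --fpr 1e-4 --fnr 0.01
Rscript inst/cli/dpcr.R scenario --lambda-grid 0.18,1.25 --n-sims 1000 --pipette-cv 0.05 --seed 1
```

Exit codes: 0 ok, 2 parse error, 3 boundary (saturated counts).  Data
goes to `--out`/stdout, logs to stderr, and each `--out` run writes a
JSON manifest with the seed and config snapshot for reproducibility.
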