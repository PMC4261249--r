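---
title: "Variance components in digital PCR quantification: model, simulator and design analytics"
author: "dpcrsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Variance components in digital PCR quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpcrsim)
```

## The estimation model

Digital PCR divides a reaction into $n$ partitions (droplets or
microchambers), amplifies, and reads an endpoint fluorescence per
partition.  With $X$ the number of target copies in a partition and
$\lambda$ the expected copies per partition, random dispersal of copies
into equal-volume partitions gives $X \sim \text{Poisson}(\lambda)$, so
the void probability is $p = P(X = 0) = e^{-\lambda}$.  Counting $K$
negative partitions among $n_r$ with a returned readout,

$$\hat\lambda = -\ln(K / n_r), \qquad
  \widehat{\text{Var}}(\hat\lambda) = \frac{e^{\hat\lambda} - 1}{n_r},$$

the variance following from the delta method on the binomial proportion
$K/n_r$.  `estimate_lambda()` implements this with a Wald interval
floored at zero.  Concentrations in copies per nanoliter are
$\hat\theta = \hat\lambda / v$ with $v$ the mean partition volume
(`to_concentration()`).

Technical replicates can be combined two ways:

* **pooling** (`pooled_estimate()`): sum counts over replicates and
  treat them as one reaction.  This is only valid when replicates truly
  share $\lambda$; any between-replicate technical variation is
  invisible to the pooled variance.
* **replicate-based** (`replicate_based_estimate()`): average the
  per-replicate $\hat\lambda_i$ and build a
  $t_{m-1}$ interval from their empirical standard deviation.  The
  empirical variance captures Poisson *and* technical variation, at the
  price of wider (honest) intervals.

The package's central empirical claim, reproduced in the test suite, is
that under realistic pipette error the pooled interval's coverage
collapses (well below 0.5 at a nominal 95%) while the replicate-based
interval stays at nominal coverage.

## The data-generating process

`simulate_experiment()` composes the workflow stages in order, each
independently switchable through `sim_config()`:

| stage | parameter(s) | default | what it models |
|---|---|---|---|
| pipette draw | `pipette_cv` | 0 (off); 0–0.10 realistic | Normal(1, cv) factor on the replicate's effective $\lambda$; lumps pipette error, sample heterogeneity and between-replicate volume variation |
| partitioning | `n_created` | 20 000 | partitions created per replicate |
| partition size | `size_sigma` | 0 (off); 0.1 ≈ 10% volume CV | lognormal relative volumes, rescaled to mean exactly 1 per replicate; copy seeding is Poisson with mean $\lambda s_i$ |
| partition loss | `loss_mean`, `loss_sd` | off; 14 000 / 1 800 typical | number returned drawn from a rounded, clamped Normal; a uniformly random subset is retained (missing completely at random) |
| classification | `fpr`, `fnr` | 0 | per-partition Bernoulli misreads: empty reads positive w.p. `fpr`, occupied reads negative w.p. `fnr` |

Defaults state the conditions of a typical droplet system: 20 000
created partitions, 8 technical replicates (one column of a 96-well
plate), ~30% droplet loss with SD 1800 when loss is enabled, 10%
partition-size CV when size variation is enabled, and a working range of
$\lambda$ from $10^{-4}$ to 5 copies/partition.

Two numerical choices deserve note.  Sizes are rescaled to mean
**exactly** 1 within each replicate so that within-replicate size
heterogeneity does not leak into between-replicate variation — that
channel is modelled (and switched) separately as pipette error.  And the
loss distribution family is a rounded clamped Normal: only its two
moments matter for the estimates because the loss is MCAR.

When `size_sigma = 0` every returned partition reads negative with the
same probability
$p_{\text{obs}} = e^{-\lambda_{\text{eff}}}(1-\text{fpr}) +
(1-e^{-\lambda_{\text{eff}}})\,\text{fnr}$, so `simulate_experiment()`
draws $K$ in a single binomial call per replicate (the *fast path*,
~1000× faster for scenario sweeps).  The per-partition path is retained
as the reference; a two-sample test in the suite checks the two paths
give indistinguishable $K$ distributions.

The fluorescence layer (`fluorescence_model()`, `draw_fluorescence()`,
`apply_threshold()`) is a deliberate invention: two Gaussian clusters
(defaults 2000 and 6000 arbitrary units) with a configurable fraction of
positive partitions emitting uniformly between the cluster centers
("rain").  Real instruments publish no emission distribution; this
stand-in exists to let users *exercise threshold choice* and read off
realized false rates, not to mimic any particular chemistry.

What a green simulation test does **not** establish: the generator has
no spatial correlation of chamber loss, no systematic (non-stochastic)
pipette bias, no inhibition kinetics behind the misclassification rates,
and no between-sample biological variation.  Conclusions transfer to
real experiments only insofar as those mechanisms are negligible or
handled by design.

## Design analytics

All closed-form (no Monte Carlo):

* `optimal_lambda()` — the asymptotic relative variance
  $(e^\lambda - 1)/(n\lambda^2)$ is U-shaped; its minimizer solves
  $\lambda = 2(1 - e^{-\lambda})$, about **1.594** copies/partition
  (~80% positive partitions).  Root-finding is bracketed on
  $[0.5, 10]$ to stay away from the double root at 0.
* `loss_precision_factor()` — MCAR loss inflates the relative SD by
  $\sqrt{n_{\text{created}}/n_{\text{retained}}}$; 14 000 of 20 000
  costs 19.5%.
* `relative_ci_width_table()` — replicate planning: interval width
  $\propto t_{m-1}/\sqrt{m}$, normalised to $m = 2$.  Improvements are
  computed from unrounded widths.  Four or more replicates are
  worthwhile; beyond eight the gain is marginal.
* `misclassification_bias()` / `unbiased_ratio()` /
  `corrected_lambda()` — the naive estimator converges to
  $-\ln p_{\text{obs}}$; false positives dominate at low $\lambda$,
  false negatives at high $\lambda$, and the two cancel exactly when
  $\text{fnr}/\text{fpr} = e^{-\lambda}/(1 - e^{-\lambda})$
  (equivalently $e^{-\lambda}\,\text{fpr} =
  (1-e^{-\lambda})\,\text{fnr}$: expected misread empties equal expected
  misread occupied partitions).  The correction inverts the forward map,
  $\hat\lambda_{\text{corr}} = -\ln\frac{\hat p_{\text{obs}} -
  \text{fnr}}{1 - \text{fpr} - \text{fnr}}$, and supports a two-pass
  analysis: estimate with the default threshold, then re-estimate with
  prior rate information.
* `size_variation_bias()` — with lognormal sizes $S$ (mean 1,
  $\sigma$ = `size_sigma`), $E[e^{-\lambda S}] > e^{-\lambda}$ by
  Jensen, so the estimator is biased down, to second order by
  $-\lambda\sigma^2/2$ (≈ −2.4% at $\lambda = 5$, $\sigma = 0.1$).  The
  lognormal Laplace transform has no closed form; we integrate on the
  standard-normal scale $S = e^{\sigma Z - \sigma^2/2}$, which stays
  well-conditioned as $\sigma \to 0$ where the lognormal density itself
  degenerates to a spike that adaptive quadrature misses.
* `volume_bias()` — reporting $\theta = \lambda/v$ with an inaccurate
  $v$ biases $\theta$ by $v_{\text{true}}/v_{\text{assumed}} - 1$;
  assuming 0.89 nL for droplets averaging 0.868 nL understates
  concentration by 2.5%.

```{r analytics}
round(optimal_lambda(), 3)
loss_precision_factor(14000, 20000)
head(relative_ci_width_table(2:8), 4)
100 * size_variation_bias(5, 0.1)$relative_bias
```

## Monte-Carlo scenarios

`run_scenario()` sweeps a $\lambda$ grid, simulating `n_sims`
experiments per point (default 1000, matching the stable-summary
convention for this kind of study) and summarising relative bias,
relative SD, relative RMSE
$\sqrt{\text{relVar} + \text{relBias}^2}$ and CI coverage per
estimation method.

Degenerate runs are handled explicitly: a replicate with *zero*
negative partitions leaves $\hat\lambda$ undefined (saturation).  Such
runs raise a typed boundary error in the estimators; the scenario
engine excludes them from the moments but counts them in `n_boundary`,
so censoring at high $\lambda$ is visible rather than silent.  A cell
is marked `undefined` only when every run failed.  All-negative
replicates return $\hat\lambda = 0$ with a one-sided rule-of-three
upper bound $-\ln(1 - 3/n)$ — a defined contract for a case the
theory leaves open.

Each grid point derives its seed deterministically from the root seed,
so sweeps sharing a root seed are paired across scenario variants; this
is what `sequential_components_report()` exploits when switching
components on cumulatively (loss → pipette → size → misclassification,
the conventional ordering for this decomposition).

```{r scenario}
cfg <- scenario_config(
  sim_config(lambda_true = 1, n_created = 20000, m = 8, pipette_cv = 0.05),
  lambda_grid = c(0.18, 1.25), n_sims = 200,
  methods = c("pooled", "replicate_based"), seed = 1)
run_scenario(cfg)[, c("lambda", "method", "rel_bias", "rel_sd", "coverage")]
```

Pooled coverage collapses while replicate-based coverage holds — the
design message in one table.

## Numerical and interface choices

* Intervals are built on the $\lambda$ scale by the delta method; a
  log-scale alternative would be asymmetric and is out of scope.  The
  symmetric relative limits match how precision is conventionally
  displayed across dilutions.
* $t$ quantiles and all roots are computed at double precision;
  planning-table comparisons round only for display.
* Counts tables are plain CSV (`replicate_id`, `n_returned`,
  `k_negative`) — dPCR has no community standard file format — and every
  CLI run can write a JSON manifest (seed, config snapshot, package
  version) so outputs are reproducible bit for bit.
* The scenario engine's inner loop avoids `data.frame()` construction
  per simulated experiment; containers are assembled once per grid
  cell.

## Known limitations

Single-target chemistry only (no duplex/CNV ratios); no Bayesian or
exact binomial intervals; misclassification rates are taken as given
rather than derived from amplification kinetics; loss is strictly MCAR;
biological (between-sample) replication is outside the model — the
replicate machinery here quantifies *technical* variation, and real
studies need biological repeats on top of it.
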