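# motorlab

Quantitative single-molecule analysis of viral genome packaging by the
bacteriophage T4 terminase motor (gp17), a ring ATPase that pumps DNA into
the capsid. The package is aimed at single-molecule biophysicists working
with fluorescence (TIRF) and optical-trap recordings of packaging motors,
and at anyone who wants a fully testable re-implementation of this analysis
chain on synthetic data.

It implements five connected analyses:

* **Stoichiometry from photobleaching.** Cy3 step counts pooled over motors
  follow a binomial law, $s(k) = \binom{n}{k} p^k (1-p)^{n-k}$, with ring
  size $n$ and labeling efficiency $p$; a zero-truncated likelihood accounts
  for invisible unlabeled motors, and candidates exceeded by an observed
  count are infeasible. Step counting is penalized changepoint segmentation
  with merged-step resolution and an edge-preserving nonlinear
  forward–backward filter for smoothing.
* **Coordination model.** Motors assembled from a pool with inactive-subunit
  fraction $p$ have $\mathrm{Binomial}(n, 1-p)$ active subunits; ensemble
  activity under a coordination threshold $k_{\min}$ is
  $\mathrm{Activity}(k_{\min}, p) = \frac1n \sum_{k \ge k_{\min}} k f(k,p)$,
  fitted to activity-vs-doping data by least squares.
* **DNA-engagement kinetics.** Changepoint idealization of Cy5 spike
  trajectories; transient (< 2 s) / semi-transient (2–10 s) / long-lived
  (> 10 s) classification; censored exponential-mixture MLE of dwell times
  with BIC order selection; engagement frequencies, class transition
  matrices, and packaged-DNA counts.
* **Optical-trap packaging traces.** Extensible worm-like-chain conversion
  of extension to base pairs and tether screening; rolling-window velocity;
  variance-rule pause detection (> 0.1 s rule) with plateau/unpackaging
  classification; pause-free velocity, pause frequency, and start times.
* **Kinetic Monte Carlo simulator.** Gillespie simulation of packaging as a
  1-D walk with 2-bp steps, exponential slips, inactive-subunit rules, and a
  strict-arrest comparison scheme.

Synthetic-data generators with exact ground truth stand in for the raw
recordings, so the whole chain is testable end to end.

## Worked example

Simulate a stoichiometry experiment at a realistic experimental scale — 486 analyzable
trajectories, 66% labeling, step:noise 3 — and recover the ring size:

```r
library(motorlab)

comps <- sample_motor_composition(520, doping_fraction = 0,
                                  label_prob = 0.66, seed = 7)
pb <- gen_photobleach_traces(comps, seed = 8)
keep <- pb$truth$trace_id[pb$truth$detectable][1:486]
trs <- split(pb$traces[pb$traces$trace_id %in% keep, ],
             pb$traces$trace_id[pb$traces$trace_id %in% keep])

# two-pass counting: per-trace steps, then a dataset-level amplitude
# calibration resolves merged double steps
pass1 <- lapply(trs, count_steps)
unit <- median(unlist(lapply(pass1, function(x) x$step_amplitudes[[1]])))
counts <- vapply(trs, function(tr) {
  count_steps(tr, unit_amplitude = unit)$n_steps
}, integer(1))

fit <- fit_binomial_stoichiometry(counts[counts > 0])
glance(fit)
#> # A tibble: 1 × 5
#>   n_hat p_hat log_lik truncated n_obs
#>   <int> <dbl>   <dbl> <lgl>     <int>
#> 1     5 0.636   -707. TRUE        486
```

The fitted stoichiometry is 5 with labeling efficiency 0.64 (truth: 5 and
0.66); `tidy(fit)` shows that $n = 3, 4$ are infeasible (five-step
trajectories were observed) and $n = 6$ trails by 13.6 log-likelihood
units.

The composition model for a 1:1 active:inactive mix:

```r
composition_pmf(doping_fraction(1, 1))
# P(no inactive subunit)  = 3.1%
# P(>= 1 inactive)        = 96.9%
# P(1 or 2 inactive)      = 46.9%
```

And the packaging simulator at its standard parameters:

```r
r0 <- simulate_packaging(sim_config(n_inactive = 0, p_pause_slip = 0.65),
                         n_traj = 200, seed = 9)
r1 <- simulate_packaging(sim_config(n_inactive = 1, p_pause_slip = 0.75),
                         n_traj = 200, seed = 10)
mean(r0$mean_velocity) / mean(r1$mean_velocity)
#> [1] 2.480726
```

An all-active motor packages about 2.5× faster than a doped one in this
model (observed experimentally as a ~2× ratio, 960 vs 650 bp/s).

`run_pipeline(default_run_config())` runs every stage on synthetic data and
writes TSV/JSON artifacts plus a summary; see the methods vignette
(`vignettes/motorlab-methods.Rmd`) for the models, defaults, and their
rationale.

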