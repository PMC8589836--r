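---
title: "Models and methods behind motorlab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind motorlab}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motorlab)
```

motorlab analyses single-molecule measurements of viral genome packaging by
the bacteriophage T4 terminase motor, a ring of five gp17 ATPase subunits
that pumps DNA into the capsid. The package covers five connected analyses —
subunit stoichiometry from photobleaching, a hetero-pentamer coordination
model, DNA-engagement kinetics, optical-trap packaging dynamics, and a
kinetic Monte Carlo packaging simulator — plus synthetic-data generators
with recorded ground truth, so every stage can be validated end to end
without access to raw recordings. This vignette documents the models, the
defaults and why they were chosen, the numerical choices, and the known
limitations.

## Stoichiometry from photobleaching (Cy3 channel)

A motor whose subunits carry fluorescent labels loses intensity in discrete
steps as the labels photobleach; the number of steps counts the labeled
subunits. Pooled step counts across many motors follow a binomial law: if
the ring has $n$ subunits each labeled with probability $p$, the probability
of observing $k$ steps is
$s(k) = \binom{n}{k} p^k (1-p)^{n-k}$.
Because a motor with zero labels produces no detectable spot, the observable
distribution is the zero-truncated binomial; `fit_binomial_stoichiometry()`
fits both forms (truncation is the default) and profiles the likelihood over
candidate $n$. Candidates exceeded by any observed count are infeasible and
receive zero likelihood — this is what rules out $n = 4$ when five-step
trajectories are observed, while $n = 6$ loses on likelihood because
six-step trajectories never occur. Without truncation the MLE has the closed
form $\hat p = \bar k / n$; with truncation it is found by one-dimensional
optimization. The untruncated option matters for experiments that label only
the ATPase-dead subunits, where zero Cy3 steps co-occur with a valid Cy5
signal.

Step counting itself is a changepoint problem. `count_steps()` uses greedy
binary segmentation with a residual-sum-of-squares gain penalty of
$30\hat\sigma^2$ ($\hat\sigma$ a successive-difference MAD), run on the raw
trace: the penalty calibration assumes independent frame noise, which the
edge-preserving smoother's output violates. Three refinements matter at
realistic signal-to-noise (step:noise 3:1):

* **Merged steps.** Two labels bleaching within a few frames of each other
  merge into one transition of twice the unit amplitude. Detected
  amplitudes are therefore rounded to integer multiples of an estimated
  quantum — the candidate unit whose multiples best explain all transitions,
  with a mild parsimony preference for fewer steps. A dataset-level
  calibration (`unit_amplitude`, e.g. the median detected amplitude across
  an experiment) resolves the cases a single trace cannot, such as a lone
  two-label drop.
* **Early bleaching.** A label that bleaches within the first few frames
  leaves a leading level too short for the global penalty. A direct z-test
  of the initial frames against the first fitted level (z > 4.25,
  accounting for the reference-mean noise) recovers most of these, and the
  total count is additionally anchored on the first-to-last level difference
  divided by the unit amplitude, which is immune to transition-splitting
  errors; a boundary detection always counts as
  exactly one step because one- or two-frame amplitudes cannot support a
  multiplicity estimate.
* **Short levels.** Interior segments shorter than 3 frames are treated as
  transition artifacts; their frames are excluded and the flanking levels
  compared directly.

With these choices, exact-count recovery on synthetic traces (1–5 steps,
step:noise 3, 10 Hz) is about 97% with a ~0.1% overcount rate; the residual
misses are labels bleaching within about one frame of the start and labels
that outlive the recording — both information-limited at the single-trace
level.

The nonlinear forward–backward filter (`nonlinear_fb_filter()`) is provided
for trace smoothing and event thresholding: banks of forward and backward
running-mean predictors (windows $4j$ frames, $j = 1..3$) are combined with
weights proportional to their mean squared one-step prediction error raised
to the power $-20$. The error averages include the current frame, so a
predictor whose window straddles a step is suppressed from the first frame
past the edge — this is what preserves edges to within a frame. The
parameter triple (window 4, bank 3, exponent 20) follows the fluorescence
analysis convention; all three are configurable.

## Hetero-pentamer coordination model

Doping the assembly pool with a molar fraction $p$ of ATPase-dead subunits
yields motors whose active-subunit count $k$ is $\mathrm{Binomial}(n, 1-p)$
(equal assembly affinity of active and inactive subunits is assumed, as
supported by head-binding measurements). Ensemble packaging activity is
modelled by a coordination threshold: at least $k_{\min}$ active subunits
are required for any activity, and each active subunit contributes $1/n$ of
full activity,
$$\mathrm{Activity}(k_{\min}, p) = \frac{1}{n} \sum_{k = k_{\min}}^{n} k\, f(k, p).$$
$k_{\min} = 1$ is a completely uncoordinated motor (activity $1 - p$
exactly); $k_{\min} = n$ is strict coordination (activity $(1-p)^n$).
`fit_kmin()` selects $k_{\min}$ by least squares against observed
activity-vs-doping data, which is assumed pre-normalized to the undoped
condition; ties break toward the more coordinated model. At a 1:1 doping
ratio the model gives the reference numbers 96.875% of motors with at least
one inactive subunit, 46.875% with one or two, and 3.125% fully active.

## DNA-engagement kinetics (Cy5 channel)

Short Cy5-labeled DNA engaging the motor produces intensity spikes.
Engagements are classified by observed lifetime: transient (< 2 s, failed
initiation), semi-transient (2–10 s, aborted packaging), and long-lived
(> 10 s, interpreted as complete encapsidation, with the dye eventually
photobleaching). The boundary values 2 s and 10 s are assigned to the middle
class — the conventional class definitions leave both boundaries ambiguous, so
the convention here is the closed interval [2, 10].

Dwell times between engagements are fit as exponential mixtures: a
two-component mixture for gap times (short gaps within engagement bursts of
the DNA-engaging state; long gaps set by the quiescent state) and a
three-component mixture for lifetimes. `fit_exponential_mixture()` maximizes
the censored likelihood by EM — density terms for observed durations,
survival terms for right-censored ones — with multiple spread-out starts and
BIC order selection. Dwells are measured start-to-start; the ongoing
interval at the end of a recording enters as a right-censored observation,
which removes the length bias against long gaps. The headline summary is
the amplitude-weighted mean $\tau_{avg} = \sum_i w_i \tau_i$.

Idealization (`idealize_engagements()`) segments the raw trace by optimal
partitioning with PELT pruning (penalty $8\hat\sigma^2$ per changepoint;
greedy binary segmentation cannot find two-frame bumps, which brief
engagements are), classifies segments as engaged above a threshold midway
between baseline and a 3-noise-s.d. spike, and refines each event boundary
by maximum likelihood with fixed levels. The baseline is estimated in two
passes (a low quantile, then a refit from provisionally non-engaged
segments) because a plain median fails on traces that spend close to half
their time engaged. On kinetics whose events and gaps sit at or above the
0.1-s frame resolution, ≥ 90% of events are recovered with both boundaries
within one frame at spike:noise 3. Exponential dwell distributions always
place some mass below the resolution — under wild-type burst kinetics
(gap components 5 s and 40 s, transient lifetime ~0.7 s) roughly 10–15% of
true events or gaps span fewer than ~3 frames and cannot be resolved by any
detector at this sampling and noise; detected event counts still track the
resolvable truth within ~15%, and this limit applies equally to analyses of
real recordings.

## Optical-trap packaging dynamics

At constant force the tether's extension is proportional to the unpackaged
length: $x = N_{bp} \cdot 0.34\,\mathrm{nm} \cdot x_{rel}(F)$ with the
extensible worm-like chain
$x_{rel}(F) = 1 - \tfrac12\sqrt{k_BT / (F L_p)} + F/K$
(persistence length 50 nm, stretch modulus 1000 pN, $k_BT$ = 4.11 pN·nm at
23 °C; 0.9409 at 5 pN). Tethers are screened by fitting a constant extension
offset against the model for a 3400-bp tether (1156 nm contour, i.e.
3400 bp × 0.34 nm/bp; this tether length is sometimes quoted with a bp unit
attached to the 1156 figure, which is read here as nm) and rejecting
offsets outside [−100, 50] nm or
residual extremum/variance above global thresholds (defaults 15 nm and
25 nm², a few times the measurement noise).

Velocity is the slope of an ordinary least-squares line over a running
0.1-s window, sign convention packaging-positive. Pause detection assigns a
velocity threshold from the variance of the velocity series —
`max(v_floor, median(v) − c · MAD(v))` computed over the packaging mode
(points above the floor), since pause-heavy traces otherwise inflate the MAD
and collapse the threshold — and records below-threshold intervals
outlasting 0.1 s plus half a window (the window smears a stall of duration
$d$ into an excursion of about $d + w/2$; the allowance keeps sub-0.1-s
interruptions from being reported, per the > 0.1 s pause definition).
Pauses are plateaus (|v| within a 50 bp/s band) or unpackaging events
(gradual DNA release, observed from about −100 to −500 bp/s). Per-trace
metrics excise the pauses, catenate the packaging intervals, and report the
pause-free velocity as packaged base pairs over packaging time, with a
half-window guard trimmed at pause edges so boundary smearing does not bias
the velocity; pause frequency is pauses per kb packaged, and the start time
is the interval from ATP exposure to the first packaging instant (an
initial non-packaging interval is the start delay, not a pause). Median
pause-free-velocity error on synthetic traces is well under 5% across
100–2000 bp/s; below ~300 bp/s individual plateaus become hard to
distinguish from packaging noise and detection degrades gracefully.

## Kinetic Monte Carlo packaging simulator

Packaging is a continuous-time 1-D walk on unpackaged length, simulated
with the Gillespie algorithm. Each event is either a controlled 2-bp
packaging step (probability $1 - p_{pause\&slip}$) or an uncontrolled
pause-and-slip releasing an exponentially distributed length (mean
$\mu = 0.5$ bp); event durations are exponential with means 10 (package)
and 2 (pause&slip) arbitrary time units. Trajectories start with 30–40 bp
pre-packaged out of 3400 bp, succeed when the unpackaged length reaches 0,
and fail when it exceeds the DNA length (the tether slips out).

Two readings of the inactive-subunit rule are implemented:

* **Effective (default).** $p_{pause\&slip}$ is a condition-level parameter
  already reflecting the motor's inactive-subunit content — 0.65 for an
  all-active motor and 0.75 for motors with one or two inactive subunits —
  and the walk is homogeneous. This is how such simulations are run in
  practice: the per-condition probabilities are calibrated against the
  measured velocities and encapsidation success rates. A fully inactive
  motor can never package and always fails.
* **Per-position.** A grip pointer rotates around the ring and packaging is
  forbidden whenever it sits on an inactive subunit. With condition-level
  $p_{pause\&slip} = 0.75$, `kmc_expected_drift()` shows the per-event
  drift is exactly zero for one inactive subunit and −0.125 bp for two:
  under this literal reading doped motors cannot sustain packaging over
  3400 bp, so it cannot produce the observed ~2× velocity ratio. It is kept
  as an option because it is the more mechanistic picture and its
  qualitative predictions (drift signs, guaranteed failure at full doping)
  are tested.

Under the effective reading, renewal-reward arithmetic gives asymptotic
velocities $0.375/4.8 = 0.0781$ and $0.125/4.0 = 0.0312$ bp per time unit
for the two conditions — a ratio of exactly 2.5, with finite-length and
success-conditioning corrections bringing simulated ratios to ≈ 2.49. A
`strict_arrest` scheme (permanent arrest when the pointer reaches an
inactive subunit) provides the strictly coordinated null: its success
fraction is zero for any doped motor. Velocities are reported in bp per
arbitrary time unit and only ratios are interpreted. Slip lengths are
continuous by default; integer rounding is available. Inactive subunits are
placed randomly on the ring per trajectory. The grip pointer advances after
every event by default (the minimal rule consistent with continued
cycling); advancing only after packaging events is available but stalls
per-position doped motors by construction. The per-trajectory event cap
(10^6) bounds runtime in near-zero-drift configurations and marks capped
runs as censored.

## Synthetic data: what it does and does not emulate

The generators produce the three data classes the analyses consume, each
with exact ground truth: Cy3 photobleaching staircases (independent
exponential bleach times per label; initial intensity = label count ×
step amplitude), Cy5 engagement trajectories (gap-mixture sampling of
quiescent intervals — the mixture is the observable the analysis fits, so
gaps are drawn directly rather than through a hidden two-state process —
with per-engagement photobleach censoring at a 40-s mean), and
constant-force extension traces (worm-like-chain conversion, Poisson pause
placement in packaged length, plateau or unpackaging pauses).

Study-condition defaults, fixed once: 0.1-s frames everywhere; photobleach
mean 15 s over 100-s recordings with unit step amplitude and noise 1/3
(step:noise 3 — no reference signal-to-noise is available, so a value at the
conservative end of single-molecule practice was chosen and is exposed as
configuration); wild-type gap mixture (0.8, 5 s; 0.2, 40 s), whose
amplitude-weighted mean is 12 s; engagement-lifetime mixture with weights
(0.6, 0.2, 0.2) and means (0.7, 4, 30) s, putting ~80% of engagements in
the failed classes; trap traces at 960 bp/s pause-free velocity, 1.2
pauses/kb, 0.8-s mean pause duration, 10% unpackaging pauses at −300 bp/s,
2-nm extension noise at 200 Hz. Noise is i.i.d. Gaussian per frame and the
baseline is zero: no camera artifacts, drift, blinking, spectral crosstalk,
or image-level effects are modelled. Passing tests therefore demonstrate
correctness of the inference chain under the stated stochastic models, not
robustness to instrument systematics.

## Reproducibility and numerics

Every stochastic function takes a `seed` and restores the caller's RNG
state; identical seeds give bit-identical outputs, and `run_pipeline()`
derives fixed per-stage sub-seeds from its global seed so summaries are
byte-identical across runs. EM fits converge on relative log-likelihood
changes below 1e-9 with five restarts per order; mixture weights and
lifetimes are reported in ascending-lifetime order. Changepoint penalties,
detection thresholds, and the pause rule constants are documented at each
function and exposed as arguments. Simulation problem sizes used by the
test-suite checks (for example, 100 datasets of 486 photobleaching traces
for the stoichiometry recovery study, 1500+ successful trajectories per
simulated packaging condition) were chosen to keep Monte Carlo standard
errors a few times smaller than the tolerances being checked.
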