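---
title: "Models and methods behind reachadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind reachadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reachadapt)
```

`reachadapt` analyzes implicit visuomotor adaptation in center-out shooting
tasks: a participant slices a cursor through a target on a 5 cm ring while
the cursor is perturbed — clamped at a fixed angle from the target
(task-irrelevant feedback that drives purely implicit adaptation), rotated
against the hand (task-relevant), or ramped up so slowly that the
perturbation goes unnoticed. This vignette documents the models, the
estimators, the tunable parameters, and the numerical choices, in the order
of the pipeline.

## Experiment schedules

Three designs are built trial-by-trial by `build_design()`:

| design | days | targets | phases per day (cycles) | perturbation |
|---|---|---|---|---|
| 1 | 2 | 8 (every 45°) | baseline 15, adaptation 40, decay 40 | 30° CCW clamp (day 1), abrupt 30° CCW rotation (day 2) |
| 2 | 1 | 4 (diagonals) | baseline 40, adaptation 80, decay 80 | 4° CCW clamp |
| 3 | 2 | 8 | baseline 20, adaptation 40, decay 40 (day 1); day 2 as design 1 | ramp 0→30° over 320 trials (0.09375°/trial) |

A cycle visits each target exactly once in seeded random order; baselines
of designs 1 and 2 end with 10 feedback-free cycles, and design 3's day-1
baseline is all veridical. The gradual ramp applies `k * 30/320` degrees on
the k-th ramp trial (1-based), reaching exactly 30° on trial 320.

Two bookkeeping notes. First, the customary session summary for the
gradual design — 110 cycles, 880 trials — does not equal the enumerated
day-1 phase sum (20 + 40 + 40 = 100 cycles) nor the day-2 sum (95); the
enumerated design keeps the per-phase counts, and
`published_bookkeeping()` carries the summary arithmetic separately so both
readings stay reproducible. Second, stimulation timing (20 min from cycle
11, or cycle 31 in design 2) is metadata only: group labels are carried
through the pipeline, but no electrical quantity is modelled, and the
sham ramp-up/down protocol is not represented beyond the label.

## The synthetic cohort generator

The generator exists so that every downstream stage has ground truth. It
is a *stand-in* for real participants — its parameters are free simulation
knobs, not estimates of any real cohort.

A hidden implicit state $u_n$ (degrees, clockwise-positive compensation)
evolves over trials $n$ with retention $A$ and error sensitivity $B$:

* **clamp** (angle $\theta$): $u_{n+1} = A u_n + B\,\theta \max(0, 1 - u_n/U)$,
  a soft saturation at $U$ — small clamps drive slower, and the drift
  saturates rather than growing to the clamp angle;
* **rotation** $r_n$: $u_{n+1} = A u_n + B (r_n - u_n - s_n)$, ordinary
  error-corrective learning, where $s_n$ is the explicit strategy;
* **no feedback**: $u_{n+1} = A u_n$, geometric decay;
* **veridical**: the $r = 0$ rotation case.

The strategy $s_n$ is engaged only for abrupt rotations (the two-day
designs' re-adaptation phase): a fraction `explicit_gain` of the rotation,
ramping in over the first `explicit_ramp_cycles` cycles, accompanied by a
transient reaction-time jump (`rt_jump_ms`, decaying with time constant
`rt_jump_tau_cycles`). The strategy rotates the hand: the produced reach
direction is `target − u − s − bias − noise`, so the measured angular
deviation is $u_n + s_n + \text{bias} + \nu_n$. An alternative convention
keeps $s$ out of the reach (strategy as pure error cancellation); it was
rejected because re-adaptation would then plateau at the implicit
asymptote (~15° of 30°) instead of the near-complete ~26° compensation
that strategy-aided re-adaptation shows.

Trajectories are straight minimum-jerk reaches (radial profile
$10\tau^3 - 15\tau^4 + 6\tau^5$) of `reach_dist_cm` = 8 cm at the trial's
movement time, sampled at 125 Hz, with a hold at the origin during the
reaction time and a hold at the endpoint until 0.5 s past the 5 cm ring.
Straight reaches (no online correction) reflect the fast shooting
instruction of the task. Direction noise is per trial, not per sample; a
small per-sample jitter (`sample_jitter_cm`, 0.02 cm SD) is added so that
the low-pass filter has something to do.

Default parameters, chosen once to reproduce the qualitative phenomena of
this experiment family and then left alone:

| parameter | default | unit | rationale |
|---|---|---|---|
| `A_retain` | 0.995 | /trial | per-cycle decay $0.995^8 \approx 0.961$, the observed slow feedback-free decay |
| `B_learn` | 0.02 | /trial | gradual-ramp terminal compensation ≈ 20° of 30°; 4° clamps adapt visibly slower than 30° |
| `clamp_asymptote_deg` | 20 | deg | clamp-driven drift saturates in the 15–20° range |
| `motor_noise_sd_deg` | 3.5 | deg | typical trial-to-trial direction SD of shooting reaches |
| `baseline_bias_sd_deg` | 2 | deg | between-participant idiosyncratic bias |
| `rt_base_ms`, `rt_noise_ms` | 350, 40 | ms | ordinary shooting-reach RTs |
| `rt_jump_ms`, `rt_jump_tau_cycles` | 150, 5 | ms, cycles | ~70–80 ms mean RT cost over a 9-cycle window after an abrupt rotation |
| `explicit_gain`, `explicit_ramp_cycles` | 0.5, 3 | –, cycles | fast, partial strategic compensation |
| `mt_mean_ms`, `mt_noise_ms` | 450, 30 | ms | attainment comfortably inside the 0.2–0.8 s window |
| `overnight_retention` | 1 | – | day-2 first cycle matches the end of day-1 decay |
| `group_effect_deg` | 0 | deg | null cohorts by default; set > 0 for power/recovery studies |

What the generator does **not** emulate: online feedback corrections and
curved reaches, two-state (fast/slow) learning dynamics, use-dependent
drift toward repeated directions, savings beyond simple state carry-over,
fatigue or attention drift, and any neural effect of stimulation (group
differences exist only if injected via `group_effect_deg`). Passing tests
on synthetic cohorts therefore validate the *estimators and bookkeeping*,
not claims about real behavior.

## Kinematic processing

Positions are filtered with a 4th-order 10 Hz Butterworth filter applied
forward and backward. Zero-phase filtering was chosen because a causal
filter would delay the speed trace and bias movement onsets late; the
price is an effective attenuation order of 8. Because the generic
forward-backward filter starts from rest, each series is first extended on
both ends with 150 samples of its boundary value; reach trials genuinely
hold steady at both ends, so constant extension is the correct boundary
model and the start-up transients die inside the padding (a constant series
passes through exactly).

Radial speed is the central difference of the distance from the start
position (one-sided at the ends). Movement onset is the first sample of
the contiguous super-threshold run into the peak at which speed exceeds 5%
of the peak — the search walks backward from the peak, so sub-threshold
pre-movement jitter can never trigger onset early. "Peak outward velocity"
is interpreted as peak *radial* speed, the same quantity the onset rule
thresholds. The angular deviation is measured at that peak, as
`target − atan2-direction(hand − start)`, wrapped to the half-open interval
(−180°, 180°], positive = clockwise.

Trials are flagged too slow / too fast when the 5 cm ring is attained
after 0.8 s / before 0.2 s. Flagged trials are *retained* in cycle means by
default — the warning concerns task compliance, not measurement validity —
with `exclude_flagged = TRUE` available; genuinely unprocessable trials
(too few samples, no movement, no ring crossing, peak before onset) are
marked invalid, logged with a reason, and excluded from all averages.
Cycles with no valid trial propagate as missing, never as zero.

## Adaptation metrics

Cycle means are taken over the valid trials of each cycle. The directional
bias of each participant is the mean deviation over the **last five
baseline cycles**, computed per day and subtracted from that day's cycles.
Two corrections are deliberately different: day-2 re-adaptation metrics use
day-2's own bias, but cross-day retention — the first day-2 cycle — is
corrected with the **day-1** bias, because the day-2 baseline would absorb
exactly the retention being measured.

The initial-rate window defaults to *W* = 9 cycles for comparability
across designs. It can be recomputed (`find_learning_window()`): for each
group, one-sided paired t-tests compare each adaptation cycle with its
predecessor, and the stopping cycle is the first whose increase is
non-significant at α = 0.05; *W* is the rounded mean of the group stopping
cycles (stops of 7 and 11 give 9). One-sided is the natural reading of
"stopped increasing"; a zero-variance difference is treated as p = 0 when
the common step is positive and p = 1 when it is zero, so exactly flat
plateaus stop the scan. If no cycle qualifies, the last cycle is returned
with a warning.

For a gradual ramp the deviation rises monotonically and a fixed window is
meaningless; instead each trial contributes
$\text{rate}_n = (AD_{n+1} - AD_n) / e_n$ with $e_n = r_n - AD_n$ the
cursor error experienced on trial $n$, and the per-trial rates are
averaged. Trials with $|e_n| <$ 0.5° are excluded (`epsilon`), guarding
the division. The choice $e_n = r_n - AD_n$ is the visual error the
participant actually saw. See the limitations below for this estimator's
noise sensitivity.

Remaining measures are exact slices: extent = mean of the last 10 learning
cycles, aftereffect = first decay cycle, residue = mean of the last 10
decay cycles, ΔRT = mean RT over the first *W* learning cycles minus the
last 5 baseline cycles.

## Decay estimation

Feedback-free decay is modelled as $x(m) = x_0 \, a^{m - m_0}$ on the
corrected cycle series. Individual series are too noisy for a stable
exponential fit, so $a$ is estimated on the **group-averaged** series, and
uncertainty comes from a participant-level bootstrap: 1000 resamples of
participants with replacement, each resample averaged and refit, with the
95% interval taken as the empirical 2.5/97.5 percentiles (plain percentile
rather than BCa — the extra machinery is not warranted at these n).

The fit itself is nonlinear least squares with $x_0$ profiled out
analytically ($x_0^*(a) = \sum x_k a^k / \sum a^{2k}$), reducing the
problem to a 1-D search over $a \in (0, 1.2]$ (coarse grid, then local
refinement to tolerance 1e-10). This is deterministic, has no convergence
failures on non-degenerate input, and agrees with a Levenberg–Marquardt
fit of the two-parameter model to ~1e-5. $x_0$ is free rather than pinned
to the first decay cycle, which would propagate single-cycle noise into
$a$. An all-zero series is flagged degenerate ($a$ unidentifiable) rather
than silently returned, and a bootstrap aborts if more than 5% of resample
fits fail.

## Group statistics

Two-group measures use the pooled-variance Student t-test — two groups of
41 then give the conventional df = 80 — with a Welch option. Three-group
measures use one-way ANOVA with df derived from the data actually
supplied, never hard-coded. Each two-group test carries a default
Jeffreys–Zellner–Siow Bayes factor: a Cauchy prior with scale
$\sqrt{2}/2$ on the standardized effect, computed by writing the Cauchy as
a scale mixture of normals and integrating the resulting one-dimensional
marginal over the mixing variance with adaptive quadrature (this form is
numerically stable; it agrees with a direct noncentral-t quadrature to
~1e-12). BF10 < 1/3 is reported as moderate support for the null. No
Bayes factor is attached to ANOVA rows (a multi-group default BF is out of
scope), and no multiple-testing correction is applied — each measure is
tested separately, and the report says so.

## Determinism and test problem sizes

Every stochastic step is seeded: the design's target permutations, each
participant (seeds derived from the master seed), the decay bootstrap, and
each replicate of the calibration studies. Rebuilding or resimulating with
the same seed is byte-identical.

The validation suite runs at sizes chosen to make the properties sharp but
cheap: noiseless single participants for closed-form recovery (the
trajectory pipeline reproduces commanded directions to < 0.01°), 41
simulated participants × 100 replicates for decay-CI coverage, 20
participants × 320 trials for gradual-rate recovery, and 200 replicate
null experiments of 10 + 10 participants (on the 4° design trimmed to the
baseline tail plus the 9-cycle window) for t-test calibration and Bayes
factor behavior. The null calibration uses state-level simulation — the
learner's per-trial deviations without trajectory synthesis — which is
legitimate because the trajectory → kinematics layer is separately shown
to reproduce those deviations to within 0.01°.

## Known limitations

* **The trial-wise gradual learning rate is noise-fragile.** The
  numerator and denominator of $\text{rate}_n = \Delta AD_n / (r_n - AD_n)$
  share the trial's motor noise $\nu_n$. Writing the steady tracking lag as
  $e^*$, the estimator's expectation is approximately
  $B - \sigma^2/e^{*2}$ for small noise and drifts toward 1 when
  $\sigma \gg e^*$ (both numerator and denominator are dominated by
  $-\nu_n$). A single-rate learner consistent with slow feedback-free
  decay tracks the ramp with $e^*$ of only ~0.5–1.5°, so per-trial noise
  above a few tenths of a degree biases the estimate badly; at realistic
  noise the statistic does not recover the generating $B$. It is exact in
  the noiseless, full-retention case, and that identity is what the unit
  tests pin. Users applying it to real data should treat it as a
  qualitative index, not a parameter estimate.
* **Single-rate learner.** One state cannot simultaneously produce a large
  gradual-ramp lag and slow decay (the classic motivation for two-state
  models); the defaults favor matching saturation and decay. The clamp
  saturation is phenomenological (a soft cap), not mechanistic.
* **Bias interplay with veridical feedback.** The simulated baseline bias
  is not corrected by the learner during veridical trials; real
  participants partially correct visible bias.
* **The decay CI is conditional on the exponential form.** Percentile
  bootstrap intervals inherit any misspecification of the single-exponential
  model; with strong floor effects (long decays at small amplitude) the
  fit leans on early cycles.
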