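---
title: "Models and methods: simulating and evaluating bimanual cable-robot therapy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bicar)
```

This vignette documents the models behind `bicar`, the parameters that
matter, the design decisions taken where the problem was genuinely open, and
what the synthetic-data experiments do and do not show about real patients.

## 1. Device geometry and kinematics

The device is a two-cable robot: anchors `A = (-Wb/2, 0)` and
`B = (+Wb/2, 0)` on a fixed frame, `y` measured downward (so everything the
patient can reach has `y > 0` — taut cables), and `x` positive to the
patient's right. Bar rotation `theta` is positive counterclockwise as seen by
the patient; rotating clockwise shortens the left cable and lengthens the
right one. No published dimensions exist for the frame, so the defaults are a
plausible desk-scale device: `Wb = 1.0` m, `Wg = 0.6` m, handlebar drop
`h = 0.7` m. All kinematics are parametric in the geometry.

Three setups share the code path:

* **1-DOF**: only vertical translation; the cable length *is* the drop,
  `L = y`.
* **Planar (2-DOF)**: the two cables triangulate the position;
  `planar_cable_lengths()` offers both the angle-based closed form (with
  `atan2`, so it holds on the whole lower half-plane) and the Euclidean
  distance, which agree to machine precision and cross-check each other in
  the tests. `trajectory_points()` discretizes circles into `N` points at
  angles `i·2π/N + α`; `N = 3, 4, 5` give polygons, and a periodic cubic
  spline (20 points per edge by default) densifies closed paths.
* **Bimanual**: the handlebar attachment points sit at
  `(±(Wg/2)cosθ, h ∓ (Wg/2)sinθ)`; forward lengths are the distances to the
  anchors.

Two choices deserve a note:

* **Inverse orientation.** Each cable length fixes, by the cosine law in the
  anchor / bar-center / attachment-point triangle, the angle
  `ψ± = π/2 ± θ − atan((Wb/2)/h)`. The difference of the two arccos terms is
  therefore `2θ`, and `handlebar_orientation()` returns half of it; this is
  what makes the forward/inverse round trip exact (`≈1e-14` rad over a
  50×50 grid). A closed-form variant in circulation carries `Wg²/2` where
  the attachment-point geometry gives `Wg²/4`; both are implemented
  (`formula = "geometric"` / `"printed"`), each pair round-trips with
  itself, and `closed_form_discrepancy()` reports the length gap between
  them (≈ 5–10 cm at the default geometry) rather than guessing which was
  intended. The geometric model is the default and the authority.
* **Rotation limit.** `theta_max()` is the smaller of the slack-cable limit
  `asin(2h/Wg)` and the inversion fold `π/2 − atan((Wb/2)/h)`, beyond which
  an attachment point crosses the line to its anchor and the arccos argument
  leaves its single-valued branch. The game never commands more than ±30°,
  well inside both.

## 2. The force-map controller and the game

The patient rotates the bar by pressing one side down while lifting the
other. `classify_intent()` implements the force map on each 80 Hz sample:

* **over-force** if either side exceeds `F_max` (default 10 kgf) — a warning,
  movement is disengaged;
* **CW** if `F_right − F_left > ΔF_eff` *and* `F_left < F_rot` (mirror for
  CCW) — the lift condition prevents parking the weak arm;
* **raise** if both sides are below `F_rot`, **lower** if both exceed
  `2·F_rot` (region boundaries are configurable; no published numbers exist
  for them);
* **hold** otherwise.

`ΔF` defaults to 1.2 kgf and `F_rot` to 1.0 kgf against a 1.5 kgf per-side
baseline hold (the weighted bar's static load is not published; 1.5 kgf per
arm is a plausible share of a few-kg bar). Assistance changes the effective
threshold as `ΔF·2^-level`: level 1 halves it, level 2 additionally drifts
the bar toward the target, level 3 performs the movement by itself; negative
levels are resistive. The assist-as-needed rule evaluates the balance of the
last five objects: at `balance ≤ -1` the level rises a step, at
`balance ≥ +3` a positive level falls a step, clamped to `[-3, 3]`; the
adaptation never pushes below 0 on good performance (resistive settings are a
prescription, not an adaptation outcome). These trigger/release numbers are
design choices — only the mechanism is published.

The engagement gate used by the plant (and by the reach planner, which must
anticipate it) adds two robustness measures a real force-triggered controller
needs: the load-cell stream is low-passed with a causal 5-sample moving
average, and the gate is hysteretic — it engages above `ΔF_eff` and releases
below `0.85·ΔF_eff`. Without these, sensor tremor chatters the drive at every
threshold crossing.

The game: a wagon tracks the bar linearly (`wagon = -θ/θ_span`, default span
30° per half-field; clockwise moves it right), one object falls at a time,
and an object is collected when the wagon center is within `tolerance` of it
at floor height — boundary inclusive, so knife-edge captures count (the
anti-frustration reading of the capture window). Modes: **constant**;
**accelerated**, where the fall speed multiplies by exactly 1.10 at every
10th point; **dynamic**, where resistive assistance is scheduled as
`-floor(score/20)` (only the direction "resistive with score" is published —
the schedule is ours). The flower-catching variant is the identical game with
`tolerance = 0.05` instead of 0.15 game units. Objects spawn uniformly, at
least `max(0.25, 1.5·tolerance)` from the wagon so every repetition requires
an actual movement; all randomness comes from the session seed.

## 3. The synthetic patient

`simulate_session()` closes the loop: subject → force map → plant → sensors →
game → assistance → subject. The plant is an admittance model: while the
gate is open, `θ̇ = -c·(F_right - F_left)` with `c = 0.12` rad/s/kgf, chosen
once so session speed parameters land in a plausible range for this device
class; dynamics and inertia are neglected (slow movements, light bar).

One **reach** (one falling object) unfolds as:

1. After a reaction delay `~N(mean, sd)` (floored at 0.15 s; hemiparesis adds
   `0.25·severity` s), the subject presses the driving side with `K`
   sub-movement force pulses while lifting the other side to
   `baseline·(1 - 0.6)`.
2. Pulses rise with a minimum-jerk attack (~0.3 s) to a plateau and release
   the same way. A whole-pulse minimum-jerk bell was tried first and
   rejected: voluntary force develops much faster than a 2–5 s sub-movement
   lasts, and the slow bell made movement onset lag force onset by up to
   half a second, with large variance.
3. `K ~ 1 + Poisson(mean - 1)` (or a fixed count), capped by the correction
   granularity: each sub-movement must advance the bar by at least
   ~0.075 rad, so small targets use few sub-movements. Fragmented movers
   also hesitate: a `pause_fraction` of the movement duration separates the
   pulses (0.12 healthy, 0.45 post-stroke) — this, not slower pressing, is
   how long movement times coexist with the gate's minimum engaged speed.
4. The pulse amplitude is solved (by bisection against the same gate the
   plant uses) so the gated rotation covers the target angle; if even the
   weakest workable press overshoots, the pulses are shortened instead. The
   planned movement duration scales with target amplitude and draws from
   the profile's `movement_time` distribution.
5. Hemiparesis (severity `s` on one side) reduces that arm's force cap by
   `(1-s)`, slows its drives by `(1+0.5s)`, and degrades its lift quality by
   `(1-s)` — at high severity the lift cannot get under `F_rot` and that
   rotation direction is simply unavailable, a deliberately harsh but
   realistic failure mode. The non-paretic arm compensates with involuntary
   pressure bursts during idle phases (rate `1.2·s`/s, 1.5–3 kgf scaled by
   `0.5+s`); the force map classifies them as holds (the opposite side sits
   at baseline, above `F_rot`), so they produce force peaks without moving
   the bar — which is exactly how contralateral compensation shows up in
   per-side peak-force statistics.
6. Tremor is white force noise per side and sample. The sensor model then
   clips forces to the 20 kgf capacity, rounds to the 0.025 kgf quantum,
   samples at 80 Hz, and quantizes the angle to `2π/2000` (500 ppr encoder,
   quadrature decoding — a documented assumption).

Each reach's **ground truth** is recorded in `metadata$truth`: the drawn
delay, the realized movement onset and end (first gate engagement; gate
release after first entry into the tolerance band — the generative
counterparts of the evaluator's `T_i`/`T_f`), the executed sub-movement
count, direction, amplitude and outcome. Recovery tests compare measured
parameters against these, not against nominal profile means.

The default profiles are **calibration targets, not measurements**: the
healthy profile is tuned so that session-level reaction time ≈ 0.73 s and
movement time ≈ 2.5 s, and the post-stroke profile (severity 0.4, left) so
that ≈ 1.03 s and ≈ 4.6 s, with ~4 nominal sub-movements — the group means
this class of device reports. The profile's `reaction_delay` is the
force-onset delay; the observable movement onset follows ~0.2 s later (force
development time), and the calibration accounts for that.

## 4. The evaluation engine

Derivatives come from Savitzky–Golay polynomial differentiation
(`signal::sgolayfilt`, order 3, 0.35 s window by default): exact on
polynomials, and the only practical way to reach the third derivative of a
quantized encoder signal. Each change of desired angle opens a repetition
with landmarks:

* `T_0` — target issued;
* `T_i` — first sample with productive force direction, smoothed speed above
  the onset threshold, **and** recorded position more than one encoder step
  from its pre-movement value. The displacement condition is ours: the
  smoothed velocity is acausal (the filter window sees ahead), which
  otherwise detects onsets up to half a window early; position cannot move
  before the movement. Recovery against simulator truth shows onset bias
  well under one sample interval's worth of standard errors.
* `T_d` — first sample within the position tolerance, which by default is
  the game's capture tolerance mapped to angle, so the evaluator and the
  game share one success criterion;
* `T_f` — first sample after `T_d` with speed below the end threshold.

Onset/end thresholds default to 5% of the session's median per-repetition
peak speed (floored at 0.01 rad/s); only "a threshold" is published, the 5%
rule is ours. Repetitions without an onset, or without a `T_d` (lost
objects), are marked and excluded from time/speed statistics — marked, never
raised.

Parameters per repetition (then averaged after outlier validation):
`ω_m = mean|ω|` and `ω_p = max|ω|` over `[T_i, T_f]`;
`J_n = (1/ω_p)·mean|jerk|` — the **absolute** jerk integrand is the default
because the signed integral telescopes to the acceleration difference of two
near-rest endpoints and would measure almost nothing; the signed variant
stays available via `segmentation_config(signed_jerk = TRUE)`;
`N_p` = local maxima of `|ω|` with topographic prominence at least 15% of
`ω_p` (floored at one peak for any moving segment), counted by a small
prominence routine (`find_peaks()`) because no installed package exposes
prominence-based peak picking; the RMS of `θ − θ_d`, reported in degrees.

Session-level force peaks use the same prominence machinery with an absolute
0.5 kgf floor after a 5-sample moving average — unsmoothed 80 Hz tremor
otherwise floods the peak set with sub-kgf ripples and the outlier fence then
discards the genuine presses. `δF = F_p,left − F_p,right` (positive when the
left peaks are higher). Torque contributions are force deviations from the
per-side baseline (median force outside movement windows) times the `Wg/2`
lever, in kgf·cm, signed by the rotation they induce and classified
productive/counterproductive against the repetition's direction; total torque
is positive only when both sides are net productive — the per-side formula is
not published, this baseline-deviation construction is a documented
interpretation validated against the qualitative compensation behavior.

Outlier validation is the 1.5·IQR fence applied to every per-repetition
parameter before averaging (guarded below four values); the published rule
says only "statistical outlier relative to peak values". On clean simulated
sessions it discards well under 25% of repetitions.

## 5. Reporting

`progress_history()` aggregates report series by ISO calendar week (the week
convention is ours). `group_compare()` computes per-parameter group means,
the integer-percent excess `round(100·(B_adm − A)/A)` of one group's
admission mean over a reference group's first-session mean, and a paired
two-sided Wilcoxon signed-rank test of admission vs discharge at the 0.05
level — only the significance level is published; the signed-rank choice is
ours (paired, small n, no normality assumption). Single-subject groups are
compared without p-values.

## 6. What the synthetic experiments show — and what they do not

The generator reproduces the *statistical structure* the metrics engine
measures: delays, asymmetric force peaks by hemiparesis side, fragmentation
with a known sub-movement count, quantized sensors, closed-loop game
adaptation. Tests demonstrate that under these conditions the evaluator
recovers reaction/movement times within 3 standard errors of the generative
means over 100-repetition sessions, sub-movement counts within ±0.5, the
correct `δF` sign in ≥95% of seeded replicates, and the expected monotone
responses (severity → |δF| up, score down; fragmentation → `N_p`, `J_n` up;
smaller capture window → no higher score on identical streams).

None of that is evidence about real patients. The model has no EMG, no limb
dynamics, no learning within a session, no spasticity beyond white tremor and
pulse fragmentation, and a single compensation mechanism; patient-derived
outcome values from clinical use of such devices are not reproducible from
this package and are not claimed. Problem sizes in the test-suite (100
repetitions per session, 40 replicates for the sign test, 50–60 repetitions
for monotonicity contrasts) were chosen as the smallest sets with comfortable
statistical margins for the properties tested.

## 7. Known limitations

* The plant's gate gives movements a minimum engaged speed of about
  `c·0.85·ΔF_eff`; very slow continuous drifts cannot be simulated — slow
  subjects pause instead (which matches how fragmented movement presents).
* Bar height is fixed during a session; raise/lower intents are classified
  but not simulated as motion.
* The assist-drift level (2) can leave a small residual oscillation around
  the target near capture, a mild optimism for assisted scores.
* Encoder resolution assumes quadrature decoding; with plain edge counting
  the angle quantum would be four times coarser and onset detection
  correspondingly later.
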