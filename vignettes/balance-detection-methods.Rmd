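---
title: "Detecting impaired balance from treadmill gait: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting impaired balance from treadmill gait: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gaitbalance` studies a question that matters for fall prevention: which
gait-derived balance metrics can actually *detect* an impairment, and how
much does a within-subject baseline help? Because human datasets of
artificially impaired walking are rare and not generally shareable, the
package pairs the analysis pipeline with a synthetic cohort generator whose
ground truth is known exactly, so every stage — event detection, metric
estimation, threshold-based detection, bootstrap uncertainty — can be
validated as a measurement instrument before it is pointed at real data.

# The emulated protocol

The generator emulates a treadmill protocol: a cohort of 10 subjects walks
at 1.25 m/s under one unimpaired and three impaired conditions (ankle
braces restricting actuation, an eye mask removing vision, pneumatic jets
injecting foot-placement noise). Per condition each subject performs two
~3 min steady-state trials flanking a perturbation bout of 16 pelvis
perturbations: 7.5% or 15% bodyweight for 300 ms, in four directions, each
direction x magnitude twice, pseudorandomly ordered, 25–30 s apart, with
onset at left-leg midstance. Signals mirror an instrumented-treadmill
laboratory: marker trajectories at 100 Hz (calcaneus, fifth metatarsal and
ankle per foot; four pelvis markers; C7), per-belt vertical ground reaction
forces and the combined center of pressure at 1000 Hz, and perturbation
force channels. Coordinates: x fore-aft (+ forward), y medial-lateral
(+ leftward), z up.

# The statistical skeleton (step level)

The generator is layered. The statistical layer draws, per trial:

* **Heel-strike times.** Alternating sides; step times Gaussian with a small
  left/right asymmetry (removed later by the step-time metric's per-side
  demeaning). Toe-off follows at a fixed stance fraction (0.65) of the
  stride, so midstance — defined throughout as the temporal midpoint of
  ipsilateral stance — falls at 32.5% of the gait cycle.
* **Step widths and the placement law.** Signed step widths are drawn iid
  Gaussian, and the CoM midstance state is *solved* from the linear
  foot-placement law

  `placement = b1 * (CoM_y − stance heel_y) + b2 * CoM_vy + e`,

  (defaults b1 = 1.3, b2 = 0.25 s, residual SD 0.012 m). This inverse
  construction makes the law hold exactly at every step, keeps the residual
  SD exactly at its configured value, and keeps steady-state widths exactly
  iid — which is what makes the chi-square parameter-recovery tests sharp.
  The price is a known unrealism: absolute foot position performs a slow
  random walk (no station-keeping), which is harmless here because every
  metric is a relative quantity.
* **Perturbation responses.** A perturbation adds a decaying displacement
  and velocity offset to the CoM regressors; because foot placement chases
  the displaced CoM *through the law*, the offsets are solved sequentially
  net of the accumulated foot response so that the absolute ML CoM
  displacement at the next left-leg midstance equals the configured
  response (default 0.05 m at 7.5% bodyweight, scaled by magnitude and by
  the condition's response multiplier). The law holds exactly in perturbed
  data too, so regressions on steady-plus-perturbation pools stay unbiased.
  Recovery steps are capped from crossing the stance foot, mirroring the
  emulated protocol's safety boundary, which prevented crossover steps.
* **Stutter steps.** With configurable probability (concentrated on
  high-magnitude ML perturbations, ~5% of recoveries overall), the first
  recovery step is preceded by a brief touch-down *behind* the
  contralateral foot — the signature the exclusion logic must catch.
* **Divergence states.** Each stride carries hidden states iterated by a
  skew-tent map whose Lyapunov exponent (the branch entropy) equals the
  condition's divergence rate (default 0.35 per stride, multiplied under
  impairment). Pure amplitude noise would not do: scaling all noise leaves
  log-divergence slopes invariant, whereas a chaotic map gives a genuinely
  positive, controllable divergence rate.

Each subject's baselines are drawn once and shared across conditions, so
inter-subject offsets are unrelated to impairment. A single latent
"variability temperament" per subject (SD 0.25 around 1) scales the
subject's step-width SD, step-time SD and placement residual SD together;
its spread is configured through `inter_subject_sd$placement_noise`.
Impairment multipliers (per condition, applied to SDs, the divergence rate,
mean step width and the CoM response) default to values whose
across-impairment averages land at +54% step-width SD, +53% step-time SD and
+30% mean step width. All defaults live in one file,
`inst/extdata/default_cohort_params.yaml`; none are measured values, and
all are tunable through `cohort_config()`.

Gaussian step width and step time is an assumption, not an observation;
distributional forms for these quantities are rarely reported and the
analytic chi-square recovery bands rely on it.

# The signal layer

`synthesize_trial()` turns the skeleton into channels. Feet ride the belt
backward during stance and swing forward along smoothstep paths with a
0.12 m lift. Stance is transferred between belts over a fixed 0.17 s
cubic-smoothstep load-share ramp; the duration is deliberately constant
because the CoP-velocity zero crossing used for heel-strike detection moves
by tens of milliseconds per 10 ms of transfer-duration change, and a
constant ramp pins the crossing within ~2 ms of the true contact. The
combined CoP is the load-share-weighted average of the foot positions, so
it always lies in the convex hull of the feet and tracks the stance foot in
single support. The CoM's ML trajectory interpolates the midstance knots
with a cubic Hermite spline (position *and* velocity prescribed, so the
placement-law regressors survive the signal round trip); C7 velocity is the
CoM velocity plus a stride-periodic component plus the tent-map deviation
(amplitude 0.25 m/s, kept dominant over other stride-varying components so
the injected divergence governs the estimator's short-term slope) plus
2 mm/s white measurement noise.

Per-trial RNG streams are derived by stable hashing of
(seed, subject, condition, trial), so one trial can be regenerated without
shifting any other, and a fixed configuration and seed reproduce a cohort
bit for bit.

# Analysis pipeline choices

* **Filtering.** All filters are Butterworth designs applied
  forward-backward (zero phase; net gain at the cutoff is the square of the
  single-pass gain). Edges are handled by tangent reflection — the
  deviation from the endpoint tangent line is reflected evenly, a
  C2-continuous extension — with the tangent slope capped to the signal's
  own range so noisy signals cannot launch runaway extensions. CoP is
  filtered at 6 Hz (order 4) before event detection; GRF at 60 Hz (order 2)
  before threshold crossings; marker-derived CoM and C7 velocity chains at
  25 Hz; foot markers feeding step geometry at 10 Hz where filtering is
  needed at all.
* **Event detection.** Heel strikes are rising crossings of the fore-aft
  CoP velocity above 0 m/s (lab frame) and of ML CoP speed above 0.7 m/s;
  candidates from the two detectors within 150 ms (perturbed trials) or
  200 ms (steady trials) are merged keeping the earlier. A 100 ms
  per-detector refractory interval suppresses double crossings. Side is
  assigned from the direction of ML CoP transfer just after the event.
  Candidates are excluded when the striking foot is not in front of the
  contralateral foot, repeats the previous valid side, or has its calcaneus
  at or above 0.2 m — the stutter/marker-height logic.
* **Midstance** is the temporal midpoint between a foot's heel strike and
  its own subsequent toe-off (toe-offs from the 100 N per-belt force
  threshold). The definition is an explicit choice; the alternatives
  (CoM-over-foot, a fixed 32.5% of the gait cycle) coincide with it in this
  generator by construction of the stance fraction.
* **Budgets.** Step metrics use the chronologically first 570 qualifying
  steps of their regime; the Lyapunov exponent uses 144 strides (8 sections
  x 9 strides from each of the two steady trials); computing on fewer is an
  error, never a silent fallback, so no two conditions are ever compared on
  unequal data. Standard deviations use the n−1 convention throughout.
* **Regimes.** Steady = steady trials plus steps 18–23 s after the previous
  perturbation onset; steady-plus-perturbation = steady trials plus the 7 s
  after each onset; the CoM-displacement metric uses only the two 7.5%
  rightward perturbations. (One documented simplification: the lateral
  margin of stability uses the same 18–23 s steady rule as the step
  metrics rather than a separate "7 s preceding" window; with 25–30 s
  spacing the two windows largely coincide.)
* **Lyapunov estimator.** Nearest neighbors are restricted to other strides
  and to nonzero distances (the latter guards bootstrap-duplicated
  strides); divergence records are truncated at segment ends and the mean
  at each normalized time uses available records only; the exponent is the
  OLS slope over the first stride, in units of 1 per normalized stride time
  (the natural unit here; conversion to 1/s would divide by the mean stride
  duration).
* **Detection.** Subject-specific: strictly worse than the subject's own
  unimpaired score (a tie is classified unimpaired — the conservative
  choice). Cohort: weighted logistic regression, weights inversely
  proportional to class frequency — the unique scheme that pins a constant
  classifier at exactly 50% weighted accuracy — with leave-one-subject-out
  folds whose accuracies use the same weights (balanced accuracy) and are
  averaged. Degenerate single-class training folds are skipped with a
  warning.
* **Bootstrap.** The resampling unit is the raw datum the metric consumes —
  steps, or strides for the Lyapunov exponent — redrawn with replacement to
  400 of 570 steps (the conventional printed size; 70% of 570 would be 399)
  or 99 of 144 strides, with models refitted inside every draw.
* **Statistics.** Wilcoxon signed-rank for paired comparisons (exact for
  n ≤ 25, normal approximation with continuity correction otherwise),
  Kruskal–Wallis across metrics with a rank-sum contrast of the variability
  group (step-width, step-time, placement predictability) against the rest,
  all at the Bonferroni-corrected threshold alpha = 0.0071. The
  threshold-type comparison pairs accuracies across the computed metric x
  regime variants (five dual-regime metrics plus the perturbation-only CoM
  displacement). Learning effects: the metric on 200-step windows sliding
  by 100, an OLS slope in metric units per minute, and a signed-rank test
  of the slopes against zero; the generator's drift parameters (default 0,
  i.e. stationary) provide the known-rate oracle.

# What the synthetic validation shows — and what it cannot

Passing tests establish that the pipeline is a faithful instrument: heel
strikes are recovered with ≥99% recall/precision within 10 ms; injected
stutters are excluded without cost to proper steps; the three variability
metrics land inside their exact chi-square sampling bands; the divergence
estimator reproduces a prescribed rate within 5% on a construction with
exactly known divergence and reads near-zero on periodic strides; and the
headline ordering — subject-specific thresholds beat cohort thresholds when
inter-subject spread dominates the impairment effect, both saturate when
the effect dominates — emerges from the detection machinery, not from
tuning.

The generator does not emulate real gait's autocorrelation structure
(widths are iid by design), nonstationarity beyond optional linear drift,
marker soft-tissue artifact, crossover steps, or compensatory strategies
(e.g. the way a real margin of stability can move in opposite directions
under different impairments). Accuracy *levels* obtained on synthetic
cohorts therefore characterize the method under its own assumptions, not
expected performance on human data; the qualitative contrasts (threshold
type, variability metrics versus model-based metrics, the cost of tiny
perturbation-recovery samples such as the two-event CoM displacement) are
the transferable content.

# Problem sizes

The shipped configuration keeps everything desk-scale: 10 subjects x 4
conditions x (two 180 s steady trials + one ~8 min bout), 570-step and
144-stride budgets, 1000 bootstrap samples for step metrics, and the
chi-square recovery study at 100 seeded runs. The acceptance script runs
the full analysis in 10-15 minutes on one core (the per-condition Lyapunov
estimates dominate); the test suite takes about five minutes.
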