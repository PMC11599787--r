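---
title: "Closed-loop neuroadaptive Bayesian optimisation for infant ERP: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop neuroadaptive Bayesian optimisation for infant ERP: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbo)
```

# The problem

Traditional infant ERP designs present two stimuli (e.g. the parent's face
and a stranger's face) and compare group-mean responses. Neuroadaptive
Bayesian optimisation (NBO) inverts the design: a one-dimensional morph
continuum of 12 face images, from 100% parent to 100% stranger, is searched
*during* the recording session. After each 12-trial block the EEG is analysed
in (simulated) real time, the block-level Nc attention response is fed to a
Bayesian optimiser, and the optimiser picks the next image to present. The
session ends when the optimiser repeatedly proposes the same image — that
image is the individual's attentional optimum — or when the block budget is
exhausted.

This package implements the full loop — stimulus space, block preprocessing,
Nc metric, Gaussian-process optimiser, session rules — together with a
synthetic-EEG generator that makes the loop testable end to end, and the
post-hoc statistics used to summarise a cohort of such sessions.

# The stimulus space

`make_stimulus_space()` builds the 12-point grid. Coordinates start at 0
(pure parent) and advance in steps of 0.2, so the pure stranger sits at 2.2;
morph fractions are `i/11`. Distances (`optimum_parent_distance()`) are
reported in coordinate units on the 0–2.2 scale. The space splits exactly
into a parent half (indices 0–5) and a stranger half (6–11); with 12 points
there is no midpoint to assign a tie rule to.

# Block preprocessing

Each presented block yields 12 stimulus-locked trials. The chain
(`preprocess_segment()`), applied per channel and in order:

1. cut a 1500 ms segment, −500 to +1000 ms around the marker (750 samples at
   500 Hz). The asymmetric placement leaves at least 400 ms of guard data on
   each side of the analysis epoch for filter edge effects;
2. linear detrend and mean removal;
3. mirror padding, 1000 samples per end (reflection repeats when the padding
   exceeds the segment length);
4. zero-phase Butterworth band-pass 0.1–20 Hz. The band-pass is realised as
   a cascade of an order-2 high-pass at 0.1 Hz and an order-4 low-pass at
   20 Hz, each applied forward and backward. A single order-4 band-pass
   section would, after the forward-backward (magnitude-squared) pass, dip
   to ≈0.94 gain at 10 Hz — inside the Nc band — whereas the cascade holds
   the 10 Hz gain at ≈0.99 while attenuating 35 Hz to ≈0.01. Because the
   segment is generously mirror-padded, the forward-backward pass is applied
   as the squared-magnitude frequency response of the filters on the padded
   signal (one FFT per channel batch), which is algebraically the zero-phase
   filter on those samples and roughly two orders of magnitude faster than a
   time-domain double pass;
5. removal of the padding and cropping to the −100..+800 ms epoch;
6. baseline correction by subtracting the −100..0 ms mean (the only
   pre-stimulus interval the epoch contains).

The chain is linear, which the test suite exploits
(`pre(a·x + b·y) = a·pre(x) + b·pre(y)`).

## Artifact rejection and the quality gate

`detect_artifacts()` flags a trial-channel when the absolute amplitude
exceeds `amplitude_thresh` (default 200 µV; per-subject practice also uses
250), when the peak-to-peak range exceeds `range_thresh`, or when the
peak-to-peak range is below `flat_thresh` (a consistently flat channel).
The range threshold has no published value; the default of 400 µV
peak-to-peak is configurable and deliberately permissive — with a 200 µV
amplitude ceiling it only adds bite when tightened.

`block_quality()` counts a trial as artifact-free when it is clean on the
six fronto-central channels of interest (Fz, FC1, FC2, C1, C2, Cz). The
block passes when at least 10 of 12 trials are artifact-free. Because "10
artifact-free trials" could also be read per-channel, the rule is a config
knob (`trial_clean_rule: all | majority`); the report always carries the
per-channel clean counts and the percentage of the 72 channel-trials that
survived, so both readings are visible.

`average_and_reference()` averages each channel over its own clean trials,
pools the six channels of interest, pools the two posterior references
(P7, P8), and subtracts the pooled reference. Trials flagged *only* as flat
still enter the averaging pool: flatness marks an uninformative channel, not
a contaminated one, and an ideal (zero-noise) recording would otherwise lose
its reference channels entirely. Flat trials do count as rejected in the
quality gate.

# The Nc metric

`nc_mean_negativity()` implements the target metric: within 250–800 ms, find
the most negative sample; the "biggest negative deflection" is the maximal
contiguous run of strictly negative samples containing that minimum, clipped
to the window; the metric is the positive magnitude of the mean over that
run. Interpretive choices, fixed so the metric is a deterministic function
of the waveform:

* "biggest" refers to peak magnitude, not run width or area;
* runs are delimited by strict zero crossings and clipped at the window;
* equal global minima in distinct runs resolve to the earlier run;
* an all-non-negative window returns 0 with an empty deflection span.

`nc_window_mean_amplitude()` is the traditional signed mean over the entire
window, used for the group-level comparison analyses.

Note that a positive baseline shift does *not* always reduce the metric:
for a Gaussian-shaped deflection a small upward shift trims the shallow
tails of the run and can raise the run mean. The exact behaviour is pinned
down in the tests with flat-bottomed deflections, for which a shift of `c`
reduces the metric by exactly `c` while the run persists.

# The optimiser

`fit_surrogate()` z-standardizes the observed block metrics (recomputed at
every refit) and conditions a Gaussian process with squared-exponential
kernel `k(x,x') = σ_f² exp(−(x−x')²/(2ℓ²))` and homoscedastic noise `σ_n²`
on the observations; duplicated stimuli enter as repeated inputs. Defaults:
`ℓ = 0.44` coordinate units (a bit over two grid steps), `σ_f² = 1`,
`σ_n² = 0.25` in standardized units. Hyperparameters are fixed — no
marginal-likelihood optimisation — so that runs are reproducible and the
12-point problem is never asked to support hyperparameter inference.

`acquisition_scores()` implements expected improvement,
`EI(x) = (µ−y⁺−ξ)Φ(z) + s·φ(z)` with `z = (µ−y⁺−ξ)/s` (and
`max(µ−y⁺−ξ, 0)` where `s = 0`), and the upper confidence bound
`UCB(x) = µ + κ·s`. Proposals (`propose_next()`) take the argmax over the 12
grid points, ties to the lowest index.

**Why UCB is the default.** The session stops early only when the *same*
stimulus is proposed in three consecutive iterations. EI actively avoids
re-proposing a point it has just observed — the expected improvement there
collapses — so under realistic noise EI rarely strings three identical
proposals together and most sessions run to the block cap. UCB keeps
proposing the incumbent once its mean dominates the κ-weighted uncertainty
elsewhere, which is exactly the behaviour the stopping rule presumes. With
κ = 2 a noise-free loop can still sustain an optimum/neighbour oscillation
to the cap in a percent or two of sessions; κ = 1.5 makes the noise-free
loop converge to the true argmax for every tuning position while keeping
realistic exploration (simulated sessions converge ≈96% of the time in
≈8–9 blocks at the default noise level, against the reported ≈85% in ≈10
blocks). Both acquisitions and all hyperparameters remain configurable.

## Session rules

`run_session()` presents the four burn-ins — both extremes plus the grid
points nearest 33% and 66% stranger (indices 4 and 7) — in an order
randomised per subject, then alternates refit → proposal → presentation.
Stopping and bookkeeping:

* the third identical consecutive post-burn-in proposal stops the session
  *without being presented*; the repeated index is the predicted optimum.
  This is the only reading consistent with a 6-block minimum for converged
  sessions (4 burn-ins + 2 presented proposals + the unpresented third);
* a block failing the quality gate is repeated at the same stimulus, at most
  twice; a third failure aborts the session (`completed = FALSE`). Quality
  repetitions count toward the 15-presented-block cap but are not new
  proposals and do not extend the convergence run;
* sessions reaching 15 presented blocks without convergence are completed
  non-converged; converged sessions therefore present between 6 and 14
  blocks.

# The synthetic-EEG generator

`simulate_block()` builds each trial as pink-noise background on all eight
channels plus an Nc template on the six fronto-central channels only; the
posterior references carry noise alone so the reference subtraction cannot
cancel the signal. Choices and what they emulate:

* **Tuning curve.** `response_curve()` is a Gaussian bump on the morph axis,
  `b + A·exp(−(x−x*)²/(2w²))`, in µV of Nc mean negativity. Defaults
  `b = 8`, `A = 7` put the peak near 15 µV, the scale reported for infant
  Nc mean negativity; `w = 0.4` (two grid steps) makes neighbours
  distinguishable but not trivially so.
* **Nc template.** A negative Gaussian deflection centred at 500 ms with
  90 ms SD, so its support lies essentially inside the 250–800 ms analysis
  window. The per-trial depth is drawn `Normal(response_curve, trial_sd)`
  and the template amplitude is calibrated through the actual preprocessing
  chain (the unit template is processed once and its metric used as the
  gain), so that with no noise the downstream block metric equals the tuning
  curve value exactly; the trial-level peak is correspondingly deeper than
  the metric. `trial_sd` has no published anchor (no trial-level variance is
  reported); the default 6 µV gives block-metric noise of roughly 2 µV and
  convergence rates qualitatively comparable to the reported study, and
  should be treated as a free parameter.
* **Background noise.** `generate_pink_noise()` shapes white Gaussian noise
  to a 1/f power spectrum and standardizes to the requested SD (default
  20 µV per sample).
* **Artifacts and attrition.** With probability
  `artifact_prob + fussiness_slope·(block − 1)` per trial-channel, a 400 µV,
  100 ms square pulse is injected at a random latency inside the epoch —
  guaranteed to trip the default amplitude threshold. Attrition is modelled
  solely through this fussiness growth (quality failures → repetitions →
  abort); there is no separate dropout process. Defaults
  (`artifact_prob = 0.01`, `fussiness_slope = 0.002`) yield cohort
  completion around 85–92% with convergence among completers around 85–95%,
  the regime the method is reported to operate in.
* **Cohorts.** `simulate_cohort()` draws ages uniformly over 158–375 days
  and true optima from a point-mass mixture (mass 20/44 at the parent
  extreme, 16/44 at the stranger extreme, remainder uniform over the
  interior, matching the observed clustering). For regression-recovery
  studies a latent age→distance slope can be planted; the latent distance is
  mapped to the grid by randomized rounding, which keeps the conditional
  expectation linear in age so the planted slope is recoverable without
  discretisation bias.

What the generator does **not** emulate: volume conduction and realistic
channel covariance, other ERP components (P1/N290/P400), ocular artifacts
with realistic morphology, attention-dependent latency shifts, or any
dependence of fussiness on stimulus content. Passing tests therefore show
that the pipeline and optimiser behave correctly under a controlled,
plausible signal model — not that the method's empirical performance on real
infants is reproduced.

# Outcome statistics

`summarize_outcomes()` computes the participation / completion / convergence
flow, the optimum histogram with the parent/stranger side split and
extreme-image percentages, and distance and blocks-to-convergence summaries.
`prop_test_two_sample()` is the pooled two-proportion chi-square with Yates
correction (df = 1); on the 24/44 vs 20/44 side split it gives
X² = 0.409, p = 0.522. `mixed_anova()` is the 2 (condition, within) ×
2 (group, between) mixed repeated-measures ANOVA fitted as a multivariate
linear model with Type-III sums of squares; with balanced groups all SS
types coincide, and on unbalanced data the Type-III (unweighted-means)
convention applies. `subgroup_condition_test()` is the paired one-way
repeated-measures ANOVA within a convergence-side subgroup (its F is exactly
the squared paired t). `fit_linear_model()` and `fit_logistic_model()` wrap
OLS and binomial IRLS with per-term coefficients, SEs and two-sided p
values; the logistic wrapper flags non-convergence and (quasi-)separation.
P values are two-sided throughout and no multiple-testing correction is
applied, matching the analysis conventions the statistics mirror.

# Numerical choices and degenerate inputs

* Filters are pre-designed at configuration time and cached; the
  frequency-domain zero-phase realisation is exact for the padded samples.
* ANOVA effects with numerically zero residual SS (relative tolerance
  1e-10 of the total SS) are flagged `zero_residual` instead of reporting a
  meaningless F ratio; an effect SS at the same tolerance reports F = 0.
  Constant data partition no variance and report all-zero effects.
* GP solves add a 1e-10 jitter to the kernel diagonal; posterior variances
  are clipped at 0 before the square root.
* The observation standardization guards `sd = 0` (identical metrics) by
  falling back to unit scale.
* All randomness flows through R's RNG: a session seed makes the session —
  burn-in order, noise, artifacts, proposals — byte-reproducible, and cohort
  seeds derive per-subject seeds.

# Problem sizes used in the checks

The bundled checks run 500 noise-free sessions for the convergence floor
(minimum 6, maximum ≤ 15 presented blocks, 100% convergence), 12 noise-free
sessions for exact argmax recovery, 200 noisy optimiser sessions (block
metric SD 2 µV against a 7 µV peak contrast) for within-one-step recovery,
a 61-subject simulated cohort for the completion/convergence analogues, 200
replicate 44-subject cohorts for age-slope recovery, and a 2000-observation
logistic recovery. These sizes give Monte-Carlo error comfortably below the
effects being checked while keeping a full run in minutes on one core.

# Known limitations

* The acquisition function, kernel and hyperparameters of the original
  real-time implementation are not public; the defaults here are this
  package's own, chosen for reproducibility and for consistency with the
  published session-length and convergence behaviour.
* EDF input is not supported; continuous data enter as headered CSV plus a
  TSV of markers (or directly as simulated blocks).
* The simulator's attrition is a single mechanism (fussiness-driven artifact
  growth); real attrition mixes fussiness, experimenter interruption and
  data-quality aborts.
* Group-level F statistics, published cohort means and attrition percentages
  on real infants are not reproducible from simulation; the statistics
  module reproduces their *computational* definitions, verified on fixtures
  and oracles.
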