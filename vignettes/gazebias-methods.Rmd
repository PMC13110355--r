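---
title: "Models and methods behind gazebias"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind gazebias}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gazebias)
```

`gazebias` implements the analysis chain of a family of experiments that
separate *perceptual* effects of motivation from *behavioural* ones: does
reward change what observers perceive, or only where they look and what
they report? This vignette documents the models, the tunable parameters,
the synthetic observers, and the numerical choices, in enough detail that a
user can judge what a passing test suite does and does not establish.

## The four designs and their observers

Four experimental designs are covered, each paired with a generative
observer whose parameters are the ground truth that the analysis side must
recover.

**Digit detection under value (experiment 1).** Observers saccade to a pair
of noise discs (high-value at +3 deg, low-value at −3 deg on the vertical
axis) and report digit presence at a probed disc; 400 detection trials are
interleaved with 100 adaptive-staircase attention trials (50 per location).
The generative observer (`observer_exp1()`) draws a saccade endpoint per
trial from N(`endpoint_bias_mean`, `endpoint_sd`); its sensitivity at the
probed disc decays linearly with the endpoint-to-target distance,
d′ = max(0, d′₀ − f·dist), and its decision criterion carries a
value-conditioned shift. Responses follow the standard equal-variance SDT
sampling model (internal evidence N(d′, 1) vs N(0, 1), respond "present"
above d′/2 + c), plus a lapse probability. Digits come from a normal
distribution discretised over {1,2,3,4,6,7,8,9}, centred at 7 (high value)
or 3 (low value), with the SD solved numerically so that P(digit > 5) is
exactly 0.75 / 0.25 — the printed rule states "approximately 75%", so the
calibration is pinned at the nominal value. Scoring: +5 for correct
"absent", +digit for correct "present", −5 for errors.

**Pursuit speed judgments (experiment 2).** Two step-ramp intervals per
trial (standard 8 deg/s; comparison in {4, 6, 7, 7.5, 8, 8.5, 9, 10, 12}
deg/s; durations 540/720/900 ms; two 216-trial blocks with 36 repeats of
the three hardest comparisons and 18 of the rest, fully crossed with
stimulus order and duration). The observer's key structure is a *shared
internal velocity estimate*: each interval's estimate is its true velocity
plus trial-level sensory noise, and this single estimate drives **both**
the pursuit trace (velocity = gain × estimate + motor noise) and the speed
report. `perceptual_bias` shifts the estimate of the rewarded interval and
therefore propagates to both readouts; `response_bias` tilts only the
report comparison. This is the dissociation logic the design exists to
exploit: a perceptual bias must show up in pursuit, a response bias cannot.
Closed form: a response bias b moves the two biased-block report PSEs to
8 ∓ b (by rewarded position), so the bias index recovers 2b while the
oculomotor index stays at 0.

Raw traces are synthesised at 1000 Hz: fixation, a 1 deg backward step at
onset, pursuit onset after the latency, and error-triggered catch-up
saccades — raised-cosine velocity pulses with a main-sequence-like duration
(≈ 21 + 2.2·amplitude ms) that extrapolate target motion over the saccade,
triggered when position error exceeds 0.5 deg, rate-limited by
`catchup_rate`.

**Free viewing of ambiguous images (experiment 3).** 34 trials, three
phases: spontaneous viewing with continuous percept report, then two
instructed-percept phases ending in a 2500 ms hold. The hidden percept is a
two-state process with exponential dwell times (mean 1/`reversal_rate`);
no reversal-process model is prescribed by the designs themselves, so this
semi-Markov choice is a deliberately simple stand-in. Gaze drifts towards the diagnostic point of
the *upcoming* percept with first-order dynamics, starting `gaze_lead` ms
before the report flips — the analysis chain must recover that lead as a
pre-zero cluster onset.

**Forced fixation (experiment 4).** An illusion block (4 stimuli × 10
repetitions, five per fixation location) and a composite block (280 trials
per fixation location: 40 repeats of each difficult face proportion 0.42,
0.48, 0.5, 0.52, 0.58 and 20 of each easy one 0.2, 0.33, 0.66, 0.8).
Reports are Bernoulli draws from a cumulative Gaussian whose location is
the fixation-conditioned PSE (`pse_fix_a` = 0.43 at the eye region,
`pse_fix_b` = 0.49 at the house feature by default, matching the magnitude
of the effect the designs were built to detect).

All generators expand one session seed into per-trial sub-streams
(`derive_seeds()`), so identical (observer, spec, seed) triples reproduce
byte-identical sessions and trial-level reproducibility survives
reordering.

## Pursuit signal processing

Positions are filtered with a zero-phase (forward–backward) 2nd-order
Butterworth low-pass at 30 Hz, differentiated by central differences, and
the velocity filtered again at 40 Hz. The cutoffs are conventional for
pursuit work; the underlying literature names the filter family but not
its order or cutoffs. Two numerical points deserve note:

* `signal::filtfilt()` does not condition its initial filter states, so a
  signal that starts away from zero acquires large edge transients. The
  package therefore pads with an odd reflection (200 samples) before
  filtering and trims afterwards; a constant trace then differentiates to
  zero at machine precision.
* Zero-phase filtering mathematically caps the acceleration that a small,
  brief saccade can exhibit afterwards: a 0.5–1 deg catch-up saccade
  cannot exceed roughly 3500 deg/s² once smoothed at 30 Hz. The
  saccade-detector defaults (velocity 30 deg/s **and** acceleration
  8000 deg/s², events merged when closer than 20 ms) are the established
  video-oculography settings for lightly filtered signals and are kept as
  defaults; the experiment-2 pipeline, which detects on the filtered
  velocity, passes `a_thresh = 1500` instead. Both thresholds are exposed
  as arguments.

Desaccading replaces samples within ±10 ms (default padding) of each event
by linear interpolation between the boundary samples, merging overlapping
spans; spans touching a trace edge hold the boundary value and warn.
Pursuit velocity is the arithmetic mean of desaccaded horizontal velocity
over the half-open window [onset + 250, onset + 500) ms; if more than half
of the window was interpolated, the value carries a `low_quality` flag.
Exact velocity ties in the oculometric decision — a measure-zero event with
real noise but routine with noiseless synthetic input — are broken by a
seeded fair coin.

The saccade *endpoint* of the detection experiment is defined as the
landing position of the first saccade whose landing x-coordinate crosses
the vertical midline. A defensible alternative is the post-saccadic
fixation centroid; the first-crossing landing was chosen because it is
well-defined on every valid trial and needs no fixation-parsing layer.

## Psychometric fitting

The model is ψ(x) = γ + (1 − γ − λ)·Φ((x − μ)/σ) with γ, λ ∈ [0, 0.1].
Fitting maximises the binomial likelihood penalised by a weak Beta(1, 19)
prior on γ/0.1 and λ/0.1, which keeps small-n fits off the asymptote
boundary without moving well-identified fits (the prior's mode is 0). The
optimiser is L-BFGS-B from five deterministic starts; with fixed
asymptotes only the two free parameters enter the box (equal bounds would
break the finite-difference gradient), and γ, λ are clamped inside the
objective because L-BFGS-B probes finite differences just outside its box
where the Beta log-density is −∞.

The PSE is defined as μ — the 50% point of the *unscaled* sigmoid — rather
than the lapse-scaled 50% point. This makes the PSE exactly invariant
under γ and λ and robust to asymmetric asymptotes. Convergence is honest:
all-identical responses, fewer than three levels, or a location pinned at
the search-box boundary yield `converged = FALSE` with a diagnostic, and
`pse()` refuses non-converged fits.

The reward-referenced bias index is
s·[(PSE₁ᵇ − PSE₂ᵇ) − (PSE₁ᵘ − PSE₂ᵘ)], where subscripts denote
standard-first/standard-second fits, superscripts the biased/unbiased
block, and s = +1 when the first interval carried the high reward, −1
otherwise. The sign truth table: a bias favouring the first interval makes
the first-order comparison PSE larger (the comparison, presented second,
must be faster to beat a favoured first interval) and the second-order PSE
smaller, so the bracket is positive; with the reward on the first interval
this is reward-consistent, hence s = +1.

## Signal detection and gaze residualisation

d′ and c use the standard quantile formulas; rates of exactly 0 or 1 make
them infinite, so the log-linear correction (add 0.5 to every cell, 1 to
every denominator) is applied when needed, or unconditionally on request.
How the original analyses handled extreme rates is not stated; log-linear
is the common default and the choice is recorded here.

The residualisation asks whether the d′ difference between value locations
survives controlling for gaze. It fits a *single pooled* regression of d′
on the signed mean endpoint with location-specific slopes and a **common
intercept**. The common intercept matters: two separate per-location
regressions would each absorb their location's mean d′ into their own
intercept, making the residual comparison identically zero regardless of
the data. With a shared intercept — empirically motivated by the
near-identical per-location intercepts the pooled data show — the
residuals retain exactly the part of the sensitivity difference that gaze
cannot explain. Two tests are reported: a paired test on the residual
difference, and a "reduction" test on raw-minus-residual difference
(whether controlling for gaze significantly reduced the effect). The
latter's exact form is an interpretation (the source analysis names the
comparison but not the statistic) and is documented as such.

## QUEST staircase

The posterior lives on a 500-point grid over log10 contrast in [−3, 0.5].
The prior is Gaussian in log10 contrast, centred at log10(0.2) with sd 0.3
*log units*: the stated "prior contrast of 0.2 (sd = 0.3)" is ambiguous
between linear and log sd, and the log reading is the QUEST convention.
The assumed psychometric shape is a Weibull with slope β = 3.5, guess rate
γ = 0.5 (two-alternative orientation judgment) and lapse δ = 0.02 — none
of these is stated in the source, so the standard QUEST defaults are used.
Placement is at the posterior mean (the same quantity read out as the
threshold estimate), clamped to [0.01, 0.9] Michelson contrast; the mode
is available as an option. Self-consistency is verified by simulation: a
matched Weibull observer at threshold 0.15 is recovered with |bias| <
0.02 contrast after 50 trials.

The attentional imbalance (M_low − M_high)/(M_low + M_high) is bounded in
(−1, 1) for positive thresholds, positive when performance is worse at the
low-value location, and errors on non-positive inputs.

## Permutation inference

The cluster test takes per-participant condition means (participants are
the exchangeable unit; reversal-level curves are averaged within
participant first — the source does not state this level, and
participant-level exchangeability is the conservative reading). Per time
point a paired t is computed; clusters are maximal runs of contiguous,
same-signed samples with |t| above the cluster-forming threshold
(pointwise two-sided α_cf = 0.05 by default — no threshold is stated in
the source, so it is exposed as a parameter); cluster mass is the summed
t. The null distribution flips each participant's condition assignment
(sign-flip of difference curves); `t_crit` is the 95th percentile of
permuted strongest-cluster masses. p-values use (b + 1)/(B + 1) so that
p ∈ (0, 1]; the plain "proportion exceeding" convention would allow p = 0,
which a resampling test cannot honestly claim.

The fixation-map test permutes, within participant, the assignment of
mean gaze positions to intended percepts; statistics are the distance
between condition centroids or the absolute difference of mean distances
to a diagnostic region, with the same p-value and critical-value
conventions. Type-I calibration of both tests is checked by simulation
(nominal 5%, accepted band 3–7%).

## Group statistics

Cohen's d is mean/SD (one-sample, paired) or the pooled-SD standardised
difference (two-sample); its 95% CI inverts the noncentral-t distribution
of the observed statistic, matching common statistics-suite output (the
source does not state its CI method). The JZS Bayes factor marginalises
the noncentral-t likelihood over a Cauchy(0, √2/2) prior on the
standardised effect via adaptive quadrature (relative tolerance 1e-9),
validated against an independent fixed-grid quadrature to 0.1%. Wilcoxon
signed-rank drops zero differences (Wilcoxon's original treatment), uses
the exact distribution for n ≤ 25 without ties and the
continuity-corrected normal approximation otherwise.

C-RAI questionnaire scoring: six subscales of four items (INT, IDE, IJP,
EXT, AMO, IJN), autonomous = first three, controlled = last three,
self-concordance = autonomous − controlled, z-standardised across the
sample. Whether composites are means or sums of subscale means is ambiguous
in the source; mean-of-means is the default and `composite = "sum"` is
exposed (the two differ by a factor of 3 and z-standardisation removes the
difference downstream).

## Problem sizes, runtime and what the tests show

The test suite and the acceptance script run everything at desk scale:
dissociation cohorts of 30–50 simulated participants with full 432-trial
sessions and raw 1000 Hz traces, 60-participant criterion-recovery runs,
300–500 staircase replicates, 500–1000 null datasets for the type-I
calibration, and 199–4000 permutations per test depending on the
granularity the check needs. These sizes were chosen so each check is
statistically decisive for the property it probes.

Passing tests establish that the analysis chain is internally correct —
that it recovers the parameters of observers whose generative structure
matches the assumed models, agrees with independent oracles, and holds its
error rates under exchangeable nulls. They do not establish that real eye
traces satisfy those assumptions: the synthetic traces contain no blinks,
drift, calibration error, pupil artefacts or binocular disparity, the
percept process is memoryless, and the gaze-percept coupling is first-order
with a fixed lead. The I/O layer tolerates blink-like gaps (NA spans) and
the filter interpolates gaps up to 50 ms, but no blink *reconstruction* is
attempted.

## Known limitations

* Equal-variance SDT only; no ROC or unequal-variance extension.
* No Bayesian posterior over psychometric parameters; PSE uncertainty
  beyond the fit itself must come from resampling at the session level.
* The cluster test controls family-wise error through the max-statistic
  construction only; no TFCE.
* No archived human dataset's layout is hard-coded; `read_trace()`,
  `read_asc()` and `read_trials()` define the input contract an adapter
  for any particular archive would map onto.
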