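---
title: "Methods: climbing-fiber calcium events and stimulus-strength coding"
author: "cfcalcium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climbing-fiber calcium events and stimulus-strength coding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Each adult cerebellar Purkinje cell (PC) receives a single climbing fiber
(CF) from the inferior olive. A CF burst triggers a calcium spike that
invades the whole PC dendrite and is visible in two-photon imaging as a
fast, large, stereotyped dF/F transient (a "calcium event"). In awake
mice receiving periocular airpuffs of graded strength (durations d1-d4 =
8/15/30/45 ms at 30 psi, or pressures p1-p2 = 10/50 psi at 30 ms), these
events carry information about stimulus strength in at least four ways:
the per-dendrite probability of an evoked event, its onset latency and
jitter, the synchrony of the local dendrite population, and the size of
the calcium transient. `cfcalcium` implements the complete analysis chain
for such recordings, together with a calibrated synthetic-data generator,
so that every estimator can be validated by parameter recovery.

## Signal model and dF/F

Raw ROI fluorescence is the mean over a dendrite's mask pixels. The
baseline `Fb` at each frame is the 8th percentile of raw fluorescence in a
centered 1 s moving window (truncated at the trace edges), and
`dF/F = (F - Fb)/Fb`. The centered window was chosen over a trailing one
because it makes the baseline bias symmetric under slow drift; the
percentile uses the linear-interpolation quantile definition (type 7),
which differs from alternatives by much less than the noise for windows of
15+ frames. dF/F is invariant to multiplicative gain of F, so arbitrary
acquisition scaling (including the TIFF serialization gain) is harmless.

A CF event contributes a kernel

    k(t) = A (1 - exp(-t / tau_r)) exp(-lambda t)

normalised to unit peak. `tau_r` and `lambda` are solved jointly so that
the peak occurs at the configured time-to-peak (10 ms) and the *measured*
post-peak half-decay equals the configured half-decay (74 ms) — the
reported half-decay of CF transients is a from-peak quantity, and the rise
term keeps growing slightly past the peak, so the exponential's own
half-time is a little shorter.

## Event detection

Detection is the classic two-step rule: the dF/F trace must match the
kernel template, and the peak amplitude must exceed a threshold
(default 3x the robust noise SD, estimated as `mad(diff(x))/sqrt(2)`).
Implementation details that matter:

* The template is the kernel preceded by a flat 50 ms zero-baseline
  segment, bin-averaged at the trace's sample period. The pre-onset
  segment is what lets the correlation reject windows that begin on the
  decay tail of an earlier event or on a slow non-CF ramp.
* At frame resolution (64 ms) the kernel rise is sub-frame, so a window's
  shape depends on where the event lands inside its bin; the detector
  correlates against a small bank of sub-frame phase-shifted templates and
  scores each window by its best match. At dense (1 ms) sampling a single
  template suffices.
* Detection runs in two detect-and-subtract passes: events accepted in
  pass one are subtracted (unit kernel scaled to the detected peak) and
  the residual is scanned again, which recovers events riding on the decay
  tail of a predecessor.
* Candidates closer than the 200 ms refractory are merged keeping the
  larger-amplitude one (with one sample of slack, since frame quantization
  can pull two peaks at exactly the refractory spacing one frame closer).
* The kernel segment of the template is 200 ms long: within the
  refractory spacing this guarantees a neighbouring event cannot sit
  inside the correlation window and depress the score.

On synthetic data at the default noise level (dF/F SD 0.03 against events
of amplitude ~0.3) the detection tests require recall and precision of at
least 0.95; the dense-mode default path typically reaches ~0.99. Known
limitation: frame-resolution analysis of *stimulated* recordings is not
the default path — at 64 ms the slow non-CF transient is shape-compatible
with the template and passes the small default amplitude threshold, which
degrades precision. Stimulated data are analysed at dense resolution (or
require a higher amplitude threshold).

## Classification, latency, rates

Events whose peak falls in [onset + 50 ms, onset + 200 ms) — half-open,
as all windows in this package — are airpuff-evoked and linked to that
trial; all others are spontaneous. Onset latency is estimated as the last
time before the peak at which the trace crosses 10% of the peak amplitude
*measured relative to a local pre-event baseline* (median over
[peak - rise - 40, peak - rise - 5] ms), with linear interpolation between
samples; the local baseline keeps a slow underlying non-CF transient from
pulling the crossing early. Latencies must lie in (0, 200) ms; events
without a reachable crossing are flagged and excluded. Per-dendrite
latency summaries (median and MAD) include only dendrite x condition
cells with at least 10 latencies: sample medians of a handful of draws
from the skewed latency distribution are heavy-tailed and would dominate
the across-dendrite mean. Spontaneous rate is the spontaneous event count
divided by the recording time outside the evoked windows.

## Probability coding and dendrite categories

Event probability per condition is the fraction of trials with at least
one evoked event; the spontaneous reference 'sp' is the fraction of
matched 150 ms pre-stimulus windows containing any event (the window
length matches the evoked coactivation window; the choice is a convention,
since only the comparison matters). Duration-response profiles are
categorized as graded (category 1) or threshold-like (categories 2-5 =
step at d1-d4). A profile is graded when every condition is responsive
above a spontaneous-corrected floor (sp plus one binomial SE), the rank
order is preserved within one binomial SE, the overall trend is positive,
and a straight line fits the four probabilities at least as well as the
best least-squares step; otherwise the best-fitting step position (of the
four possible) gives the category. The step-fit comparison is needed
because a pure rank test with a noise tolerance cannot reject exact-tie
step profiles.

## Synchrony

Coactivation on a trial is the fraction of responsive dendrites with an
evoked event; fields of view with fewer than six responsive dendrites are
excluded. "Responsive" (not defined in the source analyses) is
operationalised as: the strongest condition's evoked count beats the
spontaneous-window chance level in a one-sided binomial test at alpha =
0.05. For every dendrite pair the measured joint probability (fraction of
trials in which both responded) is compared with the independent
prediction P_i x P_j; extra synchrony is 100 x (measured - independent),
averaged across pairs. Spontaneous co-activation versus mediolateral
distance uses per-frame binarized spontaneous rasters, Pearson correlation
per pair, 50 um distance bins, and a shuffled-frame control (each
dendrite's frame order permuted independently, 100 seeded shuffles).

## Event size, enhancement, and the non-CF signal

Traces are first normalized per dendrite by the peak of the mean
spontaneous event (events aligned on their detected peak frame, no
sub-frame interpolation; the aligned average is baseline-subtracted over
its leading segment so neighbouring-event background does not leak into
the peak). Event size is the trapezoidal dF/F-integral over the 100 ms
after the event peak, divided by the dendrite's mean spontaneous integral
— so spontaneous sizes average exactly 1. Trials with two or more evoked
events closer than 100 ms are excluded from size analyses (with our
generator's 200 ms refractory this is essentially never triggered; the
fraction is reported, not asserted).

The jitter-matched spontaneous reference ('sp') places the dendrite's
mean spontaneous event at the time of every evoked event and averages:
its latency jitter is therefore identical to the evoked conditions, and
jitter smearing lowers its peak below 1. Three details make the
substitution cancel the evoked events exactly under the generator's
additive model (each was diagnosed by a visible bias in the
enhancement-vs-non-CF comparison):

* the substituted shape is the CF kernel scaled to the dendrite's mean
  spontaneous event by least squares over the refractory-protected part
  of its decay ([+20, +150] ms after the peak) and kept on the trace's
  normalized scale — the raw aligned average is unsuitable because it
  carries the refractory hole and post-refractory intensity bump of the
  surrounding activity, a noise-selection spike at the alignment sample,
  and conditional suppression of its flanks;
* the shape is placed at each event's estimated onset plus the kernel
  rise, not at the detected argmax sample, which sits a few ms late on
  the flat transient top (the 10%-crossing onset estimate is unbiased);
* the trials entering the evoked mean are conditioned on having no other
  detected event from -450 ms up to the evoked window, nor in the 100 ms
  the integration window reaches beyond it — mirroring the non-CF trial
  selection, so baseline and analysis windows see the same (event-free)
  background in both routes.

The calcium-event enhancement is the evoked mean trace (pre-stimulus
baseline subtracted) minus the sp reference. The non-CF signal is
extracted from trials *without* any detected event over [-450, 300) ms
around stimulus onset; the exclusion span is wider than the [50, 200)
evoked window because (i) the randomized integration window
[t, t + 100], t ~ U[50, 200), reaches 300 ms, (ii) the 150 ms
pre-stimulus baseline and the window must be conditioned symmetrically —
selecting the window event-free but not the baseline depresses the
non-CF estimate by the mean event mass — and (iii) transient tails last
several decay half-times. Non-CF size uses the same randomized
integration window as the paper-style estimator (one seeded draw per
trial); its rise time is the time from stimulus onset to the peak of the
condition-mean trace, estimated on frame-binned samples with parabolic
interpolation around the peak bin. Enhancement and non-CF integrals are
compared per condition with paired across-dendrite means; the
supralinearity flag fires when the paired difference exceeds its
one-sided t critical value (~2 SEM for many dendrites; the t quantile
rather than a fixed 2 keeps the false-fire rate nominal at small n).

Under the generator's additive model with event gain 1, enhancement and
non-CF integrals agree within sampling error (verified pooled across
replicate simulations); a gain above 1 in a single condition raises the
flag in that condition only.

## The synthetic-data generator

The generator's defaults are the study conditions the analysis was built
for: 12 experiments of 8 dendrites; 32 x 128 px movies at 64 ms/frame
(2 um per pixel, dendrites painted as 3 px vertical stripes); 35 trials
per condition at a 4 s inter-trial interval; spontaneous CF events at
0.7 Hz per dendrite; kernel rise 10 ms and half-decay 74 ms; evoked
probability profiles rising over d1-d4 (0.30/0.45/0.60/0.75) and p1-p2
(0.40/0.70); onset-latency medians 67.1/71.8/78.8/80.9 ms and MADs
23.3/21.1/19.3/18.0 ms for d1-d4 (pressure: 81.3/79.6 ms medians, MAD
21 ms); evoked amplitude gains 1.05-1.40; non-CF rise times
73/114/130/148 ms for d1-d4 with normalized integrals 0.20-0.65; a
per-trial shared facilitation state with probability 0.15-0.30; baseline
F0 = 100 a.u. (arbitrary — dF/F is scale-free); additive Gaussian noise
of dF/F SD 0.03, chosen so that detection is near-perfect, consistent
with treating detected events as ground truth downstream. Non-CF sizes,
pressure-condition jitter and the shared-drive profile are not printed in
the source material; they were fixed once at values that reproduce the
qualitative figures (graded non-CF size, graded extra synchrony) and are
never tuned.

Mechanisms worth spelling out:

* **Spontaneous events** are homogeneous Poisson per dendrite with a
  200 ms refractory. The refractory acts as a non-paralyzable dead time
  (realized rate lambda/(1 + lambda tau)), so the generator draws at the
  inverted rate and the *realized* rate equals the configured 0.7 Hz.
  A distance-dependent fraction of events is shared between dendrites
  (copy probability 0.5 exp(-d/40 um)); primary rates are rescaled by
  solving a small linear system so every dendrite keeps its marginal
  rate.
* **Evoked events**: each trial draws a shared facilitation state
  S ~ Bernoulli(q_c); dendrites fire with probability pHi when S = 1 and
  pLo when S = 0, calibrated so the marginal equals the dendrite's
  profile value. This yields extra synchrony with the closed form
  q(1-q)(pHi - pLo)^2 per pair, used as a test oracle. At most one evoked
  event per trial per dendrite.
* **Spontaneous events whose peak would fall inside a trial's evoked
  window are suppressed**: the stimulated olivary volley dominates that
  window, and the suppression makes the marginal evoked frequency exactly
  the configured profile. The spontaneous-rate estimator only uses time
  outside the evoked windows, so it is unaffected.
* **Onset latencies** are drawn from a Beta distribution scaled to the
  observable onset support [40, 190) ms (peaks in [50, 200)), solved
  numerically to match the condition's (median, MAD). Unbounded
  right-skewed families truncated to this support cannot reach the d1/d2
  jitter values — a truncated log-normal saturates at MAD ~20.4 ms for a
  median of 67.1 ms — while the scaled Beta solves all calibrated
  conditions exactly and remains right-skewed for all of them.
* **Estimator-centred latency calibration** (default): the printed
  latency statistics are across-dendrite means of per-dendrite sample
  medians/MADs at ~35 trials. For the skewed d1 distribution the sample
  median of ~10 events is biased a few ms high, and no distribution on
  the observable support can remove this bias for both statistics at once
  (the support forces MAD < median - 40 ms). The generator therefore
  solves the distribution so that the *expectation of the estimator* at
  the configured trial counts equals the target, using a seeded Monte
  Carlo inside a damped fixed point projected onto the feasibility
  frontier; the residual centering error is below one across-dendrite SEM
  at the study scale. Setting `latencyCalibration = "population"` instead
  makes the population median/MAD match the targets exactly (used by the
  distribution-solver tests and by most unit tests for speed).
* **Rendering** sums event kernels, per-trial alpha-function non-CF
  transients (unit peak at the configured rise time, scaled so the
  100 ms post-peak integral equals the configured normalized size), and
  Gaussian noise, at a 1 ms dense resolution by default, binned to 64 ms
  frames on request; `F = F0 (1 + dF/F)` provides the raw-fluorescence
  path for dF/F recovery testing. Dense validation separates estimator
  accuracy from frame quantization.

What the generator does *not* emulate: motion artifacts, dye
photobleaching and indicator nonlinearity, locomotion-related signals,
ICA segmentation errors, overlapping ROIs, and slow drifts of baseline
fluorescence. Passing recovery tests therefore demonstrates correctness
of the estimators under the stated signal model, not robustness to those
real-data complications.

## Statistical tests

The pipeline applies two-way ANOVA (factors: condition and experiment;
dendrites, trials or pairs as observations, following the table) with
Tukey HSD post-hoc to the probability, latency, coactivation,
extra-synchrony and size tables; two-sample Kolmogorov-Smirnov tests to
the latency-window counts of the weakest versus strongest condition; and
a two-sample t test of measured versus independent joint probabilities
per condition. All tests are two-tailed and p-values are reported
exactly. The printed F degrees of freedom in the source analyses do not
unambiguously identify the factor structure; condition + experiment is a
documented choice, not a claim of equivalence.

## Problem sizes and determinism

The test-suite simulations are sized to exercise every estimator while
keeping the default run short: unit tests use 3-10 dendrites and 10-25
trials per condition; the recovery suite uses 50 dendrites x 600 s for
the spontaneous rate, 12 experiments x ~97 dendrites x 35 trials (dense
rendering) for the latency statistics, and pooled replicate simulations
(3 seeds x 10 dendrites) for the additivity properties. Every random
stage is seeded; identical configuration and seed reproduce
byte-identical report tables.

## Known limitations

* Frame-resolution detection on stimulated recordings needs a stricter
  amplitude threshold than the default 3x noise SD (see above).
* The category classifier assumes four duration conditions; pressure
  data are not categorized.
* The laterality and responsiveness criteria (binomial tests against the
  spontaneous-window chance) are explicit operationalisations of
  judgments made by inspection in the source analyses.
* The multi-event exclusion rule is implemented faithfully but is nearly
  inert under the generator's refractory; its exclusion fraction is
  reported so real-data users can monitor it.
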