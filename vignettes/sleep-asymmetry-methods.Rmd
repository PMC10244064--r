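---
title: "Lateralization of sleep EEG markers: models, detectors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lateralization of sleep EEG markers: models, detectors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sleeplat)
```

## The scientific question

A lateralized epileptic focus does not only generate interictal epileptiform
discharges (IEDs); it also perturbs the expression of physiological sleep
activity in its hemisphere. This package quantifies that perturbation on
scalp sleep EEG through nine features measured separately in each
hemisphere — delta-band (0.5–4 Hz) spectral power as a slow-oscillation
proxy; the density, amplitude, duration and slope of discrete sleep slow
waves; and the density, amplitude, duration and slow-oscillation locking of
sleep spindles — and reduces each to a per-patient lateralization index

$$LI = \frac{X_{left} - X_{right}}{X_{left} + X_{right}},$$

bounded in $[-1, 1]$ for non-negative magnitudes. Group statistics compare
the LI between patients with left and right focal epilepsy; a decision-tree
classifier with repeated stratified 5-fold cross-validation asks whether the
same asymmetries lateralize the focus patient by patient, against a
label-shuffle null.

## Signal chain

**Montage.** Analyses run on a 24-pair extended longitudinal bipolar montage
with inferior temporal electrodes (12 lateralized pairs per hemisphere, no
midline pairs); each trace is anode minus cathode. Slow waves are detected on
F3-C3, F7-T7 (left) and F4-C4, F8-T8 (right); spindles on C3-FT9 and
C4-FT10. A slow-wave candidate must also appear as a negative half-wave in
the average-referenced trace of its anode electrode; the average reference is
taken over all scalp electrodes present (configurable), since no single
standard set exists.

**Stages.** The hypnogram is an input (CSV of stage, onset, duration;
arbitrary epoch grid, half-open intervals in seconds from recording start).
Delta power and slow waves use N2+N3; spindles use N2 only. Segments with
less than 20 minutes per stage are flagged rather than rejected, so that the
cohort-level inclusion rule stays enforceable where it belongs while short
test fixtures still run.

**Delta power.** Welch periodograms with 4 s Hamming windows and 50 %
overlap, windows never spanning a gap between scored segments; band power is
the integral of the one-sided density over 0.5–4 Hz. The per-hemisphere
aggregate is the arithmetic mean over that side's lateralized bipolar
traces. Whether the source study computed N2 and N3 separately is unstated;
power here is computed jointly over both stages' segments.

**Slow waves.** Both traces are filtered 0.5–4 Hz with a 4th-order
Butterworth applied forward–backward (zero phase, so trough timing is
preserved). Negative half-waves between a positive-to-negative and the next
negative-to-positive zero crossing qualify if they last 0.25–1 s. Amplitude
is the absolute filtered minimum, duration the inter-crossing time, slope the
amplitude divided by the time from onset to trough. There is no amplitude
criterion by default — the defining criterion is duration — but a
configurable microvolt floor exists (`sw_amplitude_floor`), plus a relative
numerical floor ($10^{-9}$ of the trace maximum) that removes filter-ripple
pseudo-events on flat fixtures without breaking amplitude-scale
equivariance.

**Spindles.** An RMS amplitude-envelope detector in the Mölle family: the
trace is filtered 11–16 Hz; the root-mean-square envelope (0.2 s centered
window) must exceed the per-channel, per-night N2 mean plus 1.5 SD; runs
closer than 0.5 s merge; events must last 0.5–3 s. Because a moving-RMS
window smears a burst's supra-threshold run outwards — by an amount that
depends on where the threshold sits relative to the burst's envelope peak —
the run alone cannot express the duration criterion consistently across
SNR. Event boundaries therefore come from the run shrunk by a quarter
window per side, while the minimum-duration bound is checked against the
envelope's width around its peak at one third of the peak level, a
threshold-independent estimate of the burst's own extent. This is what
lets a 0.3 s burst be rejected at any SNR without costing recall on
genuine spindles near the minimum duration. The maximal trough is the
filtered minimum inside the event.
Spindle amplitude is the max-minus-min range of the 11–16 Hz filtered
±3 s epoch, restricted to the event's own extent (so epoch-edge filter
transients cannot contribute).

**Locking (ITC).** For each spindle the raw ±3 s epoch is filtered
0.5–4 Hz; the instantaneous Hilbert phase is read at the maximal trough
(cosine convention: 0 at a delta peak, ±π at a trough, −π/2 at a rising zero
crossing). Inter-trial coherence is

$$ITC = \frac{1}{N}\left|\sum_{k=1}^{N} e^{i\varphi_k}\right|,$$

the length of the mean unit phase vector. Amplitude never enters the
computation — the reason this measure is used instead of phase–amplitude
coupling, whose value would be confounded by the (itself asymmetric)
spindle amplitude.

## Statistics

Delta power LI is compared between groups with a two-sided Mann–Whitney test
(exact null when both groups have ≤ 12 patients and no ties, normal
approximation with tie correction otherwise). The four slow-wave features
and the four spindle features form two families: within each family one
Kruskal–Wallis test runs across the group-by-feature cells and Dunn's
rank-based contrasts compare left vs right focus within each feature, with
p-values multiplied by the number of contrasts in the family (capped at 1).
The probability of superiority,

$$ES = \frac{\#(x_L > x_R) + 0.5\,\#(x_L = x_R)}{n_L\, n_R},$$

accompanies every contrast; it equals the tie-corrected Mann–Whitney
$U/(n_1 n_2)$, which the tests exploit as a cross-check. Night stability is
a paired two-sided Wilcoxon signed-rank test of night 1 vs night 2, run per
feature within each group on the per-patient LI (whether the original
comparison used raw values or the LI is unstated; `value=` switches).
Undefined LIs (both hemispheres exactly zero) are excluded pairwise with a
count. All tests are two-sided at α = 0.05.

## Classification

A CART decision tree (Gini impurity, minimum split 2, minimum leaf 1, no
pruning, no depth cap — the default configuration, since none is stated)
consumes the nine sleep LIs of night 1 only; group statistics use pooled
nights. Each of `n_iter` iterations draws a fresh stratified 5-fold split
(stratification prevents single-class folds), trains one tree per fold and
predicts the held-out patients, so each patient is predicted exactly once
per iteration. Per-iteration accuracy, sensitivity, specificity, PPV and NPV
come from the iteration's pooled confusion matrix — this choice (rather than
averaging fold-level ratios) makes the contingency identities hold exactly;
`metric_agg = "fold"` restores fold averaging. The label-shuffle null
permutes labels anew at every iteration with class counts preserved. Runs
are compared by one-way ANOVA on per-iteration accuracies with
Sidak-adjusted pairwise contrasts (plain unpaired t-test for two runs), and
the pooled contingency table is tested with two-sided Fisher's exact.

Predictor importance follows the classical CART estimator: per tree, the
split improvement is summed per feature over branch nodes and divided by the
number of branch nodes; the per-tree values are averaged over folds and
iterations and min-max rescaled to [0, 1]. For the "difficult-to-lateralize"
analysis, patients whose |LI(IED)| lies strictly below the cohort median
absolute value are selected and the repeated cross-validation is rerun on
that subset alone — training and testing on the low-asymmetry patients is
the reading we adopt of "importance restricted to the classification of
those patients" — and per-iteration importances are compared across features
with Kruskal–Wallis plus Dunn contrasts against the IED feature.

One master seed spawns per-iteration seeds, so identical seed and matrix
reproduce a run bit for bit.

## The synthetic cohort generator

No patient recordings are distributable, so every stage is validated on
synthetic nights with exact ground truth. Per electrode the background is
$1/f^\beta$ Gaussian noise (β = 1, SD 10 µV at 256 Hz — chosen once as a
realistic scalp NREM background that keeps in-band noise well below the
injected graphoelements). Asymmetries are parameterized so the ground-truth
LI is exact by construction: a base value $B$ and target index $\ell$ give
left $B(1+\ell)$ and right $B(1-\ell)$.

* **Delta power**: the 0.5–4 Hz amplitudes of the background are scaled by
  $\sqrt{1 \pm \ell}$ (power gain $1 \pm \ell$) before the overall
  normalization, so the in-band/out-of-band ratio carries the asymmetry.
* **Slow waves**: negative half-sines (5/min per detection channel,
  amplitude scale 100 µV jittered ±10 %, duration uniform 0.35–0.8 s)
  injected at the anodes of the detection pairs with a 25 % spread to the
  cathode. Slope carries no parameter of its own; it is implied by
  amplitude and duration (amplitude over half-duration), exactly as the
  measured slope is.
* **Spindles**: 13 Hz bursts with a Gaussian waxing–waning envelope
  (σ = duration/5), 1.5/min during N2 (the reported density scale),
  peak 30 µV, duration 0.8–1.6 s. The central trough is additionally
  deepened by a fixed 6 µV, one carrier cycle wide. Both choices serve
  trough identifiability: with a flat-topped (raised-cosine) envelope the
  deepest trough is ambiguous under noise and the detector jitters by whole
  carrier cycles, collapsing the measured phase locking; and because the
  jitter probability would otherwise depend on the burst's amplitude, an
  amplitude asymmetry would leak into the measured locking asymmetry
  (higher-amplitude spindles get more faithful phase estimates). A fixed
  absolute deepening makes trough identification near-certain on both
  hemispheres regardless of the programmed amplitude asymmetry.
* **Coupling**: each spindle trough is placed where the channel's delta
  phase matches a von Mises(π, κ) draw; κ is solved from the target ITC via
  the mean resultant length $A(\kappa) = I_1(\kappa)/I_0(\kappa)$.
* **IEDs**: 70 ms biphasic transients at the temporal electrodes at a
  per-hemisphere rate. Their only role is rate asymmetry for the
  classifier; counts, not detections, feed the IED feature (IED detection
  is an input to the analysis, not part of it).

Events never overlap within a channel (up to 100 placement redraws). Same
seed, same signals, bit for bit; mirroring a patient specification swaps all
left/right parameters and exactly negates every ground-truth LI.

The default cohort profile mirrors the reported effect directions: higher
delta power (+0.05), slow-wave amplitude (+0.04, hence slope) and spindle
amplitude (+0.04) on the epileptic side; lower spindle density (−0.07, the
value implied by the reported per-hemisphere density medians 1.40 vs
1.61/min); strongly ipsilateral IEDs (+0.30); per-feature spread 0.12
(0.35 for IEDs), which places the programmed group separations at
probability-of-superiority effect sizes of roughly 0.6–0.8.

**What the generator does not emulate**: realistic sleep-cycle
architecture, REM, artifacts, K-complex morphology, topographic spindle
gradients, or volume-conduction mixing beyond the anode–cathode spread.
Passing recovery tests therefore demonstrates the correctness of the
measurement chain under known ground truth, not detector performance on
clinical recordings.

## Validation design and problem sizes

Recovery studies fix their conditions in advance:

* **Detector count recovery** uses 20 seeds of short nights (10 min N2,
  6 min N3, reduced six-pair montage) at SNR ≥ 4 (slow waves 100 µV vs
  10 µV background; spindle bursts raised to 40 µV), with the slow-wave
  amplitude floor at 35 µV. The floor is what makes count recovery
  meaningful at all: a duration-only criterion also counts background delta
  half-waves — on any background, synthetic or real — and those are
  symmetric, plentiful (tens per minute) and scale-free. Background
  half-waves stay below ≈ 27 µV under these conditions while injected
  events filter to ≥ 40 µV, so the floor separates the populations cleanly.
* **LI recovery** uses 34 patients per group, every patient carrying
  exactly the programmed group-median asymmetry (zero draw spread), two
  pooled 24-minute nights (14 min N2, 7 min N3 each), reduced montage,
  base locking 0.8. Zero spread isolates pipeline bias from cohort
  sampling noise; pooling two nights halves the variance of the noisiest
  estimator (the locking LI, a ratio of two ITC estimates from a few
  dozen phases each); the higher base coupling keeps that ratio out of
  its small-denominator regime. Group medians recover within ±0.04 for
  all nine features.
* **Classifier checks** run at 500 iterations on truth-derived feature
  matrices (no signal synthesis), which is what
  `make_feature_matrix_from_truth()` exists for.

These sizes were chosen as the smallest designs whose estimator precision
comfortably supports the stated tolerances.

## Numerical choices and degenerate inputs

* Butterworth order 4, forward–backward (`signal::filtfilt`); the filter
  family is stated in the source, order and phase handling are not.
* Hilbert transform via the standard FFT analytic-signal construction.
* ITC of an empty phase set, an LI with both sides zero, and feature
  summaries of an empty event list are `NA` markers, never silent zeros.
* Events must lie entirely within scored segments; epochs truncated below
  1 s are excluded from phase sets with a logged count.
* EDF I/O is a minimal 16-bit implementation (1 s records, fixed
  ±3276.8 µV physical range, 0.1 µV resolution); channel labels are
  normalized case-insensitively with the old T3/T4/T5/T6 names aliased to
  T7/T8/P7/P8.
* Ties in Dunn's test use the standard rank tie correction; adjusted
  p-values are Bonferroni-style within family, matching the convention of
  the commercial package named by the source study.

## Known limitations

* The identity and parameters of the published spindle detector used on the
  real cohort are not recoverable from the available text; the RMS-threshold
  detector implemented here reproduces the reported density scale but is not
  a re-implementation of that specific tool. All its parameters are exposed
  in `spindle_params()`.
* The measured locking LI is the ratio of two noisy ITC estimates; with
  realistic spindle counts per night its per-patient spread is large, which
  is why cohort-level claims about locking need either many events or many
  patients.
* The headline accuracies of the real cohort (65 % sleep-only, 75 % IED,
  77 % combined) depend on the clinical recordings and are not reproduced
  here; the package's claims are calibration of the shuffle null, exactness
  of the statistics against enumeration oracles, ground-truth recovery, and
  the direction and significance of the synthetic end-to-end
  discrimination.
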