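---
title: "Computerized CTG analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computerized CTG analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctgsuite)
```

Cardiotocography (CTG) records the fetal heart rate (FHR, beats per
minute) together with uterine activity (UC). Visual interpretation of CTG
traces is notoriously subjective, and the traces that cause the most
disagreement are the *suspicious* ones — neither clearly normal nor
clearly pathological. `ctgsuite` implements a complete computerized
analysis chain for antepartum CTG: quality screening, morphological and
time/frequency feature extraction, a rule-based annotation of suspicious
traces, and an SVM classifier evaluated with a full confusion-matrix
metric suite. Because clinical CTG archives are rarely shareable, the
package also contains a first-class synthetic generator that produces
records with known ground truth; all validation in the test suite runs on
synthetic data.

This vignette explains the models and the decisions behind them: what each
stage computes, which parameters matter, and where the design was
genuinely open.

## Record model and quality screening

A `ctg_record` holds an evenly sampled FHR trace (default 4 Hz, i.e. a
0.25 s step, which is also the resampling step of the spectral stage),
an optional UC trace, and per-sample masks. Missing samples use the
sentinel value 0, the common convention of CTG monitor exports. A sample
is invalid when it is missing, outside the physiological 50--240 bpm
range, or an artifact spike. Spike rejection is a sequential scan: an
in-range sample deviating more than 25 bpm from the last accepted sample
is rejected unless the next sample stays with it — two consecutive
deviating samples indicate a genuine level change (the onset of an
event), one alone is an artifact. The 25 bpm bound is deliberately far
above any physiological sample-to-sample change at 4 Hz.

`assess_quality()` reports duration, signal loss (missing samples) and
outliers (rejected measured samples) and checks the eligibility rules
used for antepartum CTG studies: antepartum recording in gestational
weeks 36--40, duration above 20 min, signal loss below 30%, outliers
below 5%, singleton pregnancy. Eligibility is a *predicate*, never a
gate: ineligible records load and analyze normally and simply carry
`eligible = FALSE`, so a user can always inspect why a trace failed.

`interpolate_gaps()` fills invalid runs by linear interpolation between
the flanking valid samples (nearest-value extension at the record edges).
Linearity is the most conservative choice for gap filling: it invents no
extrema, so interpolated stretches can never create spurious events.
Gaps longer than 15 s are additionally flagged as *long interpolation*;
this flag drives event invalidation downstream. The operation is
idempotent and never leaves the convex hull of the flanking samples.

## Baseline and floating line

Two trend lines with different jobs:

* The **baseline** is the slowly varying FHR level *excluding*
  accelerations and decelerations. It is an iterative trimmed running
  median: a 10-min running median, after which samples more than 15 bpm
  away from the estimate (event samples) are replaced by it and the
  median recomputed, three times. Three iterations are enough for the
  estimate to stop moving on trapezoidal events; the 15 bpm trim equals
  the FIGO event amplitude so that everything an event could contribute
  is excluded.
* The **floating line** is a plain 2-min running median. It follows the
  signal through sustained level changes but not through FIGO-duration
  (15--60 s) events, and subtracting it yields the FHR variability
  (FHRV) signal.

One consequence is worth stating explicitly: a running median of window
$w$ cannot respond to an excursion shorter than $w/2$. The 10-min
baseline therefore cannot represent a 3--5-min bradycardia at all, which
is why the arrhythmia scan below runs on the floating line. The floating
line's 2-min window in turn is why 15--60 s accelerations do *not*
contaminate it.

## Event detection

`detect_accel_decel()` scans the deviation of the FHR from the baseline
for FIGO-style events: accelerations are excursions of at least +15 bpm
lasting at least 15 s (and under 10 min — anything longer is a baseline
change), decelerations mirror this below the baseline, and a deceleration
longer than 3 min is flagged *prolonged*. The threshold scan runs on the
deviation smoothed with a 5-s centered moving average: FIGO events are
macroscopic excursions, and without smoothing the beat-to-beat
variability chops a genuine event into sub-threshold-duration fragments.
Peak amplitudes are still read off the raw deviation. The reported
episode duration is the time the (smoothed) deviation stays beyond the
threshold — for a trapezoidal event this is shorter than the full ramp-to-
ramp extent, which is the convention a threshold definition implies.

An episode that overlaps a long interpolated gap is retained in the
episode table but marked `figo_valid = FALSE` and excluded from feature
counts: a 15-s-scale event supported by a 15-s-scale reconstruction is
not evidence.

`detect_arrhythmia()` applies the run definitions: tachycardia is a rise
of the trend above 160 bpm for at least 10 min (severe when the run mean
exceeds 180 bpm), bradycardia a decline below 110 bpm for more than
3 min. The comparisons are strict (`>` / `<`, a plateau exactly at
160 bpm never qualifies) and the duration bounds mirror the wording "at
least" (inclusive) versus "more than" (exclusive). The function accepts
any trend vector plus an optional validity mask whose `FALSE` samples
terminate runs; the pipeline calls it on the floating line, for the
window-arithmetic reason above. At the 3--10-min scale of these episodes
a single interpolated dropout should not break a diagnosis, so runs are
not split at gaps; instead an episode in which more than half of the
samples are long-interpolated is discarded as unsupported by measured
data.

## Short-term variability

The FHRV signal is `FHR - floating line`. The STV index of a 30-s window
with samples $F(i)$ and mean $\bar F$ is

$$ STV = \sqrt{\frac{1}{n-1} \sum_{i=1}^{n} (F(i) - \bar F)^2 }, $$

the sample standard deviation over the window ($n = 120$ samples at
4 Hz). Windows tile the record without overlap by default (a hop
argument provides overlapping windows); the trailing partial window is
discarded. A window is *good* when fewer than half of its samples are
interpolated and none are long-interpolated; the summary `stv_mean`
averages good windows only. STV below 0.02 bpm is carried as the
`stv_absent` alarm flag (absence of variability), distinct from the
annotation cutoff below. Non-overlapping tiling was chosen so that the
per-window values are independent; with overlap the mean changes little
but its variance estimate would be misleading.

## Spectral analysis

The mean power spectral density of the FHRV signal is a short-time
Fourier transform average: frames of 32 s, Hanning-windowed, zero-padded
to 1024 points, with the per-frame PSD
$P_i(\omega) = |FT(\omega)|^2 / (L\,U\,f_s)$ and window normalization
$U = \frac{1}{L}\sum_n w(n)^2$, averaged over frames. Three choices the
frame equations leave open:

* **Scaling.** The one-sided spectrum doubles all non-DC, non-Nyquist
  bins and divides by $f_s$, so the frequency integral of the PSD equals
  the signal variance (Parseval). This makes band powers physical
  (bpm²) instead of grid-dependent.
* **Frame overlap.** 50% (the Welch convention); configurable to 0 for
  strictly independent frames.
* **Detrending.** Frames are mean-subtracted before windowing. The FHRV
  is already detrended globally, but residual frame offsets otherwise
  leak into the VLF band.

Band powers integrate the PSD over VLF 0--0.05 Hz, LF 0.05--0.2 Hz and
HF 0.2--1 Hz by the trapezoidal rule on the piecewise-linear interpolant
with *exact* band edges (a bin-membership rule would make the analytic
flat-PSD integrals grid-dependent). Total power is the band sum, and the
sympatho-vagal balance (SVB) is the LF/HF ratio — high values indicate
sympathetic dominance (reactivity), low values vagal dominance. A zero
HF power yields `NA` ("undefined"), never infinity. Signals not sampled
at 4 Hz are cubic-spline interpolated to the 0.25 s step first. Units of
the band powers are bpm²; only the dimensionless SVB feeds the
annotation rules, so the unit convention cannot affect labels.

## Rule-based annotation

The feature row of a trace (counts of bradycardia, tachycardia,
FIGO-valid accelerations and decelerations, STV, SVB and the alarm
flags) is condensed into an ordered six-bit alarm mask
(BRAD, TACH, ACC, DEC, STV, SVB): episode presence for BRAD/TACH,
*absence* of accelerations for ACC, prolonged decelerations for DEC, and
strict-below cutoffs STV < 1.70 and SVB < 8.20 — the minima these
indexes take across gestational weeks 24--42 in normal pregnancies. An
undefined SVB sets the SVB bit (non-reactivity). A trace is labeled
**suspicious** when any of four criteria fires:

1. no accelerations and at least one further alarm bit;
2. accelerations present and at least two alarm bits;
3. severe tachycardia (> 180 bpm);
4. bradycardia.

Criterion 1 contains a subtlety: with no accelerations the ACC bit is
itself 1, which would make "at least one bit" vacuous. The implementation
requires a bit *other than* ACC, which is the only reading under which
the published worked example (mask `0,0,1,0,0,1`, suspicious via the SVB
bit) is informative; a configuration flag restores the literal reading.
Whether the SVB comparison should be strict or not cannot be decided
from the worked examples (8.88 and 1.71 are both far from 8.20); strict
`<` was chosen to match the STV bit and is configurable. The labeling
pass is repeated once for verification; since the rules are pure, a
disagreement would indicate memory corruption and raises an error.

## Classification and metrics

The classifier consumes six features per trace — BRAD, TACH, ACC, DEC,
STV, SVB — and predicts normal versus suspicious with a soft-margin SVM
(linear, second-order polynomial, or RBF kernel). Evaluation is k-fold
cross-validation (default 10 folds): stratified fold assignment under a
fixed seed, z-scoring fit on the training folds only, every sample
predicted exactly once. Hyperparameters are declared, not tuned:
C = 1, RBF scale 1/(number of features) on standardized inputs,
polynomial degree fixed at 2. Both the pooled confusion matrix over all
held-out predictions and per-fold accuracies are reported; pooled is the
default basis of the metric report because a printed confusion matrix is
only reproducible as a pooled object.

The metric suite takes the positive class to be *normal* (so sensitivity
is the ability to recognize normal traces, specificity the ability to
recognize suspicious ones) and computes accuracy, misclassification
error, sensitivity, specificity, precision, $F_\beta$ (default
$\beta = 1$) and the G-mean
$\sqrt{\text{sensitivity} \times \text{specificity}}$, per class (each
class in turn positive) and aggregated as the arithmetic mean and the
class-size-weighted mean. Zero denominators produce `NA` markers.

## The synthetic generator

`generate_record()` builds an FHR trace as

> baseline level + trapezoidal events + band-limited noise + LF and HF
> sinusoids,

with bell-shaped UC pulses, random gap segments (the missing sentinel)
and isolated outlier spikes. The components map one-to-one onto what the
pipeline measures: the noise (white Gaussian, low-pass filtered below
1 Hz — the physiological FHRV band — and rescaled to an exact target SD)
drives STV; the 0.1 Hz and 0.4 Hz sinusoids set the LF and HF band
powers and hence SVB; trapezoids with 5-s ramps give events a sharp,
unambiguous ground truth while remaining smooth enough for the trimmed
median baseline. Every record derives from one seed; cohort generation
draws one sub-seed per record, so any cohort member can be regenerated
alone.

`generate_cohort()` emulates a two-class antepartum study. Normal records
are reactive: 2--6 FIGO-valid accelerations (amplitude 21--28 bpm,
duration 28--50 s — chosen so the above-threshold time exceeds the FIGO
15-s minimum by geometry), noise SD 0.7--1.1 bpm, LF amplitude
3.4--5.0 bpm against an HF amplitude of 0.25--0.5 bpm (measured SVB
above the 8.20 cutoff, with the lower tail approaching it), signal loss
2--12% and up to 1% outliers. Suspicious records violate one uniformly
sampled rule: vagal-dominant balance without accelerations (LF
2.2--3.2 bpm vs HF 0.7--0.95 bpm, measured SVB below but *near* the
8.20 cutoff), low variability (noise SD 0.4--0.8 bpm with small
oscillations, STV clearly under 1.70 but not degenerate), severe
tachycardia (level 183--192 bpm for 10.5--12.5 min), or bradycardia
(98--106 bpm for 3.7--5.5 min). The near-cutoff placement of the
spectral-balance and variability modes and the realistic signal-loss
levels are deliberate: computerized CTG studies report accuracies
around the low 90s, not 100%, because the classes genuinely border each
other in feature space. The parameter families were set so the synthetic
task sits in that regime — event counts carry measurement noise, and the
STV/SVB distributions of the two classes are adjacent rather than
separated by an empty margin.

What the generator does **not** emulate: sinusoidal pathological
patterns, deceleration morphology subtypes (early/late/variable),
contraction-coupled decelerations, gestational-age trends in the
indexes, and monitor-specific autocorrelation artifacts. Passing tests
on this generator therefore demonstrate that the pipeline recovers the
constructs it defines — not that it would classify real pathological
traces correctly.

## The scaled end-to-end experiment

`run_balance_experiment()` reproduces, at study scale, the comparison
between a balanced design (30 normal / 20 suspicious) and an imbalanced
one (40/10): cohort generation, feature extraction, annotation
consistency against the generating intent, and 10-fold RBF-SVM
cross-validation. Because single 50-record cohorts make the G-mean a
coarse statistic (one suspicious error in the imbalanced design costs
10 points of specificity), the experiment generates three cohort pairs
from derived seeds and compares mean G-means — a replicated version of
the same comparison. Record duration is 30 min and cohort size 50, the
scale the annotation rules were designed for; the full experiment (300
records) runs in a few minutes on one CPU. The imbalance penalty emerges
mechanically: with 10 suspicious records spread over four violation
modes, a training fold often sees a mode once or not at all, and the
minority-class boundary degrades — which is precisely the argument for
balanced designs.

## Known limitations

* The baseline estimator assumes events are minority occupants of its
  10-min window; back-to-back accelerations covering most of a window
  would bias it upward.
* STV here is the evenly-sampled-series branch of the index; true
  beat-to-beat (RR-interval) STV variants are out of scope.
* The annotation thresholds (1.70, 8.20) are fixed; in reality both
  indexes vary with gestational age, and week-dependent cutoffs would be
  the natural extension.
* The classifier is deliberately plain (no class weighting, no
  hyperparameter search); it measures what the features support, not the
  best achievable performance.
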