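---
title: "Artifact-robust HRV and cohort analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Artifact-robust HRV and cohort analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hrvcohort)
library(dplyr)
```

## The problem

Heart rate variability (HRV) — the beat-to-beat variation of heart rhythm —
is a noninvasive window on autonomic nervous system function, used from
cardiac risk stratification down to experimental noninvasive glucose
monitoring. Its time-domain statistics are only meaningful when computed on
*NN intervals*: the times between consecutive *normal* (sinus) beats.
Ambulatory (Holter) recordings are contaminated by ectopic beats —
ventricular (V), supraventricular (S), atrial (A), fusion (F) and
unclassifiable/paced (Q) complexes — and by electrode artifacts, both of
which inject spurious variance that can dwarf the physiological signal.
HRV also depends strongly on age and gender, so any diagnostic threshold
needs age- and gender-specific reference ranges, for diseased as well as
healthy hearts.

hrvcohort implements the full chain: beat-annotation ingestion, NN-interval
cleaning, windowed time-domain and Poincaré HRV under two
segment-aggregation conventions, cohort-level dependency modelling, quartile
normal-range estimation with a rank-based evaluation scheme, and a seeded
synthetic cohort generator that makes every stage testable end to end
without clinical data.

## NN-interval cleaning

Cleaning starts from a beat-annotation stream (time in ms + AAMI-style
label, with an extra `X` pseudo-label marking the edges of detected artifact
spans). The RR series carries both endpoint labels per interval, and an
interval is an NN candidate only when both endpoints are `N`.

Within a candidate run, each interval must stay inside a relative-change
band around the previously accepted interval:

$$\mathrm{prev}\,(1 - a) < \mathrm{cur} < \mathrm{prev}\,(1 + a),
  \qquad a = 0.15$$

with strict inequalities. The published form of this rule is printed as
$NN(n-1)\,T < NN < NN(n-1)\,(2-T)$; taken literally with $T = 0.15$ that
band would be $[0.15, 1.85] \times \mathrm{prev}$, which contradicts the
accompanying description of eliminating intervals that *change by more than
15%*. We therefore parameterise by the allowable change $a$ (equivalently,
$T = 1 - a$) and default to $a = 0.15$; any other reading is reproducible
by setting `allowable_change`.

Two further rules the published description leaves open, fixed here and
verified against a brute-force validator:

* **Restart after a violation.** The offending interval is discarded
  entirely, and the next interval unconditionally seeds a new run (it has no
  accepted predecessor to compare against). This is the least-biased
  reading; the alternative (letting the violator seed the next run) would
  re-admit exactly the jumps the rule exists to remove.
* **Minimum run length counts intervals.** Runs shorter than `min_run = 6`
  NN *intervals* are dropped. The published "value of 6 breaks" could also
  mean beats; intervals were chosen because every HRV formula operates on
  intervals.

Recordings with diagnosed atrial fibrillation are excluded outright, as are
recordings with a sinus pause/arrest — any RR interval of at least
`pause_ms = 3000` ms (a conventional clinical cut-off; the source material
names no number). Intervals bounded by an `X` marker are not pause
candidates: that gap is a detected artifact, which segment cleaning already
excises, not asystole.

## HRV parameters

All statistics use the sample ($n-1$) standard deviation; the dominant
convention in the HRV literature (the definitions in the source material do
not state a divisor, and the independent test oracle uses the same
convention).

* **SDNN** — sample SD of all NN intervals (ms).
* **SDANN / ASDNN** — the window is partitioned into contiguous 5-minute
  bins by interval onset; SDANN is the SD of per-bin mean NN, ASDNN the mean
  of per-bin SDs. Bins with fewer than 2 intervals are skipped, and at least
  2 qualifying bins are required.
* **RMSSD** — root mean square of successive differences.
* **NN50 / pNN50** — count and percentage of successive differences
  strictly greater than 50 ms ("more than 50 ms").
* **SD1 / SD2** — Poincaré ellipse axes via the standard identities
  $SD1 = RMSSD/\sqrt2$ and $SD2^2 = 2\,SDNN^2 - SD1^2$ (floored at 0); the
  parameters are named but not defined in the source material.

### Average vs Combined aggregation

Cleaning yields several disjoint NN segments per window. Two conventions
turn them into one number per parameter:

* **Average (A)**: compute each parameter per segment and take the
  unweighted mean (so A-method NN50 is a real-valued mean count). Weighting
  by segment length is a defensible alternative; unweighted was chosen as
  the plain reading of "the average of HRV calculated on these sequences"
  and is what the equality tests pin down.
* **Combined (C)**: compute once over the concatenation of all segments.
  Successive-difference statistics (RMSSD, NN50, pNN50, SD1) never take a
  difference across a segment junction — the junction jump is precisely what
  cleaning removed, and re-admitting it would leak artifact variance back
  into the short-term statistics.

SDANN/ASDNN are always computed on the window's 5-minute partition of all
accepted intervals (segments may be shorter than a bin, so a per-segment
5-minute statistic would be ill-posed); consequently they coincide between
the two methods.

With a single segment A and C agree exactly — a tested invariant. With
several level-shifted segments C_SDNN exceeds A_SDNN (between-segment
variance enters the concatenation), reproducing the known direction of the
difference between the methods.

### Sliding windows

Windows of length $w$ minutes slide by $s$ minutes: $[ks, ks + w]$ for
$k = 0, 1, \dots$ while the window fits, giving
$\lfloor (\mathrm{span} - w)/s \rfloor + 1$ windows. Study durations are 30
min (short), 2 h and 8 h (medium) and 24 h (long), with $s = 5$ min for
short/medium and $s = 10$ min for long. Window membership is by interval
onset, half-open $[start, start + w)$, so adjacent windows never double-count
an interval. The nominal record span is the observed span rounded up to a
whole minute: Holter records have nominal durations, and the final beat
falls a fraction of a beat short of them.

## Cohort statistics

Correlation and two-group machinery delegates to the standard R
implementations behind a tidy surface: Pearson via `cor.test`, Welch's
t-test (the two-group "t-test", with unequal variances since none of the
compared groups have any variance guarantee), Mann–Whitney U with normal
approximation plus tie and continuity corrections, and the two-sample
Kolmogorov–Smirnov statistic. Two deliberate deviations:

* **Spearman's p-value** is the t-transform of Pearson-on-midranks — the
  package defines Spearman *as* Pearson on mid-ranks, p-value included,
  rather than the AS 89 approximation `cor.test` would use. This keeps the
  implementation exactly equal to its textbook oracle.
* **The KS p-value** is the asymptotic Kolmogorov survival function
  $Q(\lambda) = 2\sum_{k\ge1}(-1)^{k-1}e^{-2k^2\lambda^2}$ summed to machine
  precision in package code; `ks.test`'s internal evaluation truncates at
  about $10^{-6}$, too coarse for the package's equivalence tests.

Gender is coded M = 0, F = 1 everywhere, so a negative point-biserial
coefficient means lower values in females. Age groups are half-open:
$(0,30), [30,40), \dots, [60,70), [70,130)$ — a 70-year-old is in the
oldest group (the boundary convention is not derivable from the published
group labels; this one is fixed and documented).

Before cohort-level correlation each subject is reduced to the mean of its
window-level values per parameter. Thousands of overlapping windows per
subject would otherwise pseudo-replicate every subject, deflating p-values;
per-window correlation remains available by correlating the window table
directly. No multiple-testing correction is applied; raw p-values are
reported with n.

Age dependency is modelled as ordinary least squares $y = b_0 + b_1 x$
(HRV parameter in ms against age in years) via `fit_dependency()`, with
broom-style `tidy()`/`glance()` accessors. Reference lines used throughout
the tests and the generator: healthy A_SDNN $60.62 - 0.49x$ and A_RMSSD
$42.19 - 0.32x$; arrhythmia A_SDNN $44.30 - 0.13x$ and A_RMSSD
$37.71 - 0.046x$.

## Quartile normal ranges and rank-based evaluation

Normal ranges are estimated per age-group × gender cell as Q1/Q2/Q3 by the
**median-of-halves** rule: Q2 is the median; Q1 and Q3 are the medians of
the lower and upper halves with the overall median excluded from both
halves when n is odd. Numeric libraries default to interpolation
definitions (e.g. `quantile()` type 7) that differ on small groups, so the
rule is implemented explicitly. With inputs restricted to 12 discrete
(age-group, gender) combinations, per-group quantile estimation is the
deterministic limit of any regression model trained on those inputs, so the
lookup *is* the predictor; a pluggable learner hook in the classification
harness keeps the pipeline contract open for model-based alternatives.

A predicted range is scored against a measured value in the 4-bin universe
cut by the *reference* quartiles: bins $(-\infty,q_1], (q_1,q_2],
(q_2,q_3], (q_3,\infty)$, right-closed (the boundary convention is this
package's choice; the published description fixes none). Per sample:
TP = 1 if the measured bin is among the predicted bins; FP = predicted but
not measured; FN = 1 if the measured bin was missed; TN = the rest — so
every sample contributes exactly 4 counts, and counts aggregate by
summation into TPR/FPR/PPV and F1 (harmonic mean of TPR and PPV, 0 by
convention when both are 0).

The ND/GD/BD glucose-regulation harness runs stratified k-fold (default 10)
cross-validation of a pluggable learner (default: random forest) on the
four HRV features the detector uses — A/C SDNN and RMSSD. Macro F1 is the
headline metric because the classes are heavily imbalanced; the pooled
confusion matrix is reported alongside per-fold metrics because
fold-averaged metrics and pooled counts answer subtly different questions
and do not reconcile exactly. Multiclass AUC is macro one-vs-rest on the
out-of-fold score matrix.

## The synthetic cohort generator

The generator exists so every pipeline stage can be validated against known
ground truth. Its core is deliberately minimal: RR intervals are a
stationary Gaussian AR(1) process with mean `mean_rr_ms` (800 ms), marginal
SD equal to the subject's SDNN target, and lag-1 autocorrelation

$$\rho = 1 - \frac{RMSSD^2}{2\,SDNN^2},$$

the moment-matching identity that makes the series hit both targets
simultaneously (valid iff $RMSSD < 2\,SDNN$; invalid perturbations are
resampled). Subject targets come from the condition-specific dependency
lines above — arrhythmia subjects and bad-glucose-regulation (BD) subjects
use the shallow-slope arrhythmia lines, ND/GD subjects the healthy lines —
plus a −2 ms SDNN offset for females and a 5 ms between-subject Gaussian
spread, floored at 3 ms. Intervals are truncated to [300, 2000] ms; at
study-relevant SDNN (< 60 ms around an 800 ms mean) the truncation bias is
negligible.

Ectopic beats are injected per-beat with probability `ectopic_rate`
(default 0.01), relabelled V or S, with a premature-beat timing signature:
the preceding interval shrinks by 30% and the following interval grows so
the two-interval sum is conserved. Artifact spans arrive as a Poisson
process (`artifact_rate` = 0.5/h, uniform 5–30 s lengths); beats inside a
span are removed and `X` markers fence it.

Defaults were fixed once as study conditions: ages 20–80 (the span of the
study cohorts), 15% arrhythmia (the arrhythmia share of the 284-subject
study composition), ND/GD/BD = 0.53/0.18/0.29 (the class proportions of the
pooled classification counts), 2-hour records. The gender offset direction
is a documented synthetic-world convention, not a physiological magnitude
claim; likewise the BD-class target modulation encodes the observed
BD/arrhythmia distributional similarity as ground truth so that detection
power is testable.

**What the generator does not emulate:** respiratory sinus arrhythmia,
circadian rhythm, nonstationarity within a record, non-Gaussian RR
marginals, and structured (e.g. bigeminy) ectopy. Passing tests therefore
demonstrate correctness of the *pipeline arithmetic and its contracts* on a
process with known moments — not clinical validity on real ECG.

A known, accepted consequence of the AR(1) choice: the sample SD of a
short autocorrelated segment underestimates the marginal SD by roughly
$\rho/((1-\rho)\,n)$ relative terms, so the A-method slope recovered from
heavily fragmented records attenuates a few percent toward zero. The
recovery tests quantify this (slope within 3 standard errors of the planted
−0.49 at 200 subjects) rather than hiding it.

## Problem sizes used in validation

The validation suite and the acceptance script run at desk scale, chosen as
the package's own study conditions: oracle equivalence on 1,000 random NN
series (n ≤ 50) and 500 random labeled sequences (n ≤ 200); moment recovery
on ~10⁵ generated intervals; dependency recovery on 200-subject cohorts
with 30-minute records and one 30-min/5-min window pass; the
healthy-vs-arrhythmia slope comparison on 100 replicated pairs of
40-subject cohorts; range evaluation on two independent balanced
240-subject cohorts; and the CV harness on a 300-subject mixed cohort.
30-minute records are used for the cohort experiments because the
short-term duration class is the one all four study datasets share.

## Known limitations

* The WFDB annotation reader covers the standard MIT binary format's beat
  codes and SKIP/NUM/SUB/CHN/AUX specials, mapping NOISE/ARFCT to `X`;
  exotic vendor extensions are out of scope (the CSV dialect is the
  package's canonical fixture format).
* The pause screen and AFIB exclusion act at recording level, as specified;
  no per-window re-screening is attempted.
* `hrv_average()`'s SDANN/ASDNN (and `hrv_combined()`'s) are bin-based over
  accepted intervals, not per-segment — the one place the two methods
  cannot differ by construction.
* The neural-network variant of the range predictor is intentionally
  represented by the per-group quantile lookup (its deterministic limit);
  the learner hook exists for experimentation, not parity claims.
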