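---
title: "Methods: facial action event analysis and heart rate in horses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: facial action event analysis and heart rate in horses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(equifacs)
```

## The problem

EquiFACS codes horse facial behaviour as timed events: each activation of
an action unit (AU), action descriptor (AD) or ear action descriptor
(EAD) is annotated with an onset and an offset. A study of management
stressors (road transportation, social isolation) yields, per horse, a
handful of 30-second clips per condition, each with dozens of such
events, plus a continuous R-R interval recording from a girth-mounted
heart-rate monitor. The analytic questions are: which facial actions
increase under the interventions, are the changes statistically
supported at the horse level, and do the selected actions carry enough
signal to discriminate intervention from baseline clips?

This vignette documents the models, the tunable parameters, the
numerical choices, and what the synthetic data generator does and does
not emulate.

## Event representation

Events live on a session-relative time axis in seconds, with
closed-open intervals `[onset, offset)`, so abutting events never
double-count at their shared boundary. Zero-duration events are legal:
near-instant actions count for frequency and contribute zero duration.
Clip-relative times are obtained by subtracting the clip's
`clip_start`; all analyses below only use within-clip onset differences
or per-clip counts, so the origin convention never affects results.

The unscorable-footage marker `VC74` is handled conservatively by
`drop_unscorable()`: a coded event fully contained in an unscorable
span cannot be trusted and is removed; an event that merely overlaps
one is kept untrimmed, because its coded duration is the annotator's
judgement of the full activation. We deliberately do not rescale
frequency denominators by visible time: the fraction of unscorable
footage in usable clips is small, and rescaling would silently change
the meaning of "occurrences per clip".

## The "ear flicker" movement index

*Ears forward* (EAD101) and *ear rotator* (EAD104) occurring within one
second constitute a single composite movement, the "ear flicker". The
index must consume its constituents, otherwise the same ear movement is
counted three times (EAD101, EAD104, flicker). `build_ear_flicker()`
measures proximity onset-to-onset — onsets are the most reliably placed
timestamps in FACS coding, offsets being a judgement about return to
neutral — and pairs greedily: scanning ear events in onset order, each
unconsumed event takes the earliest subsequent opposite-code event
within the window, in either order (101 before 104 or vice versa), with
ties broken by input order. The pairing is deterministic, conserves
counts (`n(EAD101) + n(EAD104) = 2 n(flicker) + n(residual ear
events)`), and guarantees the residual contains no opposite-code pair
within the window. On randomized ear streams the greedy count equals
the exhaustive maximum matching in every case we test, so nothing is
lost relative to an optimal pairer; the test suite asserts this
equality. *Ear flattener* (EAD103) is not a constituent: the index is
defined for EAD101/EAD104 only.

## Frequency-threshold selection (HFI)

The HFI method pools occurrences over all intervention clips and all
control clips (after the ear-flicker merge, and excluding `VC74`).
A code is selected when

* its share of the intervention pool's occurrences is at least the
  threshold (default 5%), and
* its per-clip mean frequency is higher under intervention than under
  control.

The threshold comparison is inclusive (`>= 5%`): published tables report
shares at one decimal, where "more than 5%" and "at least 5%" are
indistinguishable, and the inclusive reading is the stable one under
rounding. The reported `freq_difference` is the relative increase of
per-clip mean frequencies, not of pooled counts, so unbalanced pool
sizes (e.g. 25 control vs 35 intervention clips) do not bias it; it is
`Inf` when the code never occurs in control.

Note that this selection rule has no error control: under a null in
which both pools follow the same law, any code whose share clears the
threshold is selected with probability close to one half (the
probability that one sample mean exceeds another). HFI is a
*descriptive screen* for frequent, elevated codes; hypothesis-level
guarantees come from the paired tests and the co-occurrence contrast
below, and the package's null-fidelity checks are therefore phrased
against the significance-tested selection.

## Co-occurrence graphs and their contrast

For one clip and one observation window size (OWS), `build_graph()`
builds a directed multigraph count: for every ordered pair of
occurrences `(a, b)` of *different* codes with `onset(b) - onset(a)` in
`(0, ows]`, the edge `code(a) -> code(b)` gains one count; exactly
simultaneous onsets count once in each direction. Windows are anchored
at event onsets rather than on a fixed grid, which avoids phase
artifacts and matches the idea that codes "occur within a predetermined
period of one another". Self-pairs are excluded so a rapidly repeated
single code cannot masquerade as co-occurrence. Edge weights are
non-decreasing in the window size, which the suite checks as a
monotonicity property.

The per-code statistic is the *degree rate*: incoming plus outgoing
edge counts divided by clip length in minutes (`code_profile()`).
Normalising by clip length makes mixed-length clips comparable; with
uniform 30-s clips it is a constant factor. `cooccur_contrast()`
averages degree rates per horse within each condition, forms per-horse
paired differences, and applies a paired t-test per code. A code is
*selected* when its mean difference is positive and *significant* when
additionally `p < 0.05`. Pairing at the horse level (not the clip
level) is essential: clips from one horse are not independent. Per-OWS
p-values are reported raw, mirroring per-cell tables in this
literature; Holm adjustment across codes is available via
`p_adjust = "holm"`. The source method's exact node statistic is not
public; degree-rate with a sign-and-significance rule is this package's
operationalization, and cross-window selection patterns should be read
qualitatively.

## Per-clip summaries and paired tests

`summarize_clips()` reports, per clip and code, the occurrence count
and the maximum single-activation duration (maximum, not mean or total,
is the duration statistic of interest: a sustained activation is a
different signal from many short ones). `paired_tests()` averages per
horse and condition and applies the Wilcoxon signed-rank test to the
per-horse differences — consistent with the heart-rate analysis and
robust at 10–28 horses — with zero differences dropped, the exact null
distribution whenever fewer than 25 non-zero differences with untied
magnitudes remain, and the normal approximation otherwise. All-zero
differences give `p = 1`. A paired t-test is available behind
`method = "t"` for sensitivity. Significance bands are the conventional
0.05 / 0.01 / 0.001 stars.

## Inter-rater agreement

The Wexler ratio is `2 N_agree / (N1 + N2)`. Two events agree when they
are the same code in the same video and overlap in time; each event
matches at most once. Matching uses a two-pointer sweep per code in
onset order, which attains the maximum matching for interval overlap
and is symmetric in the two coders. "Any overlap" is the least
arbitrary criterion — the FACS literature does not fix an overlap
fraction — and a minimum overlap in seconds is available
(`min_overlap`). Zero-duration events match when their time point lies
inside the partner's closed interval. When neither coder coded
anything the ratio is vacuously 1.

## Heart rate

R-R series are cleaned by `filter_rr()`, a centred-median protection
zone rule: beat `i` (instantaneous rate `60000 / rr_i` bpm) is rejected
when it deviates from the median rate of the five-beat window centred
on it by more than `max(6 bpm, 0.15 x median)`. The commercial filter
used to export such files is proprietary; this re-specification keeps
its two documented ideas — a *protection zone* (a minimum deviation, 6
bpm, below which nothing is ever rejected) and a medium-strength
relative criterion (15%) — and all three parameters are exposed.
Medians are computed in a single pass over the unfiltered series, and a
rejection fraction above 25% raises a signal-quality warning.
Consequently, downstream comparisons against values produced by other
filters should be tolerance-based, not exact.

`window_mean()` implements the five-minute clip-anchored mean: the
window opens 135 s before the 30-s clip and closes 135 s after it
(width 300 s). The mean is time-weighted — beats in the window divided
by the elapsed time they span — not a mean of instantaneous rates,
matching "mean heart rate during five minutes"; for a constant R-R
series both coincide at `60000 / rr` regardless of placement. Windows
truncated by the recording edge are accepted while beat coverage is at
least 50% of the window, otherwise an error is raised rather than a
silently unstable mean.

`hr_tests()` runs paired Wilcoxon tests of each intervention against
baseline at the horse level: the PRI group's single contrast is
reported raw; the UNI group's two contrasts form a family and are
Holm-adjusted.

## Classification

`build_features()` turns per-clip summaries into a feature matrix: per
selected code a frequency and/or maximum-duration column (codes sorted
alphabetically, frequency block first), zeros for absent codes, labels
`control` (baseline) vs `intervention` (everything else). Classifier
features are typically built from the *raw* annotations, without the
ear-flicker merge, so the classifier sees unmodified data.

`loo_evaluate()` scores the features by leave-one-out: for each
held-out clip, columns are standardized using the training clips only,
the SVM cost `C` is selected from `{0.01, 0.1, 1, 10, 100}` by
stratified five-fold cross-validation on the training clips (accuracy
criterion; ties go to the smaller `C`, i.e. stronger regularization),
and a linear SVM with class weights inversely proportional to class
frequencies predicts the held-out clip. Tuning is nested inside every
LOO fold: tuning once globally would let each test clip influence its
own model's hyperparameter. Standardization is likewise fitted per
fold; frequency counts and second-scale durations are incommensurate
without it. Fold draws are controlled by a recorded seed, and folds are
redrawn if a training partition would miss a class. Constant feature
columns are dropped with a warning. Precision and recall take
`intervention` as the positive class.

## The synthetic generator

`generate_study()` emulates the data structure of a two-group study:
a null model of independent per-code Poisson processes (per-clip rates,
log-normal durations truncated at the clip end), modified by

* condition-dependent rate multipliers,
* an *ear-flicker structure*: each EAD101 occurrence spawns an EAD104
  within U(0, 1) s with a per-condition probability,
* triggered couplings (Hawkes-like injections): each trigger occurrence
  spawns a response onset at `trigger + max(0.05, N(lag_mean, lag_sd))`
  with some probability — exactly the structure the co-occurrence
  method is designed to detect,
* a heart-rate model: per-horse resting rate drawn once from a
  group-specific normal law (floored at 24 bpm, the low end of equine
  resting rates), additive intervention shifts, multiplicative log-normal
  R-R jitter, and artifact beats (a beat shortened to 0.4 x its true
  interval with probability 0.02) for the filter to remove.

`default_study_config()` fixes the emulated design: 28 horses (18 PRI
with baseline + transportation, 10 UNI with baseline + transportation +
isolation), one clip per horse and condition, group resting rates
54 ± 20 bpm (PRI) and 35 ± 4.4 bpm (UNI) with shifts of +23 (PRI
transport), +53 (UNI transport) and +30 bpm (isolation), and a
vocabulary of 17 codes whose baseline activity is dominated by blinks
and ear movements. Base rates and multipliers are calibrated in closed
form (`expected_annotations()`) so the expected number of annotations
per clip is exactly 26 at baseline, 57 during transportation and 38
during isolation — the per-clip annotation means the design targets; the
relative multiplier pattern concentrates intervention increases on eye
white, nostril, upper-lid and mouth codes.

What the generator does *not* emulate: serial dependence and
non-stationarity within clips (true facial behaviour is bursty beyond
the planted couplings), inter-code inhibition, coder noise on onsets
and offsets (available separately via `simulate_second_coder()`),
heart-rate variability spectra, and any visual content. Passing tests
on synthetic data therefore validate the *algorithms* under known
ground truth; they do not certify effect sizes in real footage.

## Validation design

The test suite follows three patterns, all with fixed seeds:

* **Oracle equivalence** — the fast implementations are checked against
  literal re-implementations on random inputs: an O(n²) ordered pair
  scan for adjacency counts, an exhaustive branch-and-bound maximum
  matching for ear pairing, brute-force groupby for summaries, a
  beat-by-beat re-evaluation of the R-R rejection rule, and closed-form
  paired-t / exact signed-rank values (six uniform-sign pairs give
  `p = 2/2^6 = 0.03125`; Holm on (0.004, 0.008) gives (0.008, 0.008)).
* **Parameter recovery** — positive controls with planted structure:
  a rate-doubled code must be HFI-selected in at least 95% of 100 seeds
  at 20 clips per condition; a planted AU25 → AD19 coupling (lag ≈ 0.5
  s, probability 0.95, 20 horses, six clips per horse and condition)
  must be flagged significant at OWS 2 in at least 90% of seeds; a
  +30 bpm shift must drive both UNI heart-rate contrasts below 0.05 in
  at least 95% of seeds. The positive-control effect sizes were chosen
  by power analysis so the checks sit well inside their bounds rather
  than on them.
* **Null fidelity** — with no planted effects, leave-one-out accuracy
  must sit at chance (50% for the balanced null design, within
  Monte-Carlo slack of ±15 points over six seeds; small-sample LOO has
  a known slight below-chance bias, which the band accommodates), and
  the per-code rate of significance-flagged co-occurrence selections
  must not exceed the nominal 5%.

Problem sizes (1000 random clips for the adjacency oracle, 100/50/20
seeds for the recovery simulations, 12 clips per condition for the
calibration check) keep the full suite under a few minutes while
leaving the Monte-Carlo bounds far from their thresholds.

## Known limitations

* The co-occurrence node statistic is this package's
  operationalization; other degree normalisations are defensible.
* HFI selection is descriptive; do not read its output as a set of
  significant codes.
* The artifact filter approximates a proprietary algorithm; absolute
  heart-rate means can differ slightly from other filters near
  artifacts (hence tolerance-based comparison).
* With very small horse counts (two or three), the paired t of the
  co-occurrence contrast has one or two degrees of freedom; selections
  there are fragile, and the package refuses fewer than two paired
  horses outright.
* YAML round-trips of configurations preserve 15 significant digits;
  regenerated event streams agree to ~1e-9 s, not bit-for-bit.
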