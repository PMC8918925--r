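---
title: "Beat-to-beat RR-interval analysis for stratifying AF-induced heart failure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beat-to-beat RR-interval analysis for stratifying AF-induced heart failure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Some patients in persistent atrial fibrillation (AF) develop a reversible,
arrhythmia-induced form of heart failure (AF-HF): their left-ventricular
ejection fraction is depressed while fibrillating and recovers once sinus
rhythm is restored. Identifying these patients before cardioversion is
clinically valuable, and the only signal this package uses is the one every
Holter recorder already produces: the sequence of RR intervals. During AF the
ventricular response is irregularly irregular, so classical sinus-rhythm HRV
interpretation does not apply; instead, the working hypothesis is that the
statistical texture of the ventricular response — its variability, asymmetry
and spectral complexity — differs between AF-HF hearts and AF hearts with
preserved function.

`hfstrat` implements the complete analysis chain: segmentation of 24-h RR
streams into 5-minute windows with day/night tagging, fourteen beat-to-beat
features per segment, correlation-gated greedy feature selection wrapped
around a decision-tree classifier under patient-grouped cross-validation,
segment- and patient-level (majority-vote) evaluation, and exact tree-Shapley
feature importance. A synthetic AF cohort generator makes the whole chain
testable end to end without patient data.

## Data model and segmentation

An `rr_series` holds one patient's consecutive RR intervals (ms), a binary
label (`AF-HF` / `control`), and the clock time of the first beat (default
08:00, the conventional start of a 24-h Holter). Beat times are the
cumulative sums of the intervals, so a series is fully determined by the
interval list — there is no separate clock channel to disagree with.

Segmentation windows **cumulative RR time**, not wall clock: window $k$
covers $[k\,d, (k+1)\,d)$ seconds of accumulated interval time ($d = 300$ s
by default, the standard short-term HRV length), and a beat belongs to the
window containing its onset. The trailing partial window is discarded.
Windows with fewer than `min_beats = 100` beats are dropped as
artifact-dominated: at 5 minutes this corresponds to a mean RR of 3 s, far
below any plausible AF ventricular rate, so the rule only removes windows
mutilated by data gaps.

Circadian assignment is by segment start time with half-open windows:
daytime is [08:00, 22:00), nighttime the complement. A segment straddling
22:00 counts as day — the start-time rule is unambiguous at boundaries,
which matters because day and night sets must partition the full-day set
exactly.

## The fourteen features

For each segment the RR series $\{RR_n\}$ and its relative transform
$relRR_n = 100 \cdot RR_n / RR_{n-1}$ (percent; scale-free) are summarised
by:

* $\overline{RR}$, $\overline{relRR}$ — means;
* $SDRR$, $SDRR_{rel}$ — standard deviations ($n-1$ denominator);
* $RMSSD_{RR}$, $RMSSD_{relRR}$ — root mean square of successive
  differences, the short-term variability workhorse;
* $DC$, $DR$ — phase-rectified signal averaging (PRSA) deceleration
  capacity and deceleration reserve (below);
* $ShanEn$, $SampEn$, $SpecEn$ of both series — histogram, template and
  spectral irregularity measures.

Acceleration capacity ($AC$) is computed as an auxiliary (it is needed for
$DR$) and carried in the feature table without being part of the fourteen.

The ratio convention for relRR follows the verbal definition "percentage of
the current interval with respect to the previous one"; the symmetric
literature variant $200\,(RR_n - RR_{n-1})/(RR_n + RR_{n-1})$ is available
via `feature_config(relrr_mode = "symmetric")` for users who want the
published relative-RR normalisation.

### PRSA capacities

Deceleration anchors are beats longer than their predecessor
($RR_i > RR_{i-1}$); acceleration anchors the reverse. Anchors whose
beat-to-beat change exceeds 20 % are excluded as likely artifacts — in AF
the beat-to-beat scatter is large, so a permissive limit is needed, but
post-extrasystolic-like jumps should not anchor the average. The capacity
is the classical quadruple
$\big(\bar X(0) + \bar X(1) - \bar X(-1) - \bar X(-2)\big)/4$, where
$\bar X(k)$ averages $RR_{i+k}$ over anchors $i$. The anchor window
half-width is $L = 2$, the minimum that supplies the quadruple's offsets
$-2 \ldots 1$; an anchor is valid when indices $i-L$ through $i+L-1$ exist.
That window is exactly the data the quadruple touches, and it makes the
definition time-symmetric: on a palindromic series $DC = -AC$ exactly, so
$DR = DC + AC = 0$. $DR$ therefore measures deceleration–acceleration
asymmetry; with no valid anchor in either direction the feature is flagged
undefined rather than imputed.

### Entropies

*Shannon*: 16 equal-width bins spanning the segment's own min–max range, in
bits. Binning over the segment's own range makes the feature scale-free; a
constant segment has zero entropy by convention. The bin count is
configurable; 16 bins on 300–500 beats keeps the per-bin counts large
enough that the estimator is not dominated by sampling zeros.

*Sample entropy*: $-\ln(A/B)$ with template length $m = 2$, Chebyshev
tolerance $r = 0.2\,\mathrm{SD}$ of the segment, self-matches excluded, and
both template counts taken over starts $1 \ldots n-m$. These are the
field-standard defaults. $A = 0$ or $B = 0$ yields an undefined flag, not
an infinity.

*Spectral entropy*: the mean-subtracted tachogram is treated as evenly
spaced over beat index (the convention for AF RR analysis, where there is
no meaningful respiratory time axis), its raw periodogram is normalised to
a probability vector over the $K = \lfloor n/2 \rfloor$ positive-frequency
bins, and the Shannon entropy of that vector is divided by $\log_2 K$ so
the result lives in $[0, 1]$: 0 for a single spectral line, 1 for a flat
spectrum. Normalising by $K$ makes segments of slightly different beat
counts comparable. A Welch variant (averaged Hann-windowed halves) is
available behind `feature_config(specen_method = "welch")`; the raw
periodogram is the default because the acceptance properties (single-line
and white-noise limits) are exact for it.

Undefined features propagate as `NA` through the feature table; segments
with an undefined value among the candidate features are dropped from model
fitting and evaluation with a logged count, because trees cannot consume
missingness flags and imputation would blur exactly the irregularity signal
being studied.

## Classifier, splits and evaluation

The classifier is a CART decision tree (Gini impurity) with **uniform class
priors**: both classes carry equal total weight regardless of segment
counts, so a patient who contributes more segments cannot tilt the decision
boundary by volume alone. Hyperparameters: minimum 5 segments per leaf,
depth effectively uncapped (the backend's limit of 30), and the backend's
default complexity penalty `cp = 0.01` — a split must explain at least 1 %
of the root impurity. That default pruning is load-bearing for the wrapper
(below): with near-zero `cp`, trees manufacture splits from pure-noise
features and the selection's validation signal degrades into chance
fluctuation.

The split protocol mirrors a 52-patient study design: a class-balanced test
set (6 + 6 patients) is drawn once and never touched during development;
the remaining 40 patients are partitioned into five class-balanced
validation folds of 8, each fold training on the other 32. All splitting is
by patient, never by segment, so no patient's segments appear on both sides
of any split. The test rows are fingerprinted (MD5 of their sorted
patient/segment keys) before selection and the fingerprint is re-verified
immediately before the single final evaluation; a mismatch aborts the run.

Evaluation reports segment-level confusion counts with AF-HF as the
positive class (ACC, sensitivity, specificity, PPV), the per-patient
accuracy $ACC_i$, and the majority-vote patient call: a patient is assigned
the class predicted for more than 50 % of their segments. An exact 50/50
tie is called AF-HF — a screening posture that prefers a false alarm to a
missed reversible cardiomyopathy — and flagged in the report. One-tailed
Wilcoxon rank-sum tests compare feature distributions between classes
(default direction: lower in AF-HF, the direction observed for spectral
entropy); a fully tied feature returns $p = 0.5$ with a degeneracy flag.

## Greedy forward selection

Selection starts empty and, each iteration, evaluates every unselected
feature whose absolute Pearson correlation with each already-selected
feature is below the gate (0.6) — computed once on the pooled non-test
segments, which avoids test leakage and keeps the gate stable across
iterations. A zero-variance feature has undefined correlations and is
conservatively treated as gated. Candidates are scored by mean validation
accuracy over the five folds of a tree on `selected + candidate`; the best
is accepted if it improves the running best by at least `min_improve`
(default 0.005, half a percentage point). Ties break toward the candidate
least correlated with the selected set, then canonical feature order, so
the procedure is fully deterministic given the split plan.

The `min_improve` epsilon is a deliberate design choice where the design
was genuinely open. The fold-mean validation accuracy at a few thousand
segments has a standard error near one percentage point; the maximum over
a dozen candidates of such an estimate exceeds the running best by a
hair's breadth with high probability even on pure noise. Under a literal
"any increase accepts" rule, selection on a cohort with *no* class signal
routinely accumulated three to five noise features; with the half-point
threshold it stops at one or two, while genuine effects (several points of
accuracy) are far above the threshold. "Performance could not be further
increased" is thus read as "not increased by a meaningful amount".

The single-feature baselines are trained and evaluated under the identical
split plan and retrain protocol as the multi-feature model, so their test
accuracies are directly comparable.

## Shapley importance

Feature importance is computed a posteriori on the final tree with exact
interventional Shapley values. For an explicand $x$ and one background row
$b$, the value of a coalition $S$ is the tree's AF-HF probability when
features in $S$ come from $x$ and the rest from $b$; restricted to one
root-to-leaf path this game is a conjunction, whose Shapley values have a
closed form in the number of path features followed only by $x$ ($p$) and
only by $b$ ($q$): each $x$-only feature receives
$v\,(p-1)!\,q!/(p+q)!$ and each $b$-only feature $-v\,p!\,(q-1)!/(p+q)!$.
Summing over leaves and averaging over the background sample yields exact
values satisfying local accuracy: each row's values sum to its score minus
the mean background score (verified to $10^{-6}$ in the tests, where the
implementation is also checked against an exhaustive-coalition oracle).

Because the per-run computation is exact, the resampling protocol — 1,000
runs, each drawing 100 segments with replacement as both explicand set and
background — produces a standard deviation that measures *sampling*
variability alone, with no estimator noise mixed in. Unused features
receive exactly zero attribution.

## The synthetic cohort generator

The generator emulates what the analysis actually consumes: beat-to-beat
statistics of 24-h AF RR streams, not ECG morphology. Each patient's
intervals follow

$$RR_n = \frac{60000}{HR(t_n)} \exp\!\big(\varepsilon_n - \sigma^2/2\big),$$

with $\varepsilon$ a stationary AR(1) process whose lag-1 autocorrelation
`ar_rho` tunes spectral complexity (higher autocorrelation concentrates
power at low frequencies and lowers spectral entropy) and whose stationary
variance is set from the RR coefficient of variation `cv_rr`; the
$-\sigma^2/2$ term centres the log-normal factor so the realised mean heart
rate tracks its target. $HR(t)$ carries a sinusoidal circadian term with
acrophase 15:00. Class defaults encode the contrast the analysis is meant
to detect: 24-h mean heart rate 91.6 vs 78.7 bpm (AF-HF faster — the
tachycardic component of arrhythmia-induced heart failure) and lag-1
autocorrelation 0.55 vs 0.05 (AF-HF less spectrally complex); `cv_rr`
defaults to 0.20 vs 0.24.

Two additions make the cohort more than a two-point distribution. First,
between-patient heterogeneity: each patient draws their own mean heart rate
(SD 8 bpm) and autocorrelation (SD 0.05) around the class values. Without
it, every patient of a class would be statistically identical and
patient-grouped cross-validation would be indistinguishable from pooled
splitting; 8 bpm keeps the classes overlapping at the patient level, which
is what makes held-out-patient evaluation informative. Second, artifact
gaps: at `artifact_rate` 0.5/h, a contiguous run of beats (mean 30 s) is
deleted and the recording shortens accordingly — the same effect as cutting
artifact stretches from an annotation file. Gaps are deletions rather than
bridged super-intervals because the series invariant (beat times are the
cumulative interval sums) leaves no way to "preserve" wall time across a
hole without fabricating an interval that was never observed.

What the generator does **not** emulate: AV-nodal conduction dynamics,
ectopy morphology, respiratory modulation, or the heavy-tailed artifact
structure of real Holter data. Passing end-to-end tests on this cohort
demonstrates that the pipeline recovers planted class effects through the
full protocol without leakage — it does not certify clinical performance on
real AF recordings, where class effects are weaker, noisier and entangled.
On the default strong-effect cohort the planted contrast is deliberately
clean, and the pipeline typically saturates near-perfect test accuracy;
chance-level behaviour on a zero-effect cohort is the complementary
calibration check.

## Problem sizes and numerical choices

The test suite exercises the selection properties at the study's daytime
scale (52 patients, about 85 daytime segments each, roughly 4,400 segments)
because wrapper stopping behaviour is sample-size dependent: pruning
reliably rejects noise splits only once per-split gains shrink below the
complexity penalty. End-to-end recovery uses five full 24-h cohorts and
chance calibration ten shorter (6-h) ones — chance level does not depend on
recording length. Feature-oracle equivalence is checked on 1,000 random
375-beat segments against independent naive implementations at $10^{-9}$
relative tolerance.

Other numerical conventions: Chebyshev distance for sample entropy with
strict `<=` matching; histogram binning by linear index with the maximum
value folded into the top bin; periodogram bins $1 \ldots \lfloor n/2
\rfloor$ (Nyquist included for even $n$ — a pure alternation is a single
line only when the length is even); correlations use pairwise-complete
observations; undefined-vs-undefined comparisons in tests require matching
`NA` flags, not silent dropping.

## Known limitations

* Real AF data will contain ectopy and post-pause accentuation patterns
  the AR(1) log-normal model cannot produce; PRSA-based features on real
  data may behave differently than on the simulator.
* The relRR ratio convention and the $DR = DC + AC$ composition are the
  package's declared readings of tersely described quantities; both are
  isolated behind configuration switches (`relrr_mode`) or single functions
  so alternative definitions can be swapped in.
* The decision tree is the only classifier shipped; the training interface
  is a single function (`train_tree`) and the evaluation machinery is
  classifier-agnostic, so plugging in another model is straightforward but
  intentionally out of scope.
* With 12 held-out patients, patient-level accuracy moves in steps of
  1/12; differences smaller than a step are not interpretable at this
  cohort size.
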