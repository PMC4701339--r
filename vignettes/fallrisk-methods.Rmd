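---
title: "Entropy-based fall-risk classification: models, calibration, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based fall-risk classification: models, calibration, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fallrisk)
```

This vignette is the package's own account of its methods: what is
computed, under which conventions, why the open design choices were made
the way they were, and what the synthetic cohorts can and cannot tell you
about real data.

## The analysis

A subject contributes eight ground-reaction-force (GRF) channels: walking
force along three axes for each foot (medial-lateral `ML`,
anterior-posterior `AP`, superior-inferior `SI`) and the vertical (`V`)
force of each foot during a sit-to-stand transfer. The working hypothesis
is that fallers produce *more regular* force signals — weaker, less
adaptable neuromuscular control shows up as smoother curves — so signal
irregularity, quantified by sample entropy, separates fallers from
non-fallers.

The pipeline is:

1. **Preprocess** each channel: divide by body weight times `g`
   (9.81 m/s²), then standardize to zero mean and unit variance.
2. **Quantify** each channel by sample entropy with `m = 2`, `r = 0.25`,
   giving an 8-vector per subject.
3. **Classify** subjects with three nearest-neighbour rules (LMKNN, PNN,
   LMPNN) over every nonempty subset of the 8 features, scored by
   leave-one-out cross-validation (LOOCV), and select the winning subset
   sensitivity-first.
4. **Compare** the groups per feature with the Wilcoxon rank-sum test at
   `alpha = 0.1` and describe relationships among selected features with
   Spearman correlation.

## Sample entropy conventions

`SampEn(m, r) = -ln(A / B)` with `B` the number of ordered template pairs
`(i, j)`, `i ≠ j`, whose length-`m` embeddings lie within Chebyshev
distance `r`, and `A` the same count at length `m + 1`. Conventions that
had to be pinned for exact reproducibility:

- **Template set.** Both `A` and `B` run over the `N − m` templates
  `i = 1..N−m`, so every template has a defined `(m+1)`-th point. This is
  the common convention in the entropy literature.
- **Tolerance.** The series is standardized first, so `r = 0.25` is an
  absolute tolerance equal to 0.25 SD. Because standardization follows
  weight normalization, entropy is invariant to the weight step (asserted
  as a regression guard) and to any affine rescaling of the raw signal.
- **Standardization divisor.** Population SD (divisor `N`). At the series
  lengths involved the difference from the sample SD is negligible, but it
  must be fixed for the exact pair-count oracle tests.
- **Undefined values.** `A = 0` or `B = 0` yields `NA` rather than an
  infinite or clamped value; the feature extractor treats an undefined
  channel as an error naming the channel.
- **Time reversal.** The `(m+1)`-point count `A` is exactly
  reversal-symmetric (the reversed series has exactly the reversed
  templates). `B` is not quite: reversal swaps which of the `N − m + 1`
  `m`-point windows is excluded, so entropy can move by a boundary term of
  order `1/N`. The tests assert exact `A` symmetry and bound the entropy
  difference.

The production pair counter is compiled; an independent, deliberately
naive R transliteration in the test helpers must agree *exactly* (same
`A`, same `B`) on hundreds of random series.

## Classifier conventions

All three rules share the per-class neighbour ordering (ascending
Euclidean distance, exact ties broken by training row index) and differ in
the class score; ties between class scores go to the earlier class level.
With fallers first in the level order, an exactly ambiguous case fails
"safe" toward a faller call, consistent with treating sensitivity as the
primary metric. `k` larger than a class truncates to the class size — a
situation LOOCV on small cohorts reaches routinely — rather than erroring.
PNN/LMPNN weights are exactly `1/j`, not normalized to sum to one.

The LOOCV × subsets × `k` sweep is compiled for speed; the exported
classifier functions are pure R, are verified against a transliteration of
the defining equations to `1e-12`, and the test suite checks fold-by-fold
that both routes produce identical confusion matrices.

## Selection rule and its sharp edges

The winner is the evaluation maximal under (sensitivity, accuracy,
specificity), then smaller subset, earlier enumeration order (ascending
cardinality, lexicographic within), smaller `k` — a total order, so the
winner is unique and duplicating evaluations cannot change it. Undefined
metrics (zero denominators) rank below any defined value. When several `k`
tie on the winning subset and metrics, all are reported (`k_values`).

One behaviour of the sensitivity-first rule deserves a warning. Nearest-
neighbour rules have a density bias: with unequal groups and large `k`,
the larger class's neighbours pack closer and the rule drifts toward
always predicting it. If the *positive* class is the majority, noise-only
feature subsets can reach sensitivity 1 with poor specificity, and
sensitivity-first ranking will happily crown them. With the positive class
in the minority the degenerate direction is sensitivity 0 and harmless.
The planted-signal recovery test therefore uses a faller-minority cohort
(14/24, the split consistent with the reference confusion matrix);
analysts applying the rule to faller-majority cohorts should inspect
specificity before trusting the selected subset.

## Statistical stage

Rank-sum comparisons use the exact null distribution when both groups have
at most 10 tie-free values and the normal approximation with tie and
continuity correction otherwise; two-sided throughout, with group means
and sample SDs reported alongside. No multiplicity correction is applied
by default (matching the reference analysis); `p_adjust = "bonferroni"` or
`"BH"` is available. Spearman correlation is the Pearson correlation of
mid-rank transforms with the two-sided t-approximation p-value; magnitude
bands are half-open (`[0.50, 1]` high, `[0.30, 0.50)` moderate,
`[0.10, 0.30)` weak, below negligible) so every coefficient receives
exactly one category. A constant feature column is flagged degenerate
rather than crashing the report.

## The synthetic cohort generator

No public dataset of this design exists, so the generator is a first-class
module. Each channel is a MIX(p) process: sample `t` equals
`sin(2πt/period)` with probability `1 − p` and uniform noise (variance 1
at `noise_amp = 1`) with probability `p`. The family was chosen because
its sample entropy is a smooth, tunable function of `p` that spans the
range seen in faller/non-faller cohorts, and because it is standard in the
entropy-methods literature.

Key choices, in the order they matter:

- **Period 200** (samples per sinusoid cycle). The entropy floor — the
  pure sinusoid at `p = 0` — must sit *below* the lowest target mean
  (≈ 0.085 for faller STS channels). The floor scales roughly like the
  inverse period: ≈ 0.29 at period 12, ≈ 0.13 at period 100, ≈ 0.06 at
  period 200, while `p = 1` yields ≈ 1.97. Period 200 is the default
  because it covers every default target with margin at all supported
  series lengths.
- **Calibration curve.** `mix_entropy_curve()` estimates mean and SD of
  SampEn over 20 standardized realizations at each of 25 grid points
  (denser near `p = 0` where the response is steepest), forces the means
  non-decreasing, and the generator inverts it by linear interpolation.
  `calibrate_irregularity()` offers the same mapping as monotone bisection
  for a single target, with common random numbers across candidate `p`
  values so the empirical response stays monotone.
- **Monotonicity has a tail caveat.** Measured carefully, mean entropy
  rises strictly with `p` until ≈ 1.99 near `p = 0.9` and then dips
  marginally (≈ 1.96 at `p = 1`): rare sinusoid samples embedded in noise
  match slightly less often than pure noise. All calibration targets live
  far below this plateau (entropy < 0.7, `p < 0.3`), where the response is
  strictly increasing; the tests assert exactly that.
- **Subject variability.** Per subject and channel, a target entropy is
  drawn around the group target and mapped through the inverted curve.
  The draw SD is shrunk by the single-realization entropy noise (estimated
  from the curve replicates) so the *realized* spread approximates the
  target SD. Latent draws are moment-matched within each group × channel
  (centered and rescaled across subjects) so realized group means sit on
  the targets instead of drifting with finite-sample noise — calibration
  to ±0.05 at `n = 100`/group is verified in the tests.
- **Correlation structure.** The channel pairs `L_SI_F`/`R_ML_F` and
  `L_V_F`/`R_V_F` share a subject-level latent factor (`rho = 0.5`),
  reproducing the qualitative cross-feature correlations of real cohorts
  (the STS pair comes out "high" in the worked example). Exact correlation
  values are not calibration targets.
- **Determinism.** One master seed; per-subject and per-channel streams
  are derived from it, so an identical `cohort_spec` yields bit-identical
  tables regardless of generation order, and the full pipeline is
  byte-reproducible (asserted via file checksums).
- **Defaults as study conditions.** 23 fallers / 15 non-fallers, body
  weight uniform on 40–90 kg, 1000 samples per channel. Sampling rate and
  trial duration are not physiological claims — they are explicit
  configuration, long enough for stable SampEn at `m = 2` and short enough
  for fast tests.

**What the generator does not emulate.** There is no gait-cycle structure,
no heel-strike transients, no stance/swing asymmetry, no force-plate
noise floor, and no dependence between body weight and entropy. Passing
tests demonstrate that the *pipeline* is correct and that the *entropy
structure* of the groups is recovered; they do not demonstrate that the
classifiers would reach any particular performance on real recordings.
Real walking data may also arrive as multiple passes per channel; the
extractor supports per-trial entropy averaging (`trial_mode = "average"`)
for that case, while synthetic channels are single continuous series.

## Problem sizes used by the test suite

Oracle equivalences run on 200 random series (lengths 10–300) and 100
random classifier instances; generator calibration uses 100 subjects per
group; planted-signal recovery runs 10 cohorts of 38 subjects through the
full 255-subset search; rank-sum calibration uses 2000 null simulations.
These sizes were chosen to make Monte-Carlo conclusions stable while
keeping the default suite around a minute on one core.

## Known limitations

- The MIX family's entropy range at a given length bounds the reachable
  targets; `generate_cohort()` refuses infeasible targets with a
  calibration error naming the achievable interval.
- Sensitivity-first selection on faller-majority cohorts can prefer
  degenerate high-sensitivity subsets (see above); an accuracy-first
  toggle (`selection = "accuracy_first"`) is provided.
- The rank-sum stage reports unadjusted p-values by default at
  `alpha = 0.1`; with eight features, roughly one false star per run is
  expected under the null.
- LOOCV winners on 38 subjects are optimistically biased model selections;
  the package reports them as the method defines them and makes no claim
  of out-of-sample validity.
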