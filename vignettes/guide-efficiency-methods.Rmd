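---
title: "Methods: boosted-tree prediction of CRISPR-Cas9 cleavage efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: boosted-tree prediction of CRISPR-Cas9 cleavage efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the modeling approach

SpCas9 guides targeting different genomic sites differ widely in how
efficiently they induce cleavage, and much of that variation is encoded in
the local sequence. guideboost predicts the cleavage efficiency of a guide
(on the indel-percent scale of lentiviral surrogate screens, roughly 0-100)
from its 30-nt *expanded target*: 4 nt of upstream context, the 20-nt
spacer, the NGG PAM, and 3 nt of downstream context. Positions are labeled
relative to the spacer: `-4..-1` upstream, `1..23` spacer + PAM, `+1..+3`
downstream; there is no position 0.

The predictor is an ensemble of gradient-boosted regression trees fit under
squared-error loss. Two properties of this model class drive the design:

* **Native categorical splits.** Position-specific nucleotides and
  dinucleotides enter as categorical variables with fixed vocabularies (4
  and 16 levels), not as one-hot indicator columns. A single split can then
  group levels (e.g. `di20 in {AC, AG, GA, GC, GG, GT}`), which keeps trees
  shallow and makes importance attribution per *position* rather than per
  indicator.
* **Exact additive interpretation.** Under squared error, every tree node's
  running prediction is the mean of its branch, so each prediction
  decomposes exactly into the training grand mean plus one signed
  contribution per feature.

## The 149 features

All features derive from the 30-mer (and, for the thermodynamic block, the
spacer alone):

| block | width | content |
|---|---|---|
| GC content | 1 | (G+C)/30 |
| k-mer counts | 4 + 16 + 64 | overlapping windows, k = 1, 2, 3, whole 30-mer |
| poly-T | 2 | number of T-runs of length >= 3; longest T-run |
| positional mono | 28 | one 4-level factor per label, excluding the static PAM GG |
| positional di | 28 | one 16-level factor per adjacent pair, keyed by start label |
| thermodynamic | 6 | Tm1-Tm4, dG_spacer, dG_full |

93 features are numeric and 56 categorical. Conventions that were genuinely
open, and the choices made:

* **Counts, not proportions, for k-mers.** "Frequency" over a fixed-length
  window is monotone-equivalent either way for tree splits; raw integer
  counts are exactly testable. `kmer_counts(..., proportions = TRUE)`
  provides the other convention.
* **`max_polyT` is reported unconditionally** (a longest run of 1 or 2 is
  reported as such), because the poly-T *segment* definition (>= 3 Ts, an
  RNA Pol III termination signal) and the guide-grouping convention
  ("maximum poly-T length") pull in different directions, and the
  unconditional value reproduces the grouping (no poly-T = run <= 2) while
  losing no information. `zero_short_runs = TRUE` zeroes runs below 3.
* **Dinucleotides are keyed by start label**: `di-1` spans the upstream/spacer
  boundary (-1, 1), `di20` spans the spacer end and the variable PAM
  nucleotide, `di23` spans (23, +1). The static pair (22, 23) is dropped.
* **Feature names match the field's plot vocabulary** (`di19`, `Tm1`,
  `TT`, ...) so importance tables are directly comparable across tools.

### Melting temperatures

Tm1-Tm4 cover labels 1-21, 1-4, 5-12 and 16-20 of the spacer (plus the
first PAM base for Tm1). They are nearest-neighbor two-state melting
temperatures: stacking enthalpies and entropies summed over adjacent pairs
(unified DNA/DNA parameter set), terminal initiation terms, a monovalent
salt entropy correction of 0.368 (N-1) ln[Na+] cal/(mol K), and
Tm = dH / (dS + R ln(Ct/4)) - 273.15. Defaults: 50 mM Na+, 250 nM total
strand concentration. Nearest-neighbor thermodynamics is the only standard
Tm family sensitive to base *order*, which is the point of using
region-specific Tm as a feature; the parameter set and concentrations are
configurable and recorded in model provenance. Short regions (e.g. the
4-mer for Tm2) can yield Tm values far below 0 degrees C; they are used as
relative covariates, not physical melting claims.

### Folding free energies

`dG_spacer` folds the transcribed 20-nt spacer; `dG_full` folds the spacer
joined to an 81-nt scaffold (101 nt total). The folding engine is an
interface: the default shells out to ViennaRNA's `RNAfold` (batched, one
subprocess for all sequences, the `structure (energy)` line parsed
exactly), and a deterministic arithmetic stub keeps pipelines runnable and
reproducible where no external folding program is wanted. The scaffold
default is the canonical S. pyogenes sgRNA scaffold followed by a 5-U
Pol III terminator (81 nt); it is configurable, and the scaffold actually
used is stored with the model.

## Cross-study harmonization

Training data for this kind of model typically combines two screens
measured on different scales. The pipeline reproduces the standard
construction: merge the first study's train/test tables (averaging
duplicate guides); filter each replicate day of the second study to guides
with at least 200 reads (inclusive) *before* intersecting, then average the
day pair; regress the first study's scores on the second study's over the
guides common to both (ordinary least squares — the direction is fixed by
which scale is the reference); rescale and merge, averaging shared guides
with unweighted means. Guide identity is the full 30-mer, because features
depend on the full 30-mer. All intermediate counts are reported so the
construction can be audited.

## Training protocol

* **Cross-validation:** 10 folds drawn once from a fixed fold seed and
  reused verbatim for every hyperparameter evaluation; per fold, up to
  7,000 trees with early stopping (patience 10) on the held-out fold under
  RMSE.
* **Final fit:** all rows, with the tree count set to the rounded mean of
  the per-fold best iterations (round-half-even, R's default).
* **Hyperparameters:** learning rate, maximum depth, maximum leaves,
  maximum histogram bins, and feature/row subsampling fractions, tuned by
  Bayesian optimization: 10 random initial points then 100 guided rounds by
  default. The surrogate is a Gaussian process (squared-exponential kernel,
  length-scale chosen by marginal likelihood over a fixed grid) with
  expected improvement maximized over a random candidate set; integer
  dimensions are rounded, the learning rate is searched on a log scale.
  Default bounds — learning rate [0.005, 0.3], depth [3, 12], leaves
  [8, 256], bins [63, 511], fractions [0.5, 1] — are standard well-behaved
  ranges for tabular regression at ~10^4 rows. Failed objective
  evaluations are recorded and skipped, not fatal.
* **No L2 shrinkage on leaf weights** (`lambda = 0`): leaf values are then
  exact branch means of the stage's residuals, which is what makes the
  branch-mean reading of tree internal values and the additive
  decomposition exact rather than approximate.
* **Determinism:** single-threaded training with fixed training, fold and
  search seeds reproduces bit-identical models; all seeds are stored in the
  model's provenance.

Unseen categorical levels at prediction time cannot occur for valid
sequences (vocabularies are closed), but malformed feature tables are
caught by the schema, and an out-of-vocabulary level is encoded as missing
(the learner's default-direction fallback) with a warning.

## Interpretation outputs

* **Importance** is total split gain per feature across the ensemble —
  the recorded improvement in the squared-error objective — normalized to
  sum to 1, ordered descending with an alphabetical tie-break. On small
  models the recorded gains are verified in tests against a brute-force
  recomputation (sum-of-squares reduction over the actual branch
  memberships).
* **Per-prediction contributions** use a path-based decomposition computed
  in double precision over the parsed trees: along each root-to-leaf path,
  the change in branch mean at every split is credited to the split
  feature. Predictions themselves are assembled from the same parsed leaf
  values, so `base + sum(contributions) = prediction` holds to machine
  precision. The learner's native SHAP-style output is available via
  `method = "native"`; it is float32-accumulated, which on a 0-100 score
  scale leaves discrepancies around 1e-5 — too coarse for an exact
  additivity contract, which is why it is not the default. The scheme used
  is recorded on the output.
* **Tree exports** carry an `internal_value` per node: the mean of the
  stage's boosting target among training rows reaching that node, computed
  in double precision by routing the supplied training rows through the
  parsed tree. The first tree's root therefore sits at the training grand
  mean and every later tree's root at 0 (squared-error residuals are
  centered). Without training data a cover-weighted aggregation of leaf
  values is used instead (accurate to the stored leaf precision, ~1e-4).
  Categorical splits are exported as category subsets, never as thresholds,
  and exports render to Graphviz DOT.

## Evaluation harness

Model comparison uses Spearman correlation (Pearson on mid-ranks, average
ranks for ties), the standard metric for this ranking-oriented task.
Evaluating on an external dataset removes guides present in the training
set first, and negative-selection dropout screens (lower log2 fold change =
more cleavage) are sign-reversed via a flag; negation flips the Spearman
sign exactly.

Two predictors sharing one observed variable are compared with Steiger's
(1980) Z2* test for dependent correlations: Fisher-z difference scaled
using the pooled-correlation estimate of the covariance between the two
coefficients, two-sided by default (a one-sided flag exists). Applying the
test to Spearman rather than Pearson correlations is the field's common
practice and is statistically approximate; the output carries that caveat,
and the Monte-Carlo calibration in the test suite is run on the test's
native (Pearson, trivariate normal) domain, where the empirical type-I
error at the 5% level sits within [0.04, 0.06] over 2,000 replicates.

## The synthetic screen generator

Real guide screens cannot be bundled, so every stage is exercised on
generated data with the statistical structure the pipeline assumes. A
screen draws uniform random 30-mers (PAM GG fixed), builds a noiseless
additive signal on the score scale — baseline 45; -10 score units per unit
of longest-T-run above 2; a quadratic GC optimum centered at 0.55 with
curvature -80; dinucleotide category effects at spacer positions 19 and 18
(spread of a few score units, purine-favoring) and a mononucleotide effect
at position 20 — adds Gaussian noise (SD 10) and clips to [0, 100],
logging the clipped fraction. Baseline and effect magnitudes were chosen
once to echo the group-mean gaps and positional-feature prominence reported
for real lentiviral screens (no-poly-T, TTT and TTTT+ guide groups spread
over roughly 45/35/20), and the noise level leaves a realistic
signal-to-noise ratio; the noiseless signal is returned alongside the
observed score so recovery can be measured against ground truth.

Paired screens emulate the harmonization setting: a second screen shares a
configurable number of guides (49 by default) with the first and reports
`intercept + slope * signal` plus noise on two replicate days, with
negative-binomial read counts so a realistic fraction of guides falls below
the 200-read filter.

What the generator does *not* emulate: the real sequence-activity
landscape (effects here are exactly additive in a handful of known
features), chromatin or delivery effects, inter-replicate correlation
structure, heteroscedastic or heavy-tailed measurement error, and the
scale of real libraries. Passing the synthetic recovery tests therefore
demonstrates that the machinery — featurization, harmonization, training,
attribution — recovers structure it is pointed at; it does not certify
predictive accuracy on real screens.

## Numerical choices and degenerate inputs

* Additivity of contributions and the branch-mean root properties are
  asserted at 1e-6; the double-precision paths make them hold far tighter
  (~1e-13 and ~1e-7 respectively).
* Affine recovery tests that check OLS confidence-interval coverage use
  wide score bounds so clipping does not distort the planted link, and
  Bonferroni 97.5% per-coefficient intervals for the joint two-parameter
  coverage statement.
* Constant responses are legal: cross-validation reports zero MSE and an
  undefined (NA) rank correlation rather than failing.
* Zero-tree models (a possible outcome of early stopping) predict the
  grand mean, contribute nothing, and yield an empty importance table with
  a warning.
* Degenerate normalization inputs (fewer than 2 overlap pairs, constant
  source) and degenerate correlations (|r| = 1, zero rank variance) raise
  typed errors rather than propagating NaN.

## Problem sizes used by the shipped checks

The test suite and the acceptance script run at desk scale, chosen so the
full suite completes in about a minute of training time: screens of
600-5,000 guides, 3-5 CV folds with tree ceilings of 60-400, a reduced
Bayesian-optimization budget (3 initial + 3 guided rounds over the two
dominant knobs), ten 2,000-guide seeds for the importance-stability check,
and 2,000 Monte-Carlo replicates for the type-I calibration. The protocol
defaults (10 folds, 7,000 trees, 10 + 100 optimization rounds) are what a
real training run uses.

## Working with real screens

The readers accept the published supplementary tables of the Kim et al.
and Xiang et al. HEK293T lentiviral screens (and the benchmark collections
distributed with the crisporPaper repository) once downloaded:
`read_guides()` with a column map, `build_training_set()` for the
harmonized ~24k-guide training set (the counts report lets you check the
construction), `tune_guideboost()` at the full protocol, and
`evaluate_dataset()` with the training sequences excluded and
negative-selection scores reversed. Quantities that depend on those real
data — cross-validated Spearman near 0.78, external-benchmark correlations,
and specific per-guide predictions and contribution values — are not
reproducible from synthetic data and are deliberately not asserted
anywhere in this package's checks.

## Known limitations

Wild-type SpCas9, NGG PAMs and U6/T7-style expression contexts only; no
off-target scoring or genome scanning; thermodynamic features use one
parameter set per model rather than per-study calibration; Steiger's test
on rank correlations is approximate; and boosted ensembles with hundreds
of trees remain only partially interpretable even with exact attribution.
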