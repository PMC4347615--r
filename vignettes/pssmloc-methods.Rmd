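---
title: "Segmented PSSM descriptors and Rotation Forest classification: models and choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmented PSSM descriptors and Rotation Forest classification: models and choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssmloc)
```

## The problem

Predicting the subcellular location of a bacterial protein from sequence
alone is a multi-class classification problem with strong class imbalance
(inner-membrane proteins outnumber nucleoid-associated ones by nearly two
orders of magnitude in the standard Gram-negative benchmark) and a
multi-label wrinkle: a few proteins genuinely reside in two compartments.
`pssmloc` implements a descriptor-plus-ensemble pipeline for this setting:
four feature groups computed per protein from its PSI-BLAST
position-specific scoring matrix (PSSM), concatenated into a 401-dimensional
vector, classified by a Rotation Forest with 10-fold cross-validated
evaluation.

The package consumes PSSMs; it does not run PSI-BLAST. Each PSSM is an
L x 20 matrix giving, per position, a substitution preference for each amino
acid. Percentage columns are divided by 100 and rows renormalized to sum to
one; an optional logistic transform of the log-odds block is offered instead
(`prob_source = "sigmoid_logodds"`), since either reading of "substitution
probability" appears in the literature and the original parameterization is
not recoverable from published descriptions. The choice is stamped into all
derived feature files.

## The descriptors

**Consensus sequence.** Position i of the consensus is the amino acid with
the maximal substitution probability, `argmax_j P[i, j]`, ties broken by the
lowest column index for cross-platform determinism. Physicochemical
descriptors are computed on this evolutionarily smoothed sequence rather
than on the raw one.

**Attribute sequence.** A physicochemical scale assigns each amino acid a
value; the 20 values are min-max normalized once per scale so per-residue
values R_i lie in [0, 1]. Min-max was chosen over z-scoring because the
density and autocorrelation sums below implicitly assume a bounded,
non-negative range; a clipped z-score variant (`zscore_clipped`, +/- 3 sd
mapped onto [0, 1]) is available for scales with single extreme outliers.
Normalization is per scale, never per corpus, so feature values do not
depend on which other proteins happen to be in a dataset.

**OSD — overlapped segmented density (31 features).** The global density
`sum(R)/L` plus, for each side of the sequence and each segmentation factor
d in {5, 10, ..., 75} percent, the sum of attribute values over the first
d% of residues from that side. Because segments extend past the midpoint
(75% > 50%), left and right segments overlap mid-sequence, which is what
gives the descriptor its view of the middle of the protein. Segment sums
are kept as raw sums; a per-length normalized variant is available
(`osd_normalize = TRUE`) since "density" suggests a mean while the defining
sum is not one — the default follows the sum as written.

**OSA — overlapped segmented autocorrelation (150 features).** For each
side and d in {10, ..., 70} percent, and for each lag i up to the distance
factor DF = 10: `sum_j(R_j * R_{j+i}) / (D - i)` over the segment's D
residues, indices counted from that side (the right side is computed on the
reversed sequence, making the right block of a sequence exactly the left
block of its reversal). A whole-sequence block with lags 1..DF completes
the 7·DF + 7·DF + DF = 150 values. Lags that do not fit in a segment
(D - i <= 0) are defined as 0 so the vector length never varies; silently
dropping or NaN-ing them would make short proteins incomparable.

**Segment boundaries.** The published description is ambiguous between a
length reading ("the first d% of L") and an attribute-mass reading (the
prefix whose value sum reaches d% of the total). Both are implemented;
`length_fraction` — `max(1, floor(d/100 * L))` — is the default because it
is the literal reading of the density construction, and the chosen mode is
recorded in the feature metadata so matrices computed under different modes
are never silently mixed. With all-zero attribute mass the mass rule is
undefined and falls back to the length rule.

**PSSM-SC — semi-composition (20 features).** Column means of the PSSM: the
profile-weighted analogue of amino-acid composition. For row-stochastic
matrices the block sums to one.

**PSSM-AC — auto-covariance (200 features).** For each amino-acid column j
and lag k = 1..10, the lag-k covariance of the column with itself, divisor
L - k. Proteins with L <= DF are refused rather than zero-padded: a padded
coefficient would be indistinguishable from genuinely zero covariance, and
the caller is told to lower DF or drop the protein instead.

The combined vector is OSD | OSA | SC | AC with fixed intra-block order
(block boundaries at 31, 181, 201), 401 features per physicochemical
attribute. One attribute per matrix is the default; concatenation of
several attributes is possible but changes the column count in multiples of
401.

## The classifier

A Rotation Forest of 100 trees. Each tree sees the data through its own
rotation matrix, assembled per tree as follows: the N features are
partitioned at random into subsets of 3; for each subset, a random non-empty
subset of classes is selected and a 75% bootstrap of their rows drawn; the
PCA loadings of that sub-matrix (components with eigenvalue above 1e-12)
form the subset's column block, placed on the rows of its features.
Zero-variance subsets fall back to an identity block, so degenerate inputs
rotate harmlessly instead of failing. The published description fixes only
"K = 100"; whether that K counts feature subsets or ensemble members is
ambiguous in the source, and the package follows the WEKA-style reading —
100 trees, 3 features per subset — with both knobs independently
configurable. The class-subset bootstrap follows the canonical Rotation
Forest construction.

Base learners are unpruned CART trees (`rpart`, `cp = 0`, `minsplit = 2`),
standing in for the C4.5/J48 learner of the original toolchain; exact J48
semantics (gain-ratio splitting, error-based pruning, fractional
missing-value weights) are out of scope. Votes are combined by plurality
with ties broken toward the lowest class index. Fitting is a pure function
of (data, labels, configuration): member t draws from a substream derived
from the seed and t, so refitting reproduces the model bit for bit.

## Evaluation

`cross_validate()` performs k-fold (default 10) cross-validation with two
deliberate departures from a naive split:

* **Group awareness.** The duplicated samples of a multi-location protein
  always land in the same fold. The alternative leaks the same feature
  vector into both train and test and inflates accuracy; the published
  account is silent on this, and the conservative choice was made.
* **Undefined per-location accuracy.** A location with no test samples
  reports `NA`, not 0, so tiny classes (the Gram-negative nucleoid class
  has 8 samples) are not conflated with fully misclassified ones.

Folds are random, sized as evenly as the group constraint allows (groups
are placed largest-first into the currently smallest fold; with realistic
corpora, where single-location proteins dominate, fold sizes differ by at
most one — 523 samples split as 52/53). Overall accuracy is
Q = 100·C/N with every (protein, location) sample counted once, matching
the benchmark denominators (523, 1456). A paired two-sided t-test utility
(`paired_ttest()`) is included for method comparisons across folds; it
refuses all-identical differences, where t is undefined.

## Synthetic fixtures

`synth_dataset()` generates labelled corpora with no external downloads:
PSSM rows are Dirichlet draws around a per-class base composition,
`base_c = (uniform + signal * sig_c) / (1 + signal)`, where sig_c spreads
mass over five seeded signature residues. The signal dial feeds every
feature group at once — SC directly, OSD/OSA through the consensus
sequence, AC through row variability — which is the simplest mechanism that
exercises the full pipeline. At `class_signal = 0` classes are
indistinguishable by construction; at 0.5 the signature residues are about
three-fold enriched and the pipeline separates classes essentially
perfectly. An imbalanced preset (`fixture_spec_imbalanced()`) mirrors the
shape of the 8-location Gram-negative class distribution for testing
per-location reporting of tiny classes.

What the fixtures do **not** emulate: homology between proteins, real
positional structure (signal peptides, transmembrane runs), or the
NR-database dependence of real PSI-BLAST profiles. Passing the synthetic
separability checks therefore demonstrates that the pipeline's plumbing and
statistics are correct — not that the published benchmark accuracies are
reproduced, which would require the original datasets and
database-version-matched PSSMs.

## Numerical and design notes

* Row renormalization tolerates and repairs all-zero percentage rows
  (uniform fallback), a real occurrence at unconserved termini.
* All feature computations are plain sums over doubles; the test suite
  pins them to independent brute-force loop implementations at 1e-12.
* Fixture PSSMs written to disk quantize percentages to integers, so a
  write/parse round trip reproduces probabilities to about 0.02 per cell;
  in-memory objects are exact.
* Problem sizes used by the simulation-based checks are the package's
  chosen study conditions: the separability run uses 4 classes x 50
  samples, lengths 50-200, signal 0.5, 100 trees, 10 folds; the null
  calibration uses 2 classes x 30 samples at signal 0 with 25 trees over 5
  seeds (chance-level behaviour does not depend on ensemble size); the
  signal-monotonicity sweep uses 2 classes x 25 samples, 20 trees, 5-fold
  CV over 5 seeds.
* Null-data cross-validation sits slightly *below* 50% on average — the
  familiar fold-imbalance anticorrelation of CV on label-free data, not a
  defect; the calibration check is a pooled binomial test, which it
  passes.

## Limitations

* No exact J48 base learner; ensemble accuracies can differ from
  WEKA-based runs in the low single digits even on identical features.
* The paired t-test utility is generic; the pairing used in the original
  comparison experiments is not recoverable from the text.
* Multi-label evaluation is limited to the duplicate-sample convention;
  no label-set metrics (subset accuracy, Hamming loss) are provided.
* Feature extraction is O(L·DF) per protein in pure R; thousands of long
  proteins take minutes, not seconds.
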