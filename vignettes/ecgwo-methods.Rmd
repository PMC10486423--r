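---
title: "Entropy-controlled grey wolf feature selection: models and methods"
author: "ecgwo package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-controlled grey wolf feature selection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecgwo)
```

## The problem

Computer-aided diagnosis of skin lesions commonly represents each
dermoscopic image by the activations of one or more pretrained
convolutional networks — for example the fully-connected and
average-pooling layers of DarkNet53, InceptionV3, InceptionResNetV2 and
DenseNet201, which give per-image feature vectors of widths 2, 1536, 1026
and 1920.  Concatenating several such blocks preserves complementary
information but inflates the dimension into the thousands and multiplies
redundancy, which hurts both accuracy and cost.  This package implements
the downstream half of that workflow as a reusable, testable toolkit:

1. **serial fusion** of feature blocks,
2. **feature-subset selection** by a grey wolf optimizer whose fitness is
   the Shannon entropy of a distribution derived from the candidate
   subset, and
3. a **stratified hold-out classification harness** reporting accuracy,
   sensitivity, specificity, FNR, FPR and F1.

Image-to-feature extraction is deliberately a plug-in boundary: any CSV
of per-sample features is accepted, and a seeded synthetic generator
stands in for CNN features so the whole pipeline runs in seconds with a
known ground truth.

## Serial fusion

Fusion is ordered concatenation: blocks of widths $p$ and $q$ fuse to
$\mathbb{R}^{p}\oplus\mathbb{R}^{q}\to\mathbb{R}^{p+q}$, values carried
over unchanged — no rescaling is applied at fusion time (normalization,
if wanted, belongs to the caller's preprocessing).  A column-origin map
makes the concatenation invertible (`unfuse_block()`), and
`standard_combinations()` returns the five block combinations studied in
the source framework (FV2–FV3, FV3–FV4, FV2–FV4, FV2–FV3–FV4,
FV1–FV2–FV3–FV4).

Selection output is summarised by the *reduction percentage*
$100\,(1 - d_\text{out}/d_\text{in})$, rounded to the nearest integer
with ties away from zero.  That rounding rule is our choice — it
reproduces 14 of the 15 published reference-table rows from their
printed dimensions; the remaining row (PH2, all four blocks: dimensions
give 86, printed 88) is internally inconsistent in the published table
and is flagged, not silently matched (see
`reference_reduction_table()`).  Note that the rule can produce 100 when
$d_\text{out}/d_\text{in} < 0.005$, which the entropy-mode selector does
reach on strongly compressible inputs.

## The grey wolf optimizer

GWO is a population metaheuristic: candidate solutions ("wolves") move
under the guidance of the three best solutions found so far — the alpha,
beta and delta leaders.  For a wolf at position $\mathbf{x}$ and leader
$\mathbf{x}_\ell$, per-dimension coefficients are drawn fresh each
update:

$$A = 2a\,r_1 - a, \qquad C = 2 r_2, \qquad r_1, r_2 \sim U(0,1),$$

the encircling distance is $D = |C\,\mathbf{x}_\ell - \mathbf{x}|$, each
leader proposes $\mathbf{x}'_\ell = \mathbf{x}_\ell - A\,D$, and the
wolf moves to the average of the three proposals, clamped to the search
box.  The control scalar decays linearly, $a = a_0(1 - t/T)$ with
$a_0 = 2$: early iterations ($|A|>1$ possible) explore, late iterations
exploit.  Leaders are replaced only by improvements, so the best-so-far
trace is monotone.

Design notes, where the convention was genuinely open:

* **Update rule.**  One circulating transcription of the leader-guided
  update wraps the displacement in nested absolute values,
  $\mathbf{x}'_\ell = |\mathbf{x}_\ell - |A\,D||$, which confines the
  search to non-negative coordinates and breaks optimization in signed
  domains.  We implement the canonical form above, and expose the
  literal variant behind `update_rule = "literal"` for comparison.
* **Schedule and bounds.**  Linear $2 \to 0$ schedule; positions are
  clamped to bounds after every update; fresh independent $r_1, r_2$
  per dimension, per leader, per wolf, per iteration.
* **Determinism.**  Every run is a pure function of the seed; the RNG
  stream is carried in the optimizer state and the caller's
  `.Random.seed` is restored.

The optimizer is validated on analytic benchmarks rather than on any
claim about real features: on the 5-D sphere (30 wolves, 300
iterations) the median final fitness over 10 seeds is far below
$10^{-2}$, and on 2-D Rastrigin the optimizer reaches below 1.0 in at
least 8 of 10 seeds.  These are engineering targets for the
implementation, not results about lesion data.

## Entropy-controlled selection

Wolves live in $[0,1]^d$, one coordinate per fused column.  A position
decodes to a binary mask by thresholding at 0.5 (`binarize()`); if no
coordinate clears the threshold, the largest one is switched on, so a
mask is never empty.  This decoder is the simplest reproducible choice;
transfer functions (sigmoid/V-shaped) are deliberate non-goals.

The fitness realizes a Shannon-entropy objective
$H = -\sum_p \eta_p \log_2 \eta_p$ over the selected subset.  The
underlying description leaves $\eta_p$ under-specified ("the selected
vector"), so the package defines it concretely: the **energy** of a
selected column is its mean absolute value over samples, and $\eta$ is
the energy vector normalized to sum to one (uniform fallback when all
energies are zero).  This yields a proper, scale-aware distribution over
the subset at $O(k)$ cost per candidate.  Alternatives we considered and
rejected for the default (histogram entropy per column; flattening the
sub-matrix into one empirical distribution) are noted as extension
points.

Raw entropy grows like $\log_2 k$ and would reward selecting
*everything*, which contradicts the 63–96 % reductions the approach is
known for.  The packaged objective is therefore

$$\text{fit}(\kappa) \;=\; \frac{H(\eta_\kappa)}{\log_2 \max(k, 2)}
\;-\; \lambda\,\frac{k}{d},$$

normalized entropy minus a sparsity penalty, maximized; $\lambda = 0$
recovers the literal entropy objective.  With the default
$\lambda = 0.5$, the normalized-entropy term saturates near 1 for any
near-uniform energy subset, so the penalty dominates and selection
collapses to very small subsets on homogeneous synthetic data — the
acceptance suite measures reductions at or near 100 % under the default
conditions.  This is the objective behaving as designed, and it is why
the selection-pressure target is stated as "median reduction at least
50 %" rather than a specific output width.

**Hybrid mode** adds a wrapper term:
$w\cdot\text{acc} + (1-w)\cdot\text{fit}$, where acc is the accuracy of
a contract classifier (default: 1-nearest-neighbour) on a stratified
inner validation split (fraction 0.2, fixed by the run seed so the
objective is deterministic), with $w = 0.9$.  In entropy mode the
selector never sees labels — it is a pure filter; hybrid mode is the
labelled extension.

A caveat the test suite quantifies honestly: on easily separable data
the inner-validation accuracy saturates at 1.0 once a handful of
informative columns are selected, after which the entropy/sparsity term
drives further shrinkage that expels informative columns.
Consequently, *recall* of the full informative set is poor under the
default synthetic conditions (median around 0.15 across seeds) even
though hold-out accuracy with the selected subset stays within a few
points of the full fused matrix.  A wrapper objective rewards sufficient
subsets, not complete ones; users who need complete recovery of
correlated informative sets should not expect it from a
sparsity-seeking wrapper.

## Evaluation harness

The protocol is a stratified 70:30 hold-out: within each class,
`round(0.7 n_c)` samples train (at least one sample on each side), the
rest test; splits are seeded.  Confusion counts are taken against a
declared positive class ("malignant" by convention, the last class by
default), and the panel follows the exact identities

$$\text{FNR} = 1 - \text{sensitivity}, \qquad
  \text{FPR} = 1 - \text{specificity},$$

with zero-denominator ratios reported as `NA` with a warning, never as
0.  Published panels of this kind occasionally violate these identities
in the third decimal; ours hold to machine precision, and such
discrepancies should be read as rounding in the source.

Classifiers sit behind a `fit`/`predict` contract
(`classifier_spec()`, `fit_classifier()`).  The shipped presets mirror
the standard panel: linear/quadratic/cubic SVMs (polynomial kernels,
`coef0 = 1`, one-vs-one, via e1071), fine/medium KNN (1 and 10
neighbours, Euclidean, via class), weighted KNN (10 neighbours,
squared-inverse distance weights, implemented here), a 30-learner
random-subspace 1-NN ensemble (subspace dimension $\lfloor d/2\rfloor$),
and AdaBoost (SAMME) over depth-limited rpart trees with an optional
per-learner random undersampling of majority classes (RUSBoost).  A
"maximum of 20 splits" per tree is mapped to the largest depth whose
full tree stays within it (depth 4, at most 15 internal splits).
Library-internal defaults we could not pin down (SVM box constraint,
exact subspace dimension) follow the adapter library and are stated
here rather than guessed.

Leakage discipline: all fitting happens on training rows only, and the
test suite includes a canary — shuffling the held-out labels, with the
partition held fixed, leaves the trained model's predictions identical.

## The synthetic generator

`generate_synthetic()` emulates fused deep-feature statistics with a
known ground truth.  Defaults are the study conditions at one tenth of
the full feature widths:

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 200 | the 160/40 benign/malignant balance of the smallest benchmark dataset |
| `class_proportions` | 0.8 / 0.2 | as above |
| `block_widths` | 2, 154, 102, 190 | full widths (2, 1536, 1026, 1920) scaled ×0.1 so full-pipeline tests run in seconds |
| `n_informative` | 0, 7, 5, 8 (= 20) | a small informative core, none in the 2-wide head block |
| `n_redundant` | 0, 14, 10, 16 (= 40) | twice the informative count, emulating fusion-induced redundancy |
| `effect_size` | 2 | class means one within-class SD either side of zero: individually weak, jointly strong columns |
| `redundancy_noise_sd` | 0.1 | redundant columns correlate ≥ 0.8 with their generating combination |

Informative columns are class-conditional Gaussians (means
$\pm\delta/2$, unit SD); redundant columns are random 1–3-parent linear
combinations of informative columns plus noise; everything else is
standard Gaussian noise; column roles are scattered within blocks.  The
generator is a pure function of its spec, including the seed.

What it does **not** emulate: rectified/sparse activation distributions,
heavy tails, block-level correlation structure, or label noise — all
properties of real CNN features.  Passing tests therefore demonstrate
that the algorithms behave as specified on controlled inputs, not that
any particular accuracy will be achieved on dermoscopy images; the
published headline accuracies require the original images and
pretrained weights and are out of scope here.

`oracle_separability()` gives an upper reference for recovery tests: a
Gaussian nearest-centroid rule with class-prior correction
(discriminant $-\lVert x-\mu_c\rVert^2/2 + \log\pi_c$) on the truly
informative columns.  The prior term makes the zero-effect-size case
approach the majority-class rate rather than 0.5.

## Numerical choices and degenerate inputs

* Reduction percentages round half away from zero (base `round()`
  banker's rounding would miss printed reference values).
* CSV round-trips use 17 significant digits, which reproduces IEEE
  doubles bit-exactly; the columnar-binary format (Feather) is
  bit-exact by construction.
* All-zero energies fall back to the uniform distribution;
  $0\log_2 0 = 0$.
* Empty masks are repaired to the largest-coordinate singleton, ties to
  the lowest index.
* Stratified splits guarantee at least one train and one test sample
  per class; classes with fewer than two samples are an error.
* Objectives returning non-finite values abort with the offending wolf
  index; nothing is silently clamped.

## Problem sizes used by the test and acceptance suites

The suites run the full default synthetic conditions (200 samples, 448
fused columns, 30 wolves, 100 iterations, seeds 1–5) for the selection
criteria, the 500-column variant (20 informative + 480 noise) for
hybrid-mode recovery, and 10-seed, 300-iteration benchmark runs for the
optimizer — sizes chosen so the entire suite completes in about a
minute while exercising every code path at the stated study conditions.

## Known limitations

* The selector's entropy objective is intentionally literal to its
  source; as analysed above it is a compression objective, not a
  recovery objective.
* Only serial (concatenation) fusion is provided; no CCA or weighted
  fusion.
* The hold-out protocol is a single stratified split per seed; k-fold
  rotation is a non-goal.
* Binary confusion accounting treats multi-class problems as
  positive-vs-rest.
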