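---
title: "Multimodal feature selection and classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multimodal feature selection and classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmfs)
```

## The problem

Subjects on the healthy-control / mild-cognitive-impairment / Alzheimer's
(HC < MCI < AD) diagnostic spectrum are described by four feature
modalities: regional gray-matter volumes from MRI (93 features), regional
FDG-PET intensities (93), three CSF protein concentrations (A&beta;42,
t-tau, p-tau), and SNP genotypes coded as minor-allele counts in
{0, 1, 2}.  The genetic block is wide (thousands of markers before
screening) and individually weak; the imaging blocks are strong but
partially redundant.  The package asks the practical question behind
multimodal studies: *which modalities, and which features within them,
carry the signal, and how much does each modality add to a classifier?*

The analysis framework is deliberately simple and fully pipelined:

1. unsupervised screening of the SNP block to a manageable width,
2. train-fitted normalization of every block,
3. a feature-selection learner that produces a per-feature weight vector,
4. element-wise multiplication of the features by those weights,
5. a linear SVM on the weighted features (one-vs-rest with argmax for the
   three-class task),
6. stratified 10-fold cross-validation with grid search, reporting
   accuracy, sensitivity and specificity as mean &plusmn; standard
   deviation.

## Unsupervised screening scores

Two scores rank features without looking at labels; both are exposed with
the selector convention of features in rows (`d x N`).

**Laplacian score.**  With the dense heat-kernel similarity
`W_ij = exp(-||x_i - x_j||^2 / sigma)` over all sample pairs, degree
matrix `D` and Laplacian `L = D - W`, a feature row `X_k` scores
`s(k) = X_k L X_k' / (X_k D X_k')`.  The graph is deliberately the full
all-pairs kernel — with at most a few hundred subjects there is no need
for kNN sparsification.  Two numerical points: the numerator is evaluated
through the identity `X_k L X_k' = 1/2 sum_ij W_ij (X_ki - X_kj)^2`, so
constant features score an exact zero rather than accumulated rounding
noise; and zero-denominator features are defined to score 0.  The
formulation scores the raw feature row; the degree-centered variant of the
original locality-preserving proposal is available behind
`centered = TRUE` for users who want it.  `sigma` (unitless, default 1 on
normalized features) is the one tunable; the score is known to be
sensitive to it, which is the stated motivation for the second score.

**Local/global-discriminative (LGD) score.**  The ratio of the global sum
of squares of a feature to the accumulated local sum of squares of its
value neighborhoods: for each sample, the `m` values nearest to it (self
included) contribute their squared deviations about their own mean.  The
neighborhood size `m` is not pinned down by the score's definition, so it
is an explicit parameter with default 5 — small enough to be genuinely
local at cohort sizes of one to a few hundred, large enough that a
neighborhood mean is meaningful.  Distance ties are broken by ascending
sample index, making the score fully deterministic.  The denominator
carries a `+ epsilon` guard (default `1e-8`, as everywhere a small
positive constant is needed) so that locally constant features produce
large finite scores rather than infinities; this keeps rankings sortable.

Rankings are descending by score with ties broken by ascending feature
index.  The SNP screen keeps the top 189 features (`snp_screen_k`),
matching the block width to the combined imaging/CSF width so neither
source dominates by dimension alone.

## The three learners

All three produce a per-feature weight vector used for the element-wise
weighting stage; they differ in the loss and in the structure of the
sparsity they induce.

### Multiple kernel learning (`mkl_fit`)

The simplex-constrained MKL objective

$$\min_{\beta \ge 0,\ \|\beta\|_1 \le 1}\ \min_{w, b}\
  \sum_m \frac{\|w_m\|^2}{2\beta_m}
  + C \sum_i \max\{0,\ 1 - y_i(\textstyle\sum_m w_m^\top x_i^{(m)} + b)\}$$

with one **linear kernel per feature** by default.  The granularity is a
design choice: per-feature kernels make the learned `beta` a per-feature
weight profile directly comparable to the other learners' outputs (and to
weight-profile figures over the concatenated 93+93+3+189 layout); a
per-modality grouping (`M = 4`) is available through `groups` for users
who want modality-level kernel weights.  The solver alternates two exact
steps: the weighted-kernel SVM (a linear SVM on features scaled by
`sqrt(beta_m)`, solved by libsvm and then refined by an exact active-set
KKT re-solve) and the closed-form simplex update
`beta_m = ||w_m|| / sum_k ||w_k||`.  Both steps are exact minimizations,
so the objective trace is non-increasing; iteration stops on a small
objective decrease, a stabilized `beta` (`beta_tol`, default `1e-3` of a
weight), or `max_iter`.  The `l1`-constrained kernel weights make MKL a
*winner-take-all* selector: among strongly correlated informative
features it will concentrate weight on a subset, which is visible in the
test suite (redundant planted features shared across modalities are not
all retained) and is a property of the method, not of the solver.

### High-order graph-matching feature selection (`hgmfs_fit`)

A multi-target LASSO augmented with two geometric-consistency penalties
comparing predicted vectors `W'x_i` with targets `y_i`:

* pairwise: `B = sum_ij ||(y_i - y_j) - W'(x_i - x_j)||^2`,
* triplet: `T = sum_ijk ((y_i - y_j)'(y_j - y_k) -
  (x_i - x_j)' W W' (x_j - x_k))^2`,

minimized as `||W'X - Y||_F^2 + lambda1 ||W||_1 + lambda2 B + lambda3 T`.
`||W||_1` is the entrywise sum of absolute values — the standard LASSO
extension to a coefficient matrix.  The sum in `T` runs over **all**
ordered triples, including degenerate ones with repeated indices: their
summands are well defined, the convention is applied identically in the
implementation and in the brute-force oracles, and at `N^3` scale their
relative contribution is negligible.

Two implementation facts matter for practical use.  First, `B` collapses
to `2N ||R H||_F^2` for the column-centered residual `R H`, and `T` has an
exact `O(N^2)` closed form obtained by expanding the square of
`E_ij + E_jk - E_ik - E_jj` for `E = Y'Y - X'WW'X`; both identities are
verified against explicit loops in the tests, and they are what makes the
triplet penalty affordable at cohort size (the naive loop is `O(N^3)`).
Second, `T` is quartic in `W`, so the full objective is nonconvex; the
solver is an accelerated proximal-gradient scheme with backtracking and a
monotone safeguard (an accelerated candidate that would increase the
objective is replaced by a plain proximal step, which the backtracking
majorization guarantees to descend).  `W` starts at 0.  With
`lambda2 = lambda3 = 0` the fit agrees with coordinate-descent LASSO
solutions to the stated `1e-4`; with the nonconvex term active the
contract is value-competitiveness against multi-start descent, checked on
small instances.  Features are "selected" when any coefficient magnitude
exceeds `select_tol` (default `1e-6` — "non-zero coefficient" needs a
numerical meaning); per-feature weights are row-wise `l2` norms of `W`.

### Sparse multimodal learning (`smml_fit`)

A multiclass hinge model over the blocked coefficient matrix
`W = [w_p^q]` (modality `q`, class `p`):

$$\min_W\ \sum_i \sum_p \bigl(1 - y_{pi}\, w_p^\top x_i\bigr)_+
 \;+\; \gamma_1 \sum_p \sum_q \|w_p^q\|_2
 \;+\; \gamma_2 \|W\|_{2,1}.$$

The first penalty works group-wise — whole (modality, class) blocks can
be switched off — while the second works feature-wise, keeping or
dropping a feature jointly across all classes.  There is no bias term
(none appears in the formulation's parameter set); a constant feature
emulates one when needed.  The objective is convex but triply nonsmooth,
so the solver is consensus ADMM with three auxiliary copies: the score
matrix (elementwise hinge prox), a block-penalized copy (group
soft-threshold) and a row-penalized copy (row soft-threshold); the `W`
update is a cached Cholesky solve.  ADMM iterates oscillate in the primal
objective, so the solver tracks the *incumbent* — the best iterate seen —
and reports that: the returned `W` and the recorded trace are monotone by
construction, and the final value is verified in the tests against an
independent smoothed-objective BFGS continuation oracle to `1e-4` on
batches of random instances.  The hinge summed with uniform weight across
classes and the (modality &times; class) granularity of the first penalty
are the reconstruction choices for this objective; both are stated here
precisely because alternatives (class-weighted hinge; modality-row
groups) exist and are *not* silently mixed in.

## The classification protocol

`run_cv` implements the evaluation contract end to end.  Within every
training fold — and using training rows only — the SNP block is screened
by LGD score, continuous blocks are z-scored (population `1/N` standard
deviation, exactly as the normalization formula is written, not `N-1`),
the SNP block is min-max scaled, and the concatenated matrix is scaled to
the training unit ball per feature.  Test rows reuse the fitted statistics
verbatim; under min-max they may leave `[0, 1]`, which is correct
behavior, and the leakage test verifies bitwise that deleting test rows
changes no fitted statistic.  The selector then produces weights, features
are multiplied by them, and a linear SVM (cost `C`) is trained on the
weighted features.  Binary tasks use the first-named group as the positive
class; the multiclass task trains three one-vs-rest SVMs and predicts the
argmax decision value, with exact ties resolved by the fixed class order
HC < MCI < AD.  For multiclass MKL a single weight profile is shared
across the three one-vs-rest scorers (the average of the three fits'
profiles), mirroring kernel weights common to all tasks.

Folding is stratified: subjects are permuted within class under the run
seed and dealt round-robin, so per-fold class counts deviate from balance
by at most one.  Stratification is a package choice — at 50–100 subjects
per class, unstratified folds can easily lose a class from a fold
entirely.  Grid search evaluates every cell on the same fold partition
and reports the best mean accuracy ("best performance reported").  That
estimate is optimistically biased; `nested = TRUE` provides the unbiased
alternative where each outer fold chooses its cell on an inner split, and
the non-nested mode remains the default because it is the protocol being
mirrored.  Ties between cells resolve to the first cell in grid order,
which makes results reproducible to the byte under a fixed seed.

The default grids (`default_grid`) span `C` over `10^-3..10^3` and the
selector penalties over `10^-4..10^1` in the `"full"` profile.  The
`"quick"` profile fixes the SVM cost at 1 and varies each selector
penalty over two values (the baseline, whose only parameter is `C`,
varies it over three).  The quick grids are what the package's own tests
and the acceptance script use; with them the default single-configuration
experiment across all methods and tasks runs in minutes on one CPU, and
the full nine-configuration preset (`full_sweep_config()`) in
proportionally longer.  Every reported number states the grid it came
from.

## The synthetic cohort generator

`generate_multimodal` emulates the statistical skeleton the analysis
assumes, not real biology.  Class signal is *ordinal*: an informative
feature's mean moves linearly with class index 0, 1, 2 along
HC &rarr; MCI &rarr; AD, so the extreme pair is twice as separated as
adjacent pairs — reproducing the qualitative difficulty ordering (AD vs
HC easy, AD vs MCI hard) that disease-progression cohorts show.
Continuous features are Gaussian with standardized shift
`effect_size * noise_sd` per class step.  SNP genotypes are
`Binomial(2, p)` with the per-SNP allele frequency drawn uniformly from
`snp_maf_range` and shifted *on the logit scale* by class index times
effect size for informative SNPs — the logit parameterization keeps
genotypes valid probabilities for any effect size.  A single master seed
derives independent per-modality substreams, so the same spec and seed
reproduce the dataset bit for bit while modalities stay independently
drawn.

Default shape: 47/93/49 subjects (HC/MCI/AD), 93+93+3+189 features, 10
informative MRI, 10 PET, 2 CSF and 10 SNP features, effect sizes 0.8,
1.0, 0.7 and 0.3 per class step.  The effects encode the modality
ordering such cohorts exhibit — PET strongest, MRI close, CSF useful,
SNP individually weak — and are deliberately moderate so that binary
tasks are good but not saturated.  What the generator does **not**
emulate: linkage disequilibrium between SNPs (draws are independent),
spatial correlation between imaging regions, missing genotypes, site or
batch effects, and any nonlinearity in the class signal.  Passing tests
therefore certify the pipeline's correctness and its behavior under the
stated generative model; they do not certify performance on real cohort
data, whose class-conditional distributions the generator makes no claim
to match.

## Numerical choices, in one place

* `epsilon = 1e-8` in every guarded denominator (normalizers, LGD).
* Population (`1/N`) standard deviation in the z-score, following the
  written formula.
* Score ties broken by ascending feature index; fold ties and grid ties
  broken by first occurrence; multiclass score ties broken by class
  order.  Everything that could be arbitrary is deterministic.
* `select_tol = 1e-6` defines "non-zero" coefficients for all selectors.
* The inner SVM is libsvm plus an exact active-set KKT refinement; the
  refinement is what lets objective values be compared to independent QP
  solutions at `1e-6` rather than libsvm's termination-tolerance scale.
* HGM-FS backtracking doubles the local curvature estimate until the
  majorization holds and lets it decay by half per iteration; divergence
  is structurally impossible (a failed line search ends the iteration).
* SMML ADMM uses `rho = 1` on unit-ball-normalized features and stops
  after 50 iterations without incumbent improvement beyond `tol`.
* The triplet term switches nothing at runtime: the `O(N^2)` closed form
  is exact at every `N` and is used throughout, with the `O(N^3)` loop
  kept in the test oracles.

## Problem sizes used by the tests

The test suite exercises oracle equivalences at `d <= 10`, `N <= 30`
(scores) and `N <= 8` (triplet loops), solver optimality on batches of
instances with a dozen samples and up to six features, and protocol
properties on synthetic cohorts of 36–600 subjects with tens to hundreds
of features.  The acceptance script runs the full default-shape cohort
(189 subjects, 378 features) through all four methods and tasks with the
small documented grids.  These sizes are the package's own choice of a
thorough-but-interactive regime; the implementations themselves scale to
the full study geometry (the closed-form triplet term and cached ADMM
factorizations exist precisely for that).

## Known limitations

* The grid-search estimate in the default non-nested mode is
  optimistically biased; use `nested = TRUE` for honest generalization
  estimates.
* MKL's simplex constraint under-selects within groups of strongly
  correlated informative features (winner-take-all); its recovery
  guarantees hold per feature block, not across redundant concatenations.
* With SNP screening active (`snp_screen_k` below the block width), the
  screened feature set can differ between folds; averaged weight vectors
  are aligned by position in the processed design matrix.
* The HGM-FS objective with `lambda3 > 0` is nonconvex: the solver
  guarantees monotone descent and value-competitiveness against
  multi-start baselines, not a global optimum.
* The experiment runner's summary tables report the protocol's
  "best-cell" performance; they are method-comparison numbers, not
  clinical performance claims.
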