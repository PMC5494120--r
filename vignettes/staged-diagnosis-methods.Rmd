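---
title: "Methods: staged dementia classification from morphometric features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: staged dementia classification from morphometric features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admorph)
```

## The problem

Structural MRI morphometry summarizes a brain scan as a table of regional
measurements — here, grey-matter volumes of named structures (hippocampus,
amygdala, cortical parcels), in mm^3^, typically produced by FreeSurfer's
segmentation pipeline. Staged dementia diagnosis asks a classifier to
assign each subject to one of three ordered classes — normal control (NC),
mild cognitive impairment (MCI), Alzheimer's disease (AD) — from a few
dozen such features measured on a few hundred subjects. Two statistical
difficulties dominate: the feature count is large relative to the cohort,
and the MCI class overlaps both neighbours. `admorph` implements a
complete, seeded pipeline for this setting: PCA feature selection, four
classifier families, three cross-validation protocols, and permutation
testing of the cross-validated accuracy.

## Pipeline and models

### PCA feature selection

Each training fold is centred, scaled to unit variance (on by default —
regional volumes span very different scales; it can be disabled), and
reduced to its top *k* principal components. Every component is a linear
combination of the original features; the first covers the maximum
variance and each subsequent one the maximum residual variance. The
component count is either fixed (default *k* = 10) or chosen by an inner
stratified cross-validation over the grid {2, 4, …, 20}, maximizing the
inner accuracy of the same classifier that will consume the scores, with
ties broken toward the smaller *k*. PCA is always refit inside the
training fold (outer or inner) that uses it, so held-out rows never touch
the fitted means, scales or loadings. Component signs are fixed
(largest-magnitude loading positive) so results do not depend on the
linear-algebra backend.

### Kernel logistic regression and the import vector machine

Multinomial logistic regression is lifted to a nonlinear model by an RBF
kernel $k(x, x') = \exp(-\gamma\|x - x'\|^2)$. With reference set $R$ and
softmax link (last class pinned at zero for identifiability), the fit
minimizes the convex regularized negative log-likelihood

$$Q(w) = -\sum_i \log P(y_i \mid x_i; w) +
  \frac{\lambda}{2}\sum_c w_c^\top K_{RR}\, w_c,$$

with the Gram-matrix penalty standard for kernel logistic regression (an
identity penalty is available for comparison) and an unpenalized bias.
Minimization is damped Newton–Raphson from the zero start: Cholesky solve
of the blocked Hessian with escalating jitter if the factorization fails,
then objective-decrease line search. Convergence is declared at max-abs
gradient ≤ `tol` (default 1e-6); non-convergence within `max_iter` is an
error carrying the last gradient norm.

The import vector machine (IVM) makes the model sparse: starting from the
empty reference set, each greedy step adds the training point whose
inclusion (weights refit on the enlarged subset) most decreases $Q$, and
stops when the relative change $|Q_t - Q_{t-\Delta t}|/|Q_t|$ drops below
$\varepsilon$ (defaults $\varepsilon = 10^{-3}$, $\Delta t = 1$), when
all points are included, or at the import cap. Because the accepted model
is always refit to convergence and the previous optimum is feasible for
the enlarged set, the objective trace is non-increasing by construction.

Scoring every candidate with a full refit is cubic in practice; the
default scores candidates with a bounded number of warm-started Newton
steps (`greedy_iter`), with `exact_refit = TRUE` available where exact
greedy behaviour is wanted (the test suite's brute-force comparisons use
it). At pipeline level (`cross_validate`) the IVM additionally caps the
import set at 30 and scores a seeded random subset of 64 candidates per
step: on ~190-point training folds this cuts one 10-fold evaluation from
minutes to seconds while leaving the two-blob sparsity behaviour and the
separability results intact. These are design defaults of this package;
`fit_ivm` called directly scores all candidates (two Newton steps each)
with a cap of min(50, n).

The ridge strength defaults to a fixed $\lambda = 0.01$; `lambda = "cv"`
switches on an inner 3-fold selection over $10^{-3}\ldots10^{1}$. A fixed
default was chosen because an always-on inner search multiplies the cost
of every greedy IVM evaluation roughly five-fold for little gain on
standardized PCA scores. The RBF width defaults to
$\gamma = 1/(d \cdot \overline{\mathrm{Var}})$, the usual
scale-heuristic.

### Extreme learning machines

An ELM is a single-hidden-layer network whose hidden parameters are never
trained: input weights and biases are drawn i.i.d. Uniform(−1, 1) as a
pure function of `(d, L, seed)`, the hidden matrix is
$H_{ji} = g(w_i \cdot x_j + b_i)$ (sigmoid default; tanh, relu
available), and the output weights solve a linear problem against one-hot
targets in {0, 1}:

* plain ELM: $\beta = H^{+}T$ (minimum-norm least squares via SVD
  pseudoinverse);
* regularized ELM (RELM):
  $\beta = (I/C + H^\top H)^{-1} H^\top T$, solved by Cholesky
  factorization of the SPD system rather than explicit inversion — the
  result is contract-identical, the conditioning better.

$C \to \infty$ recovers the plain ELM; $C \to 0$ shrinks $\beta$ to zero.
Hidden width defaults to $L = \min(1000,\, 10N)$.

The hybrid variant gates each test row on prediction reliability, defined
as the top-1 minus top-2 score margin: reliable rows keep the (R)ELM
argmax; unreliable rows are re-classified by sparse representation over
the retained training dictionary — greedy orthogonal matching pursuit
(≤ `n_nonzero` atoms, default 10, atoms and query ℓ2-normalized), then
the class whose atoms' partial reconstruction leaves the smallest
residual. A margin gate was chosen because "use the fallback when the ELM
is wrong" is not operational at test time (true labels are unknown); the
margin is the standard observable surrogate. The gate threshold defaults
to 0, i.e. the pure (R)ELM pipeline, making the hybrid strictly opt-in
(`relm-hybrid` uses 0.1).

### SVM baseline

The baseline delegates to libsvm (`e1071`), linear or RBF. Multiclass
prediction is a one-versus-all reduction written here — one binary
machine per class, argmax of decision values — to match the OVA
evaluation convention, since libsvm's native multiclass is one-vs-one.

### Evaluation and significance

Confusion matrices are accumulated per fold (rows true, columns
predicted). Binary folds report ACC, SEN = TP/(TP+FN),
SPE = TN/(TN+FP); three-class folds report trace accuracy plus macro
(unweighted) one-versus-all sensitivity/specificity. Three protocols are
provided: stratified 70/30 splits repeated 100×, stratified 10-fold
repeated 10×, and leave-one-out (repetition re-seeds randomized
classifiers; LOO emits one record per held-out subject, with aggregates
from the pooled per-repeat confusion). All fitting — PCA, any grid or
$\lambda$ search, the classifier — is confined to training folds.

Significance of a cross-validated accuracy uses permutation testing: the
identical CV procedure is re-run on cohorts whose diagnostic labels have
been uniformly permuted (values untouched, label multiset conserved),
giving the null distribution of the statistic. The p-value uses the
add-one estimator $p = (1 + \#\{\text{null} \ge \text{obs}\})/(1 + B)$,
which cannot return 0.

## The synthetic cohort generator

No clinical data ship with the package; the generator produces cohorts
with the statistical structure the pipeline assumes. Defaults: 70 NC /
74 MCI / 70 AD subjects; 54 volume features of which 12 are
disease-sensitive; healthy baseline 5000 mm^3^ with within-class SD
500 mm^3^ (a 10% coefficient of variation, typical of subcortical
volumes). An affected feature's class mean drops by
`effect × noise_sd` per disease stage (NC = 0, MCI = 1, AD = 2),
encoding monotone staged atrophy NC > MCI > AD; `effect` is therefore a
standardized effect size, with 0 a true null and 3 a near-separable
cohort. Noise is Gaussian with optional non-negative equicorrelation
$\rho$, realized exactly by the one-factor construction
$x = \sqrt{1-\rho}\,e + \sqrt{\rho}\,g$. Cohorts are bit-reproducible
from the spec's seed.

What this emulates — and what it does not: real FreeSurfer volumes are
right-skewed, heteroscedastic across structures, corrupted by
segmentation error, and correlated in blocks rather than uniformly; MCI
is clinically heterogeneous rather than a clean intermediate shift.
Passing tests on these cohorts therefore demonstrate correctness of the
algorithms and protocols — not expected accuracy on clinical data.
Because no public effect sizes exist for the regional volumes this
package targets, the effect magnitudes are free parameters chosen once
(null at 0; strong separation at 3 SD per stage), not calibrations to
any cohort.

## Numerical choices and degenerate inputs

* KLR Newton: zero start (convexity makes the optimum unique in value);
  Cholesky with escalating jitter, then halving line search; gradient
  tolerance 1e-6.
* PCA: SVD of the centred/scaled matrix; `k ≤ min(n−1, d)` enforced;
  zero-variance columns are an error when standardizing.
* RELM: SPD Cholesky solve; pseudoinverse tolerance
  `max(dim) · eps · max(singular value)`.
* Matching pursuit stops early when the residual norm falls below 1e-10;
  ties in atom correlation and in class residuals resolve to the lowest
  index / earliest class.
* All argmax label decisions break ties toward the earlier class in the
  declared order, making every predictor deterministic.
* Missing values are rejected at load time (the loader names the first
  offending cell); features with zero variance only matter under
  standardization, where they are named in the error.
* Empty test folds (possible when 10-fold is asked of very small
  cohorts) are skipped rather than scored.
* Every random quantity — cohorts, folds, hidden layers, candidate
  subsets, permutations — is a pure function of a seed derived from one
  master seed by a fixed integer recurrence, so identical configurations
  give byte-identical JSON reports.

## Problem sizes used by the shipped checks

The test-suite and acceptance-script experiments run at the sizes the
package documents as its reference conditions: the default 214-subject,
54-feature cohort for classifier-recovery and protocol checks (strong
atrophy at effect 3, nulls at effect 0 over 20 seeds); a reduced
60-subject cohort with 200 permutations × 50 runs for permutation
calibration; small random instances (n ≤ 30, d ≤ 5) for the
oracle-equivalence checks against independent optimizers and
decompositions.

## Known limitations

* The IVM pipeline defaults trade exact greedy selection for speed (see
  above); `exact_refit` restores the exact behaviour at cubic cost.
* Plain 70/30 splits are reported by the evaluation engine but are known
  to be high-variance on cohorts of this size; the 10-fold and LOO
  protocols are the ones the package's own checks rely on.
* The sparse-representation fallback uses greedy pursuit, not ℓ1
  minimization; for the small dictionaries of this setting the two
  rarely disagree, and the brute-force support-enumeration tests pin the
  intended behaviour.
* No ROC/AUC, calibration analysis, kernel ELM, or online variants.
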