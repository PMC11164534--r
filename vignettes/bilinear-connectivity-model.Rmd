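---
title: "The bilinear connectivity model: methods and design choices"
author: "biconn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The bilinear connectivity model: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(biconn)
```

## The problem

Which genes determine whether two neuronal types form synapses? Single-cell
transcriptomics delivers expression profiles of neuronal types; connectomics
delivers a matrix of how strongly those types connect. `biconn` links the two
with a bilinear latent-factor model borrowed from collaborative filtering:
presynaptic neurons play the role of users, postsynaptic neurons of items,
and connectivity of ratings. The predicted connectivity between presynaptic
cell $i$ and postsynaptic cell $j$ is the inner product of their linearly
transformed expression features,

$$\hat z_{ij} = (x_i A)(y_j B)^\top,$$

with $A \in \mathbb{R}^{p \times d}$ and $B \in \mathbb{R}^{q \times d}$
projecting the two sides into a shared latent space of dimension $d$. Each
latent dimension is a connectivity motif; the product $\hat O = AB^\top$ is a
low-rank gene–gene interaction ("rule") matrix, directly comparable with the
full-rank rule matrix of the spatial connectome model (SCM) baseline, which
predicts $XOX^\top$ by ridge regression over physically contacting pairs.

## Two data regimes

**Cell level.** When expression and connectivity are known for the same
cells (e.g. gap-junction connectivity with innexin expression), the loss is

$$L(A,B) = \lVert W \odot (Z - XA(YB)^\top)\rVert_F^2
  + \tfrac{\lambda_A}{2}\lVert A\rVert_F^2
  + \tfrac{\lambda_B}{2}\lVert B\rVert_F^2 .$$

The weight matrix $W$ either carries a binary physical-contact mask (pairs
without contact never enter the fit) or the type-balancing weights
$1/(n_i n_j)$ so that abundant types do not dominate rare ones
(`weight_matrix()`). Because the weights sit inside the squared Frobenius
norm, the exact gradient carries $W \odot W$; for binary masks the two are
identical. We implement the exact derivative throughout so that analytic
gradients agree with finite differences to machine precision — that
agreement is asserted in the test suite, and any inexact shortcut would
fail it.

**Type level.** Usually expression and connectivity come from different
sources and can only be aligned at the level of neuronal types. The model
then approximates every cell by its type average, fits the type-mean
matrices, and controls the within-type variance of the latent features.
After approximating the within-type covariance by its diagonal, this
constraint turns into dividing each type-mean feature by the pooled
within-type standard deviation of that feature
(`typewise_stats()` + `normalize_type_matrix()`), and into Gram-matrix
penalties on the factors:

$$L(\hat A,\hat B) = \lVert \bar Z - \hat X\hat A(\hat Y\hat B)^\top\rVert_F^2
  + \tfrac{\lambda_A}{2}\lVert \hat A^\top\hat A\rVert_F^2
  + \tfrac{\lambda_B}{2}\lVert \hat B^\top\hat B\rVert_F^2 .$$

The $\epsilon$-constrained formulation behind this penalty is implemented
only through this Lagrangian surrogate; $\epsilon$ is never a runtime
parameter. The pooled within-type variance uses the population divisor
$1/n_i$ and sums each type's contribution, so singleton types contribute
zero; features with zero pooled sd are divided by `sd_floor` (default
`1e-8`) instead. The two penalty strengths are consolidated into a single
`lambda` knob by default, with `lambda_A`/`lambda_B` as the escape hatch,
because equal values worked best in practice.

A note on the type-level gradients: the two printed update rules one would
naively write down for this loss are dimensionally inconsistent unless the
residual is transposed in the $\hat B$ update, and the exact derivative of
the Gram penalty is $2\lambda \hat A(\hat A^\top\hat A)$, twice the
"obvious" term. `bilinear_grad()` implements the exact derivatives of the
stated loss — the finite-difference property tests pin this down.

## Optimization

`bilm()` minimizes either loss by alternating gradient descent: factors are
initialized with standard-normal draws under `seed`, each iteration forms
the prediction once, computes both gradients from it, and updates $A$
before $B$. Iteration stops when the absolute loss change falls below
`tol` (default `1e-6`) or at `max_iter` (default `1e6`); a non-finite loss
aborts with an error suggesting a smaller rate. A fit is a pure function of
its data and arguments, and never perturbs the session RNG.

Two step-size rules are provided:

* `step = "fixed"` is the plain constant-rate loop. Its trajectory is
  monotone whenever the rate is below the local stability limit.
* `step = "bb"` (default) keeps the same gradient directions but sets the
  magnitude by the Barzilai–Borwein spectral formula
  $r_t = \langle s,s\rangle/\langle s,y\rangle$ (with $s$, $y$ the joint
  parameter and gradient differences), safeguarded by the standard
  nonmonotone rule: a trial step whose loss exceeds the maximum of the
  last 20 losses is halved until accepted.

The spectral default exists because the variance normalization makes the
type-mean matrices badly scaled (dividing by pooled sds of order
$10^{-1}$ inflates feature columns by a factor of 4–6 here), and the
resulting curvature spread makes a constant rate impractically slow: on
the package's default synthetic scenario a fixed-rate fit is still far
from the optimum after $10^6$ iterations, while the spectral step
converges in $10^4$–$10^5$. Both rules are first-order, deterministic,
and judged by the same stopping criterion.

## Building connectivity matrices

For laminar circuits (retinal bipolar → ganglion cells) the connectivity
proxy between two cells is the cosine similarity of their stratification
profiles — the linear density of voxel volume as a function of
inner-plexiform-layer depth (`build_cell_connectivity()`). Profiles are
parsed from museum-style JSON records and linearly interpolated onto a
common grid of 120 evenly spaced points on normalized depth $[0, 1]$
(`ipl_depth_grid()`); the grid length is a reporting-resolution choice,
not a tuning parameter, and records without a stratification entry are
skipped with a warning.

The pipeline then **standardizes the cell-level matrix** (entrywise mean 0,
population sd 1, so both positive and negative values occur) **and then
averages by type** to obtain $\bar Z$. Standardize-then-average and
average-then-standardize differ in general; the package fixes the former
as the default order (the standardization is defined on the cell-level
cosine matrix) and the two steps are exposed separately
(`standardize_connectivity()`, `average_by_type()`) so the other order is
one line away. ON/OFF starburst-amacrine laminae and the outer/inner
boundary are kept only as reporting landmarks and never enter any
computation.

## Preprocessing transcriptomes

`normalize_counts()` rescales each cell to the median total count and
applies $\log(1+x)$ (the paper-standard choice for zero-inflated counts
where plain log is undefined at zero). `select_hvgs()` concretizes
mean–variance-based gene selection as a regression of $\log \mathrm{CV}^2$
on $\log$ mean with a standardized-residual threshold (default $z = 1$);
genes with zero mean or variance can never be selected. `pca_reduce()`
centers, rotates, and keeps the smallest number of components reaching a
cumulative 95% explained variance. When two neuronal classes are
processed (e.g. BCs and RGCs), each class gets its own pipeline instance —
they live in different feature spaces by construction. Type names across
sources are aligned by an explicit two-column table (`align_types()`);
fuzzy name matching is deliberately not attempted.

## Model selection and evaluation

`cv_bilm()` runs $k$-fold (default five-fold) cross-validation over a grid
of $(\lambda, d)$. The fold unit is the observed connectivity entry:
entries with positive weight are shuffled under a seed and partitioned;
training masks the held-out entries via $W$, and validation is the
unregularized weighted data term on them. Entry-level folding keeps both
factors estimable in every fold, which row- or column-level folding would
not. Selection minimizes the mean validation loss with ties broken toward
smaller $d$, then smaller $\lambda$; a diverging grid point contributes an
infinite loss rather than aborting the search. `cv_scm()` applies the same
harness to the SCM's ridge strength, for parity in comparisons.

`roc_auc()` evaluates reconstructions of binary connectomes by the
rank-based AUC (ties count half) over contact pairs by default, since the
model is fit only on those; `matrix_pearson()` handles continuous targets.
`discrepancy_score()` compares rule matrices entrywise with
$DS = |\hat o - o|/(|\hat o| + |o|) \in [0,1]$, with $DS(0,0) := 0$ as the
limit of no discrepancy; `discrepancy_report()` flags entries with
$DS \ge 0.5$ unless both magnitudes fall below 0.1, because
regularization pushes unimportant coefficients toward zero where the score
is dominated by noise.

## Consistency across restarts, and its limits

`consistency_across_runs()` scores pairs of fits by the mean absolute
cosine of paired factor columns, averaged over the two sides and maximized
over column pairings (all $d!$ permutations for $d \le 4$, greedy
matching beyond), which makes the score invariant to the sign-flip and
swap indeterminacy of the factorization.

Two caveats follow from the model itself. First, the type-level loss is
invariant under any joint *rotation* of the latent columns, which the
cosine measure does not credit; observed consistency therefore reflects
the optimizer's tendency to break that symmetry the same way across
restarts, not an identifiable quantity. Second, when the feature count
exceeds the number of types, the feature matrices have nontrivial null
spaces, and coefficient components in them are determined only by how far
the penalty has shrunk them at convergence — consistency rises with
stronger regularization and tighter convergence. Predictions, by
contrast, are stable across restarts essentially exactly. The acceptance
script therefore runs restarts at the cross-validation-selected
$\lambda$ and reports both the factor-level consistency and the
prediction-level stability.

## Latent-space interpretation

`reconstruct_dimension()` isolates one latent dimension's rank-one
connectivity motif (they sum exactly to the full prediction);
`latent_coordinates()` places types in latent space, with zero coordinates
grouped into the positive half for stratification reporting.
`gene_weights()` back-projects factor columns to gene space through the
inverse preprocessing chain — PCA loadings times the $1/\hat\sigma$
scaling — because the model operates on variance-normalized PC features
while interpretation wants named genes; the top-$n$ positive and negative
weights per dimension default to 50. `predict_partners()` projects new
(e.g. transcriptionally defined) types into the trained latent space and
ranks candidate partners by predicted connectivity (default top 3); it
refuses feature spaces whose dimension does not match the trained model,
since a new type is only comparable after the identical preprocessing
chain (same HVGs, same loadings, same pooled sds). Rankings depend only on
$AB^\top$, so they are immune to the latent-basis indeterminacy.

## Synthetic data

The generators exist so that every pipeline stage can be tested against
known ground truth.

* `simulate_bilinear()` draws type-mean features $\sim N(0,1)$, cell
  features as type mean plus $N(0, \texttt{within\_type\_sd})$, true
  factors $\sim N(0,1)$, connectivity $XA^*(YB^*)^\top$ plus
  $N(0, \texttt{connectivity\_noise\_sd})$, and a Bernoulli contact mask.
  The Gaussian within-type noise mirrors the model's own approximation
  (cells ≈ type means). Defaults — 25 × 12 types, 20 cells per type,
  30 features per side, $d^{*} = 2$, both noise sds 0.05, full contact —
  mirror the retina problem's shape and mild-noise regime at desk scale.
* `simulate_counts()` draws Poisson counts with uniform per-cell library
  sizes and multiplicative type programs on a planted gene subset, giving
  highly-variable-gene selection a known answer.
* `simulate_stratification()` assigns Gaussian-bump depth profiles per
  type with per-cell jitter and emits museum-style JSON records, so the
  parser is exercised end to end; with zero jitter the bumps are exact
  and the discretized cosine matches continuous quadrature.

What the generators do not emulate: dropout curves, ambient RNA, batch
effects, doublets, or any non-bilinear connectivity rule. Passing tests
on this data demonstrates correctness of the machinery and recoverability
under the model's own assumptions — not performance on real tissue.

## Numerical choices and degenerate inputs

* Convergence is judged on the absolute loss change; `tol` defaults to
  `1e-6` with `max_iter = 1e6`.
* Divergence (non-finite loss) is an explicit error, not a silent result.
* The SCM normal equations are solved directly up to $p^2 \le 2500$
  unknowns and by conjugate gradients (tolerance `1e-10`) beyond; a
  singular system at $\lambda = 0$ produces an error directing the user
  to ridge regularization. Gap-junction rule matrices are constrained
  symmetric through symmetrized design rows, with unordered pairs counted
  once and self-pairs excluded by default.
* Zero-variance features meet `sd_floor`; zero-norm stratification
  profiles, zero-total cells, constant matrices in standardization or
  correlation, and single-class ROC truths are all hard errors naming the
  offender.
* Ties in partner rankings are broken by partner order; ties in
  cross-validation by smaller $d$, then smaller $\lambda$.

## Problem sizes in the tests

The suite and the acceptance script run entirely on generated data:
gradient checks on instances up to 10 features per side; noiseless
recovery on a 6 × 5-type, 3-cells-per-type instance; type-level recovery
on the default 25 × 12 scenario over five seeds; dimension selection on
15 × 12 single-cell-per-type instances over ten repetitions; SCM
equivalence on a 12-neuron, 4-gene consistent instance. These sizes keep
the full suite under a minute of compute while leaving every claim
testable at higher sizes by changing one scenario argument.

## Known limitations

The model is linear: it favors genes whose expression correlates directly
with connectivity and can miss regulators acting through nonlinear
combinations (the natural extension is a two-tower nonlinear encoder,
out of scope here). Stratification overlap is a proxy, not a measurement,
of synaptic strength. Factor-level interpretation inherits the rotation
indeterminacy discussed above, so per-dimension gene lists should be read
together with the per-dimension connectivity motifs, which are stable.
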