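---
title: "Eigenslope subspace projection: model, assumptions and design notes"
author: "eigenslopes package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eigenslope subspace projection: model, assumptions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Cross-sectional classifiers of neurodegenerative disease compare subjects'
images at a single time-point, where large between-subject anatomical
variation (head size, age, education-linked differences) can swamp the
subtle atrophy that separates, say, mild cognitive impairment from healthy
ageing.  Longitudinal designs measure each subject repeatedly and focus on
*within-subject change*, which is far more specific to progressive disease.
This package turns that idea into a feature-construction step usable with
any linear classifier: it estimates each subject's rate of change, finds
the low-dimensional subspace in which those rates vary across subjects,
and projects single-time-point samples onto it before classification.

## The model

Each subject $i$ with $m_i$ scans of dimensionality $D$ is modelled by an
independent polynomial regression
$$X_i = Z_i B_i,$$
where $X_i$ is the $m_i \times D$ matrix of the subject's samples, $Z_i$
the $m_i \times (P+1)$ design matrix of raw powers of time (constant
column included) and $B_i$ the $(P+1) \times D$ coefficient matrix.
`fitTrajectory()` solves this by a QR least-squares factorization — one
solve for all $D$ dimensions — rather than explicit normal equations,
because clustered scan times make $Z_i'Z_i$ ill-conditioned.

Stacking the first-order rows of all $l$ subjects in the longitudinal
training set gives the $l \times D$ slope matrix $B^{(1)}$
(`assembleCoefficientMatrix()`, the *LTC* route, any number of scans).
With exactly two scans per subject the least-squares slope reduces to the
interval-scaled difference
$$D_L = \tfrac{1}{t_\Delta}\left(X^{(t_2)} - X^{(t_1)}\right) = B^{(1)},$$
implemented directly by `lmDifferenceMatrix()` (the *LM* route), with a
per-subject interval $t_{\Delta,i}$ in the unbalanced variant.  The
equality of the two routes on balanced two-scan data is a package test.

PCA on the row-centred slope matrix yields orthonormal *eigenslopes*
$U_k$ ($D \times k$): directions of common longitudinal change.  Because
$l \ll D$, the decomposition runs through the $l \times l$ Gram matrix
(snapshot method), which is exact for the nonzero spectrum.  Given a
target explained-variance fraction `pvar`, $k$ is the smallest number of
components whose eigenvalues sum to at least that fraction of the total.

Cross-sectional samples at a chosen time-point are then projected,
$X_{\mathrm{train}} = X_N(t)\,U_kU_k'$, mean-centred with the training
means, and classified with a linear soft-margin SVC at fixed $C = 1$
through the kernel $K = XX'$.  The ambient ($D$-dimensional) output is the
default so that weight vectors remain images; the compact form $X U_k$
yields the identical kernel (orthonormality) and is what the
cross-validation driver uses internally.

Two experiment designs are supported.  *Within-set* prediction builds the
subspace from the classification cohort itself; at every
cross-validation fold the held-out subjects' longitudinal data are
excluded from the slope matrix ($L = \bar L \setminus T$), so no test
information reaches the subspace.  *Information-transferring* prediction
uses a disjoint cohort's slopes, giving one fixed subspace for all folds.

## Tuned parameter and nested cross-validation

The method's single tuned parameter is `pvar`, the explained-variance
fraction selecting $k$.  `nestedLooCv()` runs an outer leave-one-out loop
for unbiased prediction and, inside each outer fold, an inner
leave-one-out loop that evaluates every value of the grid (default 5–95%
in 5% steps) and picks the one with the highest pooled inner balanced
accuracy.  Two open choices were resolved as follows:

* the inner loop re-builds the eigenslope basis excluding *both* held-out
  subjects' longitudinal data (full nesting, no optimistic bias);
* ties in inner balanced accuracy go to the smallest `pvar` (parsimony).

Decision values of exactly zero predict the control class (conservative
toward disease calls).  The whole run is deterministic given the data and
configuration.

## Performance metrics and significance

`computeMetrics()` reports sensitivity, specificity, balanced accuracy
$(\mathrm{sens}+\mathrm{spec})/2$, PPV, NPV (undefined ratios are reported
as missing, never 0) and the ROC AUC in its midrank (Mann–Whitney) form,
with ties counted one half.  Percentages render half-up at one decimal.

`permutationTest()` shuffles the subjects' labels (class counts
preserved), re-runs a user-supplied cross-validation runner per
permutation and counts the fraction of null balanced accuracies at or
above the observed one.  The unsmoothed estimator can return exactly 0;
a `smoothed` flag switches to $(b+1)/(m+1)$.  Because a fully nested run
per permutation costs tens of seconds, the packaged `fixedPvarRunner()`
precomputes the label-independent per-fold kernels once and re-solves only
the SVC duals, making a 1000-permutation null practical on one CPU; the
significance statement then applies to the fixed-`pvar` classifier.  The
fully nested runner (`nestedCvRunner()`) remains available when the
selection step itself must be inside the null.

## Interpretation maps

`weightMap()` reconstructs the primal weights $w = \hat X' \bar\alpha$
from the signed support-vector coefficients and the centred training
features; its inner products reproduce the dual decision values to
numerical precision (a package test).  `forwardMap()` is the Haufe-style
encoding counterpart, $a \propto \mathrm{Cov}(X, \tilde y)$, computed from
the classifier's *continuous* decision values and scaled to maximum
absolute value 1, matching how such maps are usually displayed; unlike
$w$ it represents the group-difference pattern.  `tMap()` provides
mass-univariate pooled-variance two-sample $t$ statistics (pooled rather
than Welch — the simplest standard choice, stated here because either is
defensible).  All maps can be written through a binary mask to
double-precision NIfTI volumes, which round-trip exactly.

## The SVC solver

The classifier is the standard C-cost soft-margin SVC.  The package
solves the dual with a small compiled SMO (maximal-violating-pair
selection with the second-order working-set rule, stopping tolerance
$10^{-6}$) operating directly on the precomputed kernel.  This keeps a
full nested LOO-CV — roughly $n^2 \times$ grid solves — in the tens of
seconds at the default study scale.  The test suite verifies agreement of
the decision values with the LIBSVM reference implementation (e1071) to
well below the solver tolerance on random problems.

## What the synthetic generator emulates

`simulateCohort()` produces the structure the method assumes: subject
trajectories $x_i(t) = b_i + s_i t + \varepsilon$, slopes
$s_i = W(\theta_g + \eta_i)$ confined to a random rank-$r$ subspace
$W$, a between-group mean-slope difference of norm `delta` inside that
subspace, isotropic intercept dispersion over all $D$ dimensions and
i.i.d. Gaussian observation noise.  Balanced designs have $m$ scans at a
fixed interval; unbalanced designs draw $m_i$ and the gaps at random.

Defaults (chosen once, before any benchmark was run): 20 + 20 subjects,
$D = 500$, $r = 3$, `delta` = 0.6, `sigmaSlope` = 0.3, `sigmaNoise` = 0.1,
`sigmaBaseline` = 1, `baselineShift` = 0, interval 2.5 years (balanced,
$m = 2$), 2–4 scans with 0.8–3 year gaps (unbalanced).  The scales follow
a simple power argument: at follow-up the group signal has norm
$\delta\,t_\Delta = 1.5$ against per-dimension noise of roughly unit
standard deviation, so the Bayes-optimal accuracy *within* the rank-3
subspace is in the mid-70s percent — the regime the method targets —
while the unprojected problem stays near chance because the baseline
dispersion spreads over all 500 dimensions with only 40 training
subjects.  The follow-up interval and scan counts mirror typical
ageing-cohort MRI designs.

What the generator does **not** emulate: registration artefacts, spatial
autocorrelation of voxels, non-Gaussian pathology distributions,
correlated intercept/slope effects and scanner drift.  Passing tests
therefore demonstrate the statistical machinery under the model's own
assumptions, not clinical performance on real images.

## Numerical choices

* Eigenvalues below $10^{-12}$ of the largest are treated as rank loss;
  requesting more components than the rank clips with a warning.
* Eigenvector signs follow a fixed convention (largest-magnitude entry
  positive) for reproducible bases.
* The slope matrix is mean-centred before PCA by default, following the
  standard PCA procedure; a `center = FALSE` flag supports sensitivity
  analysis since uncentred decompositions are also coherent here.
* Raw (uncentred) powers of relative time form the design matrix; times
  are stored relative to each subject's first scan, which the constant
  column absorbs.
* Mask vectorization uses the mask volume's column-major array order, so
  feature indices are bit-reproducible across runs.

## Problem sizes used in the packaged checks

The simulation-based checks run at the generator defaults: 20-seed
replications for the null-calibration, projection-benefit and
LTC-versus-LM comparisons, 200-permutation nulls for significance, and a
single-cohort acceptance script.  These sizes keep each replication's
Monte-Carlo error small relative to the effects being demonstrated while
completing in minutes on a single core.

## Known limitations

* Leave-one-out CV on class-balanced cohorts is slightly pessimistic
  under the null: every outer fold trains on a split unbalanced against
  the held-out subject's class, nudging the SVC toward the majority
  label.  At the default cohort size the null balanced accuracy sits
  near 0.49 rather than exactly 0.5, with substantial per-cohort spread
  (sd ≈ 0.12); permutation tests are unaffected because their null
  shares the same bias.
* Per-subject independent fits ignore between-subject correlation of
  trajectories; mixed-effects coupling could sharpen slope estimates with
  very few scans per subject but is out of scope here.
* First-order subspaces dominate: higher-order coefficient matrices are
  supported by `assembleCoefficientMatrix(order = P, extract = p)` but
  no joint multi-order feature concatenation is provided.
* The LM routes pick a fixed scan pair (first–last or last-two); other
  pairings require calling `lmDifferenceMatrix()` directly.
* Permutation p-values with the unsmoothed estimator are granular at
  $1/m$ and can be exactly zero.
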