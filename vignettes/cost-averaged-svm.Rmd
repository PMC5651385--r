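---
title: "Bayesian cost averaging for voxel-based SVM classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bayesian cost averaging for voxel-based SVM classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svmbma)
```

## The problem

Group studies of scalar diffusion-MRI maps (mean kurtosis, fractional
anisotropy, mean diffusivity) ask whether patients can be told from controls
from voxel intensities inside a tissue- and region-restricted mask, and
*which* voxels carry that signal. With cohorts of a few dozen subjects and
thousands of voxels, a single classifier fit is fragile: the soft-margin SVM
cost parameter C is essentially unidentified on separable data, and any one
choice of C risks over- or under-fitting. svmbma implements a pipeline that
treats C honestly as a nuisance parameter: it fits 19 linear SVMs across a
data-driven grid of costs and averages them with Bayesian posterior weights,
then wraps the whole construction in repeated stratified cross-validation so
that both performance estimates and coefficient maps come with
across-partition variability.

## The model

For a training table $D$ (subjects $\times$ voxels, labels patient = 1 /
control = 0) the prediction for test subject $i$ is

$$H_i = \sum_{c} p(C = c \mid D)\; p(1 \mid C = c, D, i), \qquad
\text{patient} \iff H_i > 0.5,$$

a posterior-weighted average over 19 linear-kernel SVMs. Each member model
outputs a score $w \cdot x + b$ (patients positive) that a logistic link
converts to a patient probability; a tie at exactly 0.5 predicts control
(the rule is a strict inequality).

**Cost grid.** $C_\mu$ is the minimum cost at which the SVM fits $D$ with
zero classification errors; $C_{max}$ is the minimum cost at which the
training log-likelihood
$LL(D \mid C) = \sum_i [y_i \log p_i + (1 - y_i)\log(1 - p_i)]$
stops improving. With $\Delta = C_{max} - C_\mu$ the grid is
$\{C_\mu + \Delta i / 9 : i = -9, \dots, 9\}$ — 19 equally spaced costs
centred on $C_\mu$. Values that the linear formula drives to or below zero
(possible whenever $\Delta \ge C_\mu$) are clipped to $10^{-6} C_\mu$ and
flagged, preserving the formula elsewhere.

**Prior and posterior.** The model prior is Gaussian over the grid, mean
$C_\mu$ and standard deviation $\Delta/2$, evaluated at the *unclipped*
formula positions and normalized. Substituting the grid formula shows the
weights are the fixed pattern $w_i \propto \exp(-2(i/9)^2)$, independent of
$C_\mu$ and $\Delta$: the centre carries $\approx 0.0918$ and the point
seven steps out $\approx 0.0274$. The posterior is
$p(C \mid D) \propto e^{LL(D \mid C)}\, p(C)$, computed after shifting all
log-likelihoods by their maximum so nothing underflows; the posterior is
exactly invariant to such shifts and the evidence is reported on the
shifted scale alongside the shift. The prior's job is regularization: with
near-equal likelihoods (common on separable data) it pulls weight away from
the high-cost tail.

**Coefficients.** Because the kernels are linear, each model is a voxel
coefficient vector $\beta_{C=c}$; a run's vector is the posterior average
$\beta_R = \sum_c p(C = c \mid D)\beta_{C=c}$, an iteration's is the mean
over the $k$ CV runs, and across $N$ iterations the package reports the
mean $\beta_\mu$, the population standard deviation
$\beta_\sigma = \sqrt{\tfrac1N \sum (\beta_I - \beta_\mu)^2}$ (denominator
$N$, matching the defining formula, not $N-1$), and the strict sign counts
$\beta_+ = \#\{\beta_I > 0\}$, $\beta_- = \#\{\beta_I < 0\}$ (exact zeros
in neither). Negative coefficients mark voxels where controls have the
higher intensities.

**Cross-validation.** Stratified 5-fold CV with the cost grid recalculated
for every run's training folds; each subject is predicted exactly once per
iteration, and iteration metrics (accuracy, F1, sensitivity, specificity;
patient positive) are computed on those pooled out-of-fold predictions. The
source design does not say whether its per-iteration metrics are pooled or
fold-averaged; pooling is the standard lower-variance reading and the
pooled accuracy equals the subject-weighted mean of per-fold accuracies, a
property the tests assert. Iteration $t$ uses seed `base_seed + t`, so
experiments on different measures with the same base seed share fold
allocations exactly and can be compared pairwise per iteration.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `threshold` (`build_mask`) | 0.20 | inclusive white-matter probability cutoff |
| `cost` grid size | 19 (fixed) | models per ensemble |
| `lower_cap` (`find_c_mu`) | 1e-4 | probe floor for the minimum separating cost |
| `cap` | 1e8 | separability / plateau search ceiling |
| `n_candidates`, `span` (`find_c_max`) | 40, 1e4 | initial plateau scan: 10 candidates/decade over 4 decades |
| `tol_flat` | 1e-6·max(1, \|max LL\|) | plateau flatness tolerance |
| `k` | 5 | CV folds |
| `n_iterations` | 1000 | experimental iterations (the full design) |
| link | logistic | score-to-probability map |

## Numerical and design choices

**Logistic link.** The member SVMs output scores, not probabilities; the
link here is the plain logistic $p = 1/(1 + e^{-score})$ with no fitted
scaling, which keeps $LL(D \mid C)$ a pure, deterministic function of the
SVM fit. A Platt-scaled variant (`link = "platt"`, sigmoid fitted to the
training scores by logistic regression) is available for sensitivity
analysis, not as the default. Probabilities are clipped to
$[10^{-12}, 1 - 10^{-12}]$ so log-likelihoods stay finite.

**Finding $C_\mu$.** The error-to-zero transition is bracketed (doubling
upward from $c = 1$ when $c = 1$ still errs) and bisected in $\log_{10}$
space to 1% relative tolerance, returning the zero-error endpoint. One
regime needs care: when voxels far outnumber subjects, *any* positive cost
can separate the training set — the infimum is 0 and "the minimum
separating cost" does not exist. The search therefore probes a floor of
$10^{-4}$ first and returns it when even that separates. The floor is a
reporting convention, not a claim that $10^{-4}$ is special; everything
downstream (grid, prior, posterior) is well defined either way because the
plateau search supplies the scale.

**Finding $C_{max}$.** The log-likelihood profile is scanned upward from
$C_\mu$ at 10 log-spaced candidates per decade, smoothed with a length-3
median filter (endpoints passed through; monotone profiles are fixed
points), and the smallest candidate within `tol_flat` of the smoothed
maximum is returned. The initial window spans 4 decades; if the profile is
still rising at the top — routine when $C_\mu$ sat at the probe floor —
the window extends one decade at a time at the same density up to an
absolute ceiling of $10^8$, beyond which the search stops with an error
rather than silently returning the ceiling. For separable data the plateau
is exact (beyond the hard-margin cost the solution stops changing; the
measured profile drift there is zero with the deterministic solver), which
is why the tight flatness tolerance is safe.

**Solver.** Member SVMs are solved by the deterministic SMO implementation
in e1071/libsvm at tolerance $10^{-6}$ with shrinking disabled; the
orientation is normalized so patients score positive regardless of class
ordering. An independent check against kernlab and a brute-force KKT
enumeration oracle on tiny problems guard the hyperplane itself.

**Voxel indexing.** Feature columns are named by the 0-based *column-major*
linear index of their voxel (first grid dimension fastest — R's native
array order), recorded in `voxel_index_map()`. Coefficient maps are
reconstructed by placing values at those indices and zero elsewhere;
re-extracting with the same mask recovers the vector exactly, and the tests
assert the round trip.

**Degenerate grids.** $\Delta = 0$ (maximal fit already at $C_\mu$) makes
all 19 models identical; the prior is then uniform with a warning and the
ensemble reduces to the single model.

## The synthetic cohort generator

`generate_cohort()` emulates the feature structure the pipeline sees after
masking: 32 patients and 36 controls by default, independent Gaussian voxel
noise ($\mu_0 = 1.0$, $\sigma = 0.1$, a plausible mean-kurtosis-like scale
chosen once and documented as arbitrary), with a designated fraction of
voxels (default 10%) shifted $-d\sigma$ in patients. Patients are simulated
*lower* so that recovered coefficients should be negative at the planted
voxels — the interpretable sign convention — with a flag to flip the
direction. `generate_volume_fixtures()` embeds a cohort into NIfTI volumes
with a white-matter probability map and atlas so the masking and extraction
stages are exercised end to end; `permute_labels()` provides the
permutation null.

What the generator deliberately omits: spatial autocorrelation (an optional
effect-map smoothing exists but is off, since the classifier is voxel-wise
linear), registration error, site/scanner effects, heavy-tailed noise, and
correlated confounds. Passing tests on synthetic cohorts therefore
demonstrate that the machinery recovers what was planted under its own
assumptions — not that clinical effect sizes or the published accuracy
table would be reproduced on real data, which are not distributed with the
package.

## Problem sizes used by the test suite

The full study design (1,000 iterations on ~4,000-voxel masks) is linear in
both quantities and runs unchanged; the shipped tests run the design at
sizes chosen to keep the suite interactive: the end-to-end recovery and
paired-comparison checks use 68 subjects × 500 voxels with 50 iterations
(strong effect $d = 2$ and null $d = 0$ on identical subjects and seeds),
unit tests use cohorts of 11–17 subjects and 10–120 voxels, and the
grid-search oracle checks use 12–14 subject tables where the zero-error
transition is interior. These sizes are stated here as the package's test
design; they are arguments, not constants.

## Known limitations

- The ensemble's calibration inherits the plain logistic link; absolute
  values of $H$ should be read as ranking scores more than calibrated
  probabilities unless `link = "platt"` is used.
- On separable data the likelihood barely distinguishes the grid models,
  so the posterior is prior-dominated by construction; that is the intended
  regularization, but it means $H$ is then close to a fixed-weight average.
- The probe floor for $C_\mu$ is a convention; analyses whose feature scale
  makes $10^{-4}$ non-negligible should lower `lower_cap`.
- Misclassification counts are attributed per subject id; ids must be
  stable across measures for cross-measure comparisons.
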