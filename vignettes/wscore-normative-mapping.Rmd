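---
title: "Normative W-score mapping and mass-univariate inference for small-vessel-disease imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative W-score mapping and mass-univariate inference}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wscoremap)
```

## The problem

Cerebral small-vessel disease takes both a monogenic form (CADASIL, driven
by *NOTCH3* mutations) and sporadic forms (subcortical vascular cognitive
impairment, SVCI). Comparing their imaging signatures — white-matter
hyperintensity (WMH) topography, diffusion-tensor skeleton measures (FA,
MD), cortical thickness — is confounded by demographics: monogenic disease
manifests decades earlier, so CADASIL cohorts are much younger than SVCI
cohorts. The W-score approach handles this by scoring every patient
against a normative control model at the patient's own covariates, then
comparing the covariate-adjusted deviation maps between groups.

`wscoremap` implements that full workflow at desk scale: a synthetic-cohort
generator with known ground truth, the per-location normative model, lesion
frequency mapping, and mass-univariate group inference with FDR and
permutation-FWE correction. Because no patient data are distributable, the
synthetic generator is a first-class, tested component: it defines the
conditions under which every downstream claim is verified.

## The normative W-score model

For one modality (thickness on surface vertices; FA or MD on skeleton
voxels), each location $v$ gets an ordinary-least-squares fit on the
control cohort:

$$y_v = \beta_{0v} + \beta_{1v}\,\mathrm{age} + \beta_{2v}\,\mathrm{sex} +
\beta_{3v}\,\mathrm{ICV} + \varepsilon_v,\qquad
\varepsilon_v \sim N(0, \sigma_v^2).$$

A subject's W-score at $v$ is the standardized residual from that model,

$$W_v = \frac{y_v - \hat y_v(\mathrm{age}, \mathrm{sex}, \mathrm{ICV})}
{\hat\sigma_v},$$

so W behaves like a covariate-adjusted Z-score: mean 0 and SD 1 in the
control population, with $\pm 1.65$ at the 95th/5th percentiles under the
Gaussian working model. The sign convention is raw-minus-predicted
throughout: positive W always means larger thickness, larger FA, larger
MD. Damage therefore appears as *negative* thickness and FA W-scores and
*positive* MD W-scores (`abnormality_direction()` records this per
modality for one-sided reporting; the tests themselves are two-sided).

### Residual-SD denominator and the exact in-sample identity

"SD of the residuals" is ambiguous between the population estimate
(denominator $n$) and the df-adjusted estimate. We use the df-adjusted
denominator $n - 4$ (intercept plus three covariates), which is unbiased
for $\sigma_v^2$ and gives an exact, testable identity: because OLS
residuals with an intercept sum to zero and satisfy
$\sum_i e_{iv}^2 = (n-4)\hat\sigma_v^2$, the in-sample W-scores at every
location have mean exactly 0 and sample SD (denominator $n-1$) exactly

$$\mathrm{SD}(W_v) = \sqrt{\frac{n-4}{n-1}},$$

e.g. $0.9723$ at $n = 56$ controls. The suite asserts this to $10^{-12}$
at every location; held-out controls from the same population calibrate to
mean $\approx 0$, SD $\approx 1$ instead (slightly above 1, by the
prediction-variance factor $\sqrt{1 + x^\top(X^\top X)^{-1}x}$). This is
also why the empirical percentile of $W = 1.65$ on held-out controls lands
near 94.8 rather than exactly 95.05: finite-control prediction error
widens the held-out W distribution by $\approx \sqrt{1 + 4/n}$.

Degenerate locations (residual SD below $10^{-8}$ times the map's value
scale, e.g. exactly collinear synthetic data) are flagged and masked
rather than producing unbounded W. If a covariate is constant across
controls (a single-sex control sample), its column is dropped with a
warning and its coefficient set to zero, keeping edge cases runnable; the
residual df follow the retained rank.

Whether ICV belongs in the DTI models as well as the thickness model is
genuinely open; we apply the same three covariates uniformly to all
modalities, which is the simplest defensible reading and keeps one code
path. The fit is per-location and the design matrix is shared, so the
whole fit is a single QR decomposition applied to a locations-by-subjects
matrix.

## Geometry and the synthetic generator

The toy geometry stands in for the real meshes: a 50×40 grid-graph surface
(2,000 vertices, 3 mm spacing, periodic so every vertex has degree 4) and
a ~1,500-voxel skeleton inside a 20×20×20 grid of 2 mm voxels — a
desk-scale analogue of the 40,962-vertex hemispheres and a TBSS skeleton.

The generator draws, per subject: age from the group's normal law
(truncated at 18 by redrawing; the truncation bias is negligible at the
means used), sex as Bernoulli (female = 1, matching a single regression
column), ICV as normal, map values from exactly the linear-Gaussian
structure the normative model assumes plus localized additive group
effects, lesion masks as independent voxelwise Bernoulli draws from
group-specific probability maps, and PET uptake built so the
composite-over-cerebellum ratio is above 1.5 with exactly the intended
group probability. Default group demographics mirror the study design:
controls 68 ± 7 y (the control demographics are not fixed by any published
table, so they are configuration with this one default), a CADASIL-like
group at 57 ± 7 y (n = 11), and SVCI-like groups at 72 ± 8 (n = 15) and
74 ± 7 (n = 101).

What the generator deliberately does **not** emulate: spatial noise
correlation, scanner/site effects, registration error, partial-volume
effects, non-Gaussian tails, and spatially correlated lesions (lesion
voxels are independent; an optional probability-map smoother exists but is
off by default). Passing tests therefore demonstrate correctness of the
estimators and error control *under the model's own assumptions* — they do
not certify behaviour on real scanner data, where smoothness makes
voxelwise tests dependent and max-statistic FWE conservative rather than
exact.

## Surface smoothing

Real pipelines smooth thickness maps with a surface Gaussian kernel
(20 mm FWHM is typical). On the grid-graph we use $k$ passes of symmetric
neighbour averaging (each vertex replaced by the mean of itself and its 4
neighbours). One pass adds $2h^2/5$ variance per surface axis ($h$ =
vertex spacing), so matching a Gaussian of the requested FWHM gives

$$k = \mathrm{round}\!\left(\frac{\mathrm{FWHM}^2 \,(d+1)}{16 \ln 2\, h^2}\right),
\quad d = 4,$$

(20 passes at FWHM 20 mm, $h$ = 3 mm). The integer rounding keeps the
equivalent FWHM within 10% for FWHM ≳ 10 mm at the default spacing;
`fwhm = 0` is the identity. On the closed grid the operator is doubly
stochastic, so constants, the map mean, and total mass are preserved —
all asserted in the suite. Smoothing is off by default in the pipeline
(`fwhm_mm = 0`): on white-noise maps it only trades variance for spatial
dependence, which the independence-based calibration runs do not want.

## Lesion-frequency comparison

Group WMH maps are voxelwise lesion proportions. The between-group test at
each voxel is a pooled-variance two-sample t on the 0/1 indicators,
flagged at two-sided p < 0.001 uncorrected, matching the t-value display
convention of lesion-mapping software. Voxels whose combined stack is
constant carry no information and are excluded; a voxel lesioned in all of
one group and none of the other has zero pooled variance but maximal
evidence and is reported as $t = \pm\infty$, $p = 0$ rather than dropped.
The t approximation on Bernoulli data is discrete: its achieved size at
$\alpha = 0.001$ is within a few percent of nominal for ~100 subjects per
group (the calibration runs use that size), but can deviate noticeably for
small unbalanced groups — visible in the demo workflow, where the 11-vs-15
contrast is shown for pattern, not calibrated inference. Lesion extents
for the modified-Fazekas eligibility rule (periventricular ≥ 10 mm and
deep ≥ 25 mm for SVCI; both < 10 mm for controls) are radiological
measurements and are taken as inputs, not computed from masks.

## Mass-univariate inference

Contrasts are pooled two-sample t tests per location on the W maps
(positive t = first group higher), df $n_A + n_B - 2$. Correction is
applied within each map, not across the three pairwise contrasts:

* **Surface (thickness): Benjamini–Hochberg FDR** at q = 0.05, step-up
  over all in-mask vertices, implemented via `p.adjust(.., "BH")` and
  checked against a literally-coded step-up oracle.
* **Skeleton (FA/MD): max-statistic permutation FWE** at p < 0.05,
  restricted to the mean-control-FA > 0.2 mask (strict inequality at the
  boundary). Subject labels are permuted; the null distribution of the
  maximum |t| over the mask gives corrected p-values
  $(1 + \#\{\max |t|_{perm} \ge |t_{obs}|\})/(B+1)$ — the add-one
  estimator avoids zero p-values. When $\binom{n_A+n_B}{n_A} \le B$ the
  test enumerates all assignments and is exact (corrected p a multiple of
  $1/\binom{n}{n_A}$, identity assignment included). The default is
  B = 5000 with a mandatory seed; a tie tolerance of $10^{-8}$ relative
  absorbs floating-point differences between the observed and permuted
  statistic paths. TFCE and cluster-extent inference are deliberately out
  of scope; max-|t| is the canonical family-wise mechanism of
  permutation tools.

Vertexwise contrasts can optionally residualize age/sex again
(Freedman–Lane-style) but default to the plain comparison, since the W
maps are already covariate-adjusted.

### A calibration caveat worth knowing

The two-sample permutation and FDR nulls assume exchangeability of the W
maps between the compared groups. Normative-model estimation error breaks
this when the compared groups differ strongly in covariates: the
prediction error at a subject's covariates is shared across subjects with
similar covariates, so a large group age gap plus a small control sample
produces genuine, spatially structured spurious W differences (we observed
max |t| ≈ 5.5 on 120 null voxels with a 12-year gap and 25 controls).
Calibration runs therefore use demographically matched groups — the null
the tests actually assume — and results on strongly age-discrepant groups
should be read alongside covariate-matched sensitivity analyses, exactly
as age-matched subgroup analyses accompany the main contrasts in practice.

## Global statistics

Per-subject global mean W (over unmasked locations, FA-mask-restricted on
the skeleton) is compared across patient groups by ANCOVA
(`value ~ age + sex + group`, F test for the group factor added last) with
Bonferroni post hoc pairwise contrasts (raw p × number of pairs, capped at
1). Normality of W is checked by Kolmogorov–Smirnov with the Lilliefors
null for estimated parameters (`nortest::lillie.test`); a plain KS against
N(0,1) is also exposed since W is nominally standardized. Variance
homogeneity uses Bartlett's chi-square test; a zero-variance group is a
data error rather than a silent statistic.

## Numerical and design choices

* Residual-SD denominator $n-4$; degeneracy tolerance $10^{-8}\times$
  map scale; rank-deficient designs drop constant columns with beta 0.
* FA skeleton mask strict `> 0.2`; amyloid positivity strict `> 1.5`
  (a ratio of exactly 1.5 is negative); Fazekas thresholds inclusive
  (≥ 10 / ≥ 25) for SVCI eligibility, strict (< 10 / < 10) for controls.
* Permutation p via $(b+1)/(B+1)$; full enumeration whenever feasible;
  seeds mandatory for every stochastic stage and recorded in the
  provenance block of `summary.json` together with an MD5 of the
  canonical config.
* Voxel order follows the NIfTI layout; vertex and voxel indices are
  1-based everywhere in R-facing structures and files.
* CSV dialect: comma, header, UTF-8, `.` decimal. Volumes: NIfTI-1 via
  RNifti, doubles, with the skeleton index as a companion binary mask.

## Problem sizes used by the suite

Tests and the acceptance script run at the package's chosen desk scale:
the 2,000-vertex / ~1,500-voxel default geometry for identities and
recovery, a 100-surface-vertex / 300-skeleton-voxel geometry for the
200-dataset error-rate runs (15 + 15 subjects, 40 controls, 250
permutations), 200 null lesion datasets at 100 + 100 subjects, and
500-replicate ANCOVA/Bartlett nulls. Planted-effect recovery uses a
400-vertex block deficit at Cohen's d = 1.0 (30 vs 30 patients, 100
controls, 20 replicates): the run reports mean sensitivity ≈ 0.86 with
≈ 4% of discoveries outside the planted region, consistent with the
q = 0.05 FDR target.

## Known limitations

* No spatial dependence anywhere in the generator; real-data FWE will be
  conservative relative to the calibration shown here.
* The normative model is linear; nonlinear age effects, site effects and
  longitudinal designs are out of scope.
* W-score estimation uncertainty is not propagated into the group tests
  (see the calibration caveat above).
* Lesion extent measurement and WMH segmentation are not modelled; masks
  enter as given.
* The toy surface is a torus, not a cortical mesh: smoothing equivalences
  hold in the regular-graph sense only.
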