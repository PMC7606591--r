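---
title: "Surface-based morphometry with surfmorph: models, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surface-based morphometry with surfmorph}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis problem

Cortical volume (CV) at any point of the cortical sheet is, to first
order, the product of cortical thickness (CT) and the surface area (SA)
of the tessellation patch around that point. Case-control differences in
CV therefore conflate two biologically distinct quantities. `surfmorph`
implements a vertex-wise analysis that (i) tests for group differences
and age-by-group interactions in CT, SA and CV on a common template
mesh, (ii) corrects cluster-wise over the whole surface with
random-field theory (RFT) for non-isotropic fields, and (iii) quantifies
how CT and SA differences are spatially arranged: how much they overlap,
whether that overlap exceeds what two independent patterns would
produce, and how much of each CV difference co-localizes with a CT
and/or SA difference.

The package is written for desk-scale methodological work: every stage
can be exercised on synthetic cohorts with known ground truth, at mesh
resolutions where a thousand-replicate calibration study runs in
minutes.

## The vertex-wise model

At each vertex the measure is modelled by ordinary least squares as

```
Y = b0 + b1*site + b2*group + b3*age + b4*age^2
      + b5*(age x group) + b6*(age^2 x group)
      + b7*sex + b8*IQ + b9*related + b10*totalSA + e
```

with 0/1 indicator coding for site, group, sex and relatedness
(reference levels: site A, control, female, unrelated) and all
continuous covariates mean-centered across the combined sample. Age
powers are computed from centered age and then re-centered; interactions
are formed from the centered terms. Centering leaves fitted values and
residuals unchanged (a tested invariant) while keeping `b2`
interpretable as the group shift at the sample-mean age. Total surface
area enters as a covariate so that vertex-wise SA effects are tested
over and above the global difference between groups.

The relatedness indicator is a fixed effect, not a family-level random
effect; with only a handful of sibling pairs in the emulated design this
is a deliberate simplification, and mixed-effects modelling is out of
scope.

The age polynomial order is chosen by a step-up procedure on the
combined sample: a vertex-wise nested F test compares the linear to the
quadratic model, the resulting F field is cluster-corrected, and only if
some cluster is significant is the quadratic compared to the cubic in
the same way. The adopted order is global (the most complex order whose
addition produced at least one significant cluster), matching how such
model selection is usually reported for developmental cohorts. The
cubic step adds both `age^3` and `age^3 x group`; whether the
interaction belongs in the cubic comparison is genuinely ambiguous, so
it follows the `with_interactions` switch used everywhere else.

## Smoothing

Per-vertex data are smoothed with iterated nearest-neighbour averaging.
One step of the operator mixes each vertex with its neighbours using
Metropolis weights `1/max(deg(u), deg(v))`, which makes the operator
symmetric and doubly stochastic: constant fields are exact fixed points
and the field's total sum is conserved to machine precision. The number
of iterations and the per-step mixing weight are calibrated by the
Gaussian variance-accumulation rule: `n` steps of mean squared
displacement `s2` approximate a surface Gaussian with per-axis variance
`n * lambda * s2 / 2`, matched to `FWHM^2 / (8 ln 2)`. The mixing
weight is capped at 1/2 so the cumulative kernel stays close to
Gaussian. The calibration is verified empirically: noise smoothed at a
nominal 10 mm is estimated by the residual-based smoothness estimator
at a median FWHM within 10 +/- 2 mm.

This scheme approximates a heat kernel; it is not a geodesic-exact
Gaussian. On meshes whose edge length approaches the requested FWHM the
cumulative kernel is coarse, which is one reason the calibration suite
(below) is run at the same mesh scale as the analyses it certifies.

## RFT cluster inference

Residual smoothness is estimated from unit-normalized GLM residuals:
the summed squared difference of the normalized residual vectors along
a mesh edge estimates `2(1 - rho)`, which for small lags equals
`lambda * h^2` with `lambda` the derivative variance of the
standardized field; `FWHM = sqrt(4 ln 2 / lambda)`. Triangle areas
re-expressed in FWHM units via Heron's formula give resels, summed per
face and distributed to vertices by thirds so cluster extents in resels
add up consistently.

Clusters are connected components of supra-threshold vertices at a
vertex-level forming threshold, `p < 0.001` per tail by default. The
cluster-level familywise p uses the expected-cluster framework for
smooth fields: with `R` search resels and forming threshold `u`,
`E[clusters] = R * rho2(u)` with `rho2` the 2-D Euler-characteristic
density of the t (or F) field, cluster resel extents are taken as
exponential with mean `P(T > u) / rho2(u)`, and
`p = 1 - exp(-E[clusters] * exp(-beta * k))`. Two-tailed analyses run
the two tails separately and double the per-tail p, which keeps signed
clusters available for the overlap bookkeeping. Hemispheres are
separate search regions; their resels are summed into one whole-brain
correction. A cluster with zero resel extent is never significant
(p = 1 by convention).

Two numerical choices deserve note. First, only the leading (2-D) EC
term is used for the expected cluster count; on closed surfaces with
hundreds of resels the lower-order terms are negligible at the default
forming threshold. Second, the estimator is not a line-for-line
reproduction of any particular toolbox; its adequacy is enforced by
calibration: on 1000 null synthetic cohorts (642-vertex icosphere
templates, 50 mm radius, n = 20 + 20, 10-mm smoothness) the familywise
error at cluster p < 0.05 must land in [0.03, 0.08], and does (0.039
at the packaged seed). RFT's smoothness assumptions genuinely matter
here: applying cluster inference to unsmoothed (edge-scale) fields
produces single-vertex clusters whose p-values are unreliable, which is
why both the pipeline and the calibration suite always smooth.

## Overlap and decomposition statistics

Significant vertices from the CT and SA analyses are classified
CT-only, SA-only, or both, ignoring sign, with percentages over the
union of significant vertices. A chi-square goodness-of-fit against
equal category counts (`df = k - 1`) tests whether differences are
equally distributed. The observed overlap percentage is referred to a
simulation null: pairs of independent iid standard-normal maps are
thresholded two-tailed at `alpha` and the null distribution of
`100 * |both| / |either|` is accumulated; the empirical p uses the
add-one estimator `(1 + #{null >= obs}) / (N + 1)` and is therefore
never zero. For independent maps the expected overlap is
`alpha^2 / (2 alpha - alpha^2)`, 2.564% at `alpha = 0.05`, and the
simulation mean is tested against this closed form. The null maps are
deliberately unsmoothed — they model two spatially independent
patterns, not two smooth ones; against spatially smooth observed masks
this makes the test conservative in the direction of under-stating
significance of high overlap, which is documented rather than
corrected.

CV differences are decomposed by restricting to CV-significant
vertices, splitting by direction of the CV difference, and counting
co-occurrence with CT/SA significance (sign ignored for membership):
`ct_only + sa_only + ct_and_sa = cv_explained` and
`cv_explained + cv_unexplained = cv_total` are structural identities
checked on every input. Percentages are rounded half-up to two
decimals, and tables render cells as `count(pct)` with `0(0)` for empty
cells.

A note on published reference values: the packaged example count tables
reproduce every percentage from their counts, but the chi-square
statistics sometimes quoted alongside such tables are not recoverable
from the printed counts under the equal-distribution construction — the
counts imply far larger statistics. `chi2_equal_distribution()`
implements the described test; it makes no attempt to reverse-engineer
a different one.

## The synthetic cohort generator

The generator defines the study conditions under which everything above
is tested. Defaults emulate a two-site deletion-syndrome cohort:
62 cases and 57 controls aged 6-31; case IQ ~ N(82, 13) vs control
N(114, 16), truncated at 60; total SA 0.20 vs 0.23 m^2 with sd
0.0275 m^2 in both groups, chosen so the standardized group difference
(d ~ 1.09) matches the reported two-sample t near -5.95 at this sample
size (the published SD column for this measure is internally
inconsistent with its own range, so the t statistic was taken as the
binding constraint); mean CT 2.72 vs 2.73 mm (sd 0.14/0.12); total CV
= mean CT x total SA x lognormal noise, so 1 mm x 1 m^2 = 1 L puts it
near the published 0.59/0.64 L. Sex, site, relatedness and the
case-only prodromal-psychosis flag are assigned by exact counts rather
than Bernoulli draws, so indicator columns never degenerate in small
cohorts.

Vertex measures are built as baseline + shared quadratic age trend +
planted effect patches + spatially smoothed Gaussian noise (10-mm
default, matching the analysis smoothing). CT noise sd is 0.25 mm;
SA is generated on the log scale (sd 0.10) around each subject's total
SA distributed over the template by vertex area; CV is the per-vertex
product `CT x SA` with optional multiplicative lognormal noise. The
product rule is what makes the decomposition stage's signature
behaviours — SA-driven CV loss, opposing CT/SA effects masking CV
differences — emergent rather than hard-coded. The default quadratic
age coefficient (-0.002 mm/yr^2 for CT) describes a late-childhood peak
followed by decline and is strong enough for the step-up procedure to
adopt the quadratic model at the default cohort size, mirroring the
developmental literature this design emulates.

Planted effects are k-ring disks with amplitude `d x noise sd`, where
`d` is stated relative to the post-smoothing noise scale (the smoothed
noise is rescaled to unit variance before scaling, so planted effect
sizes mean what they say). `plant_overlap_scenario()` places a CT(+)
and an SA(-) disk whose truth-mask Jaccard overlap approximates a
requested fraction; achievable fractions are discrete (one adjacency
ring apart), and the builder errors constructively when a fraction is
unreachable at the given radius.

What the generator does **not** emulate, and what passing tests
therefore do not show about real data: scanner- and site-specific bias
fields (site is a pure mean shift), FreeSurfer reconstruction error,
within-group correlation between IQ and anatomy (the reported
within-case IQ-CV association is not modelled; the overall IQ-CV
correlation in synthetic cohorts arises from the group contrast alone
and is correspondingly weaker), spatially non-stationary smoothness,
and per-vertex effect sizes of any real population. Calibration
results transfer to real cortical data only to the extent that 10-mm
smoothed Gaussian noise on an icosphere is a fair null model for
smoothed morphometry residuals on fsaverage.

## Problem sizes and reproducibility

All Monte-Carlo suites are sized for a single desk CPU: the familywise
error study uses 1000 replicates on 642-vertex templates (about two
minutes), effect recovery uses 20 replicates at the full default cohort
size, and the overlap-null check uses 200 simulations at 300,000
vertices. Every stochastic stage takes an explicit integer seed, a
fixed seed reproduces results bit-for-bit (written reports are
byte-identical across reruns), and `write_reports()` emits a manifest
with an MD5 checksum per artifact plus the fully resolved
configuration.

## Known limitations

- Cluster inference is cluster-level only: no peak-level RFT p-values,
  no TFCE, and no permutation-based primary inference.
- The smoothness estimator assumes approximately Gaussian residual
  autocorrelation; heavy non-stationarity is only partially absorbed by
  the local-FWHM resel weighting.
- The template is assumed common across subjects; no registration or
  surface reconstruction is performed or modelled.
- Family structure is a fixed covariate, not a variance component.
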