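---
title: "Measuring and analysing retinal vascular bifurcation geometry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring and analysing retinal vascular bifurcation geometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(RVGeometry)
```

# The measurement model

A retinal vascular bifurcation is a junction where a parent vessel of
width $d_0$ splits into a larger child ($d_1$) and a smaller child
($d_2$), with $d_0 \ge d_1 \ge d_2 > 0$. Each child deflects from the
extrapolated parent direction by a branching angle ($\theta_1$ for the
larger child, $\theta_2$ for the smaller), and the bifurcation angle is
their sum, $\theta = \theta_1 + \theta_2$ — an identity of
construction, not an estimate. Murray's law for flow-optimal junctions
predicts $d_0^3 = d_1^3 + d_2^3$; the *junction exponent* $\chi$
generalises this as the root of

$$d_1^\chi + d_2^\chi = d_0^\chi,$$

so $\chi = 3$ marks optimality and departures index microvascular
dysfunction. Writing $g(\chi) = (d_1/d_0)^\chi + (d_2/d_0)^\chi - 1$,
$g$ is strictly decreasing from $g(0^+) = 1$, so a unique positive root
exists exactly when $d_0 > d_1$; when $d_0 \le d_1$ no finite root
exists and `solveJunctionExponent()` returns `NA` with reason
`"no finite root"`. Records with undefined $\chi$ stay usable; summary
functions exclude the missing values and report their count.

## Width estimation from perpendicular profiles

`extractPerpendicularProfiles()` realises the rectangle technique: a
rectangle seed is aligned with the segment centreline and intensity
profiles are sampled perpendicular to its axis at evenly spaced
stations, with bilinear interpolation at a 0.25 px sub-pixel step and a
profile half-length of twice the seed's initial width. Per profile
(`estimateSegmentWidth()`), the background level is the median of the
outer 25% of samples, the vessel core the minimum of the central 50%,
and the two edges are located where intensity crosses the half-height
level $(\text{background} + \text{core})/2$, interpolated linearly
between samples; the segment width is the mean edge-to-edge distance
across stations. The `"fwhm"` variant works on the
background-minus-intensity depth curve and takes the full width at half
the peak depth — equivalent for symmetric profiles, and matching the
analytic $2\sigma\sqrt{2\ln 2}$ for Gaussian cross-sections.

Assumptions and choices worth knowing:

* **Vessels are darker than the background** (fundus green-channel
  polarity). Bright-vessel data flips via `darkVessel = FALSE`; wrong
  polarity raises an explicit error rather than returning a spurious
  width.
* The original interactive "adapt the width to the observed edges" step
  is replaced by the deterministic half-height rule for
  reproducibility; a caller can still supply manually marked edge
  positions through `manualEdges`, preserving the semi-manual
  workflow.
* Widths stay in **pixels** throughout; no micrometre conversion is
  attempted, and the derived ratios ($\chi$, asymmetry, area ratio,
  distance ratio) are dimensionless precisely so that they survive
  resolution changes.
* Averaging across stations (rather than taking a single mid-segment
  profile) was an open choice; averaging is used because it halves the
  noise sensitivity of the estimate on rendered test scenes.

Angles come from the four annotated centreline points: the parent flow
direction is apex minus parent end, extrapolated through the apex, and
each child angle is the unsigned angle to the child's end-minus-apex
vector, in $[0, 180]$ degrees. When both children fall on one side of
the parent axis the record carries a `children_same_side` flag because
$\theta$ then exceeds the inter-child angle. Larger/smaller child roles
follow measured width, with a width tie broken deterministically in
favour of the child with the smaller deflection.

## Derived ratios

The junction exponent ratio (JER), asymmetry ratio and area ratio have
no single standard definition; the package documents its own:

* $\mathrm{JER} = d_0 / (d_1^3 + d_2^3)^{1/3}$ (1 at Murray optimality),
* $\mathrm{asymmetry} = (d_2/d_1)^2$ (1 for symmetric children),
* $\mathrm{area} = (d_1^2 + d_2^2)/d_0^2$.

Every result carries a provenance note stating that these formulas are
package defaults. JER inherits the well-known over-sensitivity of
junction-exponent arithmetic to small width errors; treat its scatter
accordingly.

# Statistical analysis

The unit of analysis is the **bifurcation**, pooled within patients:
group sizes in comparative tables count bifurcations, not patients.
Patient-level clustering is deliberately *not* modelled — the
comparative design this package reproduces did not — so p-values for
grade comparisons are anticonservative to the extent that patient
random effects exist. This limitation is intrinsic to the design and is
why the null calibration below zeroes the patient effect.

* `oneWayAnova()` wraps the classical between/within decomposition
  (via `stats::aov`), with the degenerate all-equal case defined as
  $F = 0, p = 1$.
* `flsdPosthoc()` implements the Fisher-protected least significant
  difference: pairwise two-sided t-tests from the pooled within-group
  MSE and its degrees of freedom, *gated* by the omnibus ANOVA —
  pairs can be significant only when the omnibus $p \le \alpha$
  ($\alpha = 0.05$ default, two-sided throughout, no further
  multiple-testing correction by design). Homogeneous-subset letters
  are built from maximal runs of mean-ordered groups with no
  significant internal pair.
* `fitRiskFactorModels()` fits three nested OLS models of a feature on
  demographic covariates (model 1: age, sex; model 2: + diabetes type,
  hypertension; model 3: + duration, hypercholesterolemia), with 0/1
  coding (female = 1, type 2 = 1, condition present = 1) echoed in
  every result. Bifurcation-level rows are the default; an
  `imageMean` switch averages per image first.
* `fitProgressionLogistic()` regresses the progressor flag on one
  baseline feature, reporting the per-unit odds ratio with a Wald 95%
  CI. Complete separation triggers a flagged refit with a tiny ridge
  penalty ($\lambda = 10^{-6}$) on the slope.
* `repeatabilityCoV()` turns repeated measurement sessions into a
  coefficient of variation: the within-bifurcation mean square from a
  one-way decomposition gives the between-session SD, divided by the
  grand mean. How the published averages were taken (across features
  first or bifurcations first) is unstated in the source design; this
  package averages the per-feature CoVs.

# Patient-level grade models

`matchDistanceRatio()` controls for distance from the optic nerve head
before patient-level modelling: the patient with the lowest mean
distance ratio is the untrimmed reference; every other patient loses
its most distant bifurcation repeatedly until its mean is *just* below
the reference (restoring the last discarded row would bring it back to
or above). Ties among removal candidates drop the later row; reference
ties resolve by patient id; a patient trimmed to a single row while
still at or above the reference is kept and flagged unmatchable.

`buildPatientProfiles()` then characterises each patient (one image per
patient) by the means of the model predictors over kept rows, and
`looClassify()` runs leave-one-out cross-validated logistic models:
model one separates no-retinopathy from any retinopathy (predictors:
mean parent diameter and mean smaller-child deflection angle); model
two separates proliferative from non-proliferative among retinopathy
cases (mean parent diameter only), optionally scoring the
no-retinopathy patients into an overall specificity. The decision
threshold is fixed at 0.5 by default and exposed as a parameter;
predictors are fitted on their raw scales (standardisation was an open
choice; raw scales keep coefficients interpretable per pixel/degree).
Each fold's coefficients are stored in the report for audit, which is
also how the strict-holdout property is tested: perturbing a held-out
patient must leave that fold's coefficients bit-identical.

# What the synthetic module emulates — and what it does not

`renderBifurcationImage()` draws three straight segments from an apex
with box or Gaussian cross-sections via exact distance-to-centreline
evaluation (1 px anti-aliasing ramp), seeded Gaussian noise, and emits
the annotation plus analytically known ground truth. This is the
end-to-end oracle for the measurement code: recovered widths must stay
within 0.5 px and angles within 1 degree on noiseless scenes.

`generateCohort()` simulates the feature hierarchy directly (rendering
is reserved for geometry tests; desk-scale statistics need thousands of
bifurcations): per-grade, per-vessel-type means and SDs defaulting to
the observed clinical distribution (widths increasing with grade,
smaller-child angle widening), group sizes 10/10/12/19 with a mean of
15 bifurcations per image, and the grade-specific arteriole:venule
mixes. Structural choices:

* **Widths** are generated as $d_2$ plus positive gamma-distributed
  gaps to $d_1$ and $d_0$, so the ordering invariant holds by
  construction, the three widths are positively correlated through
  shared components, and the first two moments match the configured
  values exactly (gamma parameterised by mean and SD). Where the
  configured SDs would imply a negative gap variance the gap becomes
  deterministic; the affected SDs are reproduced approximately.
* **Angles** $\theta_1, \theta_2$ are gamma marginals coupled by a
  Gaussian copula whose negative correlation is chosen so the SD of
  their sum matches the configured $\theta$ SD; $\theta$ is always the
  literal sum, and $\chi$ is always computed from the generated widths,
  never drawn.
* **Patient effects** (shared within patient, SD well below the total)
  and **covariate effects** (age, sex, type, duration, hypertension,
  cholesterol, in the directions observed clinically) shift feature
  means; covariates are centred within grade so the configured grade
  means are exact grade-conditional means. Since width marginals are
  right-skewed gammas rather than normals, the realised log-odds slope
  of a mean shift is mildly attenuated relative to the normal-theory
  mapping $\beta = \Delta/\sigma^2$ used to set the default progression
  shift — the simulated progression odds ratio therefore sits slightly
  above the nominal value.
* **Distance ratios** are gamma within patient (wide spread, as
  bifurcations are nominated across the whole image) with only mild
  clarity-driven variation in per-patient means. This is deliberate:
  the distance-matching procedure trims every patient below the
  *minimum* patient mean, and the expected number of discarded rows is
  invariant to the scale of the spread (about a third of rows at these
  shapes), so a generator with strongly varying patient clarity makes
  matching degenerate in a way the original semi-manual workflow
  evidently was not.
* `generateProgressionCohort()` adds three visits with persistent
  patient effects; progressors carry a baseline smaller-child width
  deficit (default calibrated to a log-odds slope of −0.318 per pixel
  at the no-retinopathy width SD) and proliferative-grade geometry at
  the final visit.
* `nullGenerativeParams()` removes every systematic difference —
  equal grade means, zero covariate effects, zero patient effects and
  a grade-constant vessel-type mix (with per-type means retained, a
  grade-varying mix would itself be a real signal) — so that
  bifurcations are exchangeable and downstream tests must reject at
  their nominal rate.

What passing tests on these cohorts show is that the *pipeline*
recovers the structure its generator put in; they cannot certify
behaviour on real fundus photographs, whose width profiles are not
ideal boxes, whose features have unknown joint structure, and whose
patient effects are not zero.

# Numerical choices

* Coordinates are 0-based, origin top-left, $x$ = column, $y$ = row;
  angles in degrees with $y$ pointing down.
* $\chi$ bisection bracket $[10^{-3}, 50]$, 60 halvings (bracket below
  $10^{-9}$); roots escaping the bracket are reported undefined. The
  test oracle is an independent multi-stage sign-change grid
  ($10^{-2} \to 10^{-4} \to 10^{-6}$ steps), agreeing to $10^{-6}$.
* Profile sampling step 0.25 px; half-length $2\times$ the initial
  width; flat profiles (no crossing) and polarity violations are
  errors that flag the bifurcation unusable rather than aborting the
  image.
* Logistic fits use IRLS (`stats::glm.fit`); separation is detected by
  the fitted-probability warning or slope magnitude > 25 and retried
  with the $10^{-6}$ ridge, flagged `penalized`.
* All randomness flows from a single seed per entry point, with stage
  seeds derived deterministically; generators restore the caller's RNG
  state.

# Problem sizes used in the shipped checks

The packaged validation uses 100 rendered scenes (widths 3–15 px,
child deflections 20–120° with child widths separated by > 0.4 px so
larger/smaller roles stay identifiable under sub-pixel error), 1000
random width triples against the grid oracle, 200 random patient sets
for matching post-conditions, 500 replicates for each coverage and
type-I calibration (linear-model coverage on 24-patient cohorts;
logistic coverage on 240 single-bifurcation patients with outcomes
drawn from a logistic law with slope −0.3; both with patient effects
disabled so the single-level fits are correctly specified and Wald
intervals attain nominal coverage), and 100 seeded cohorts at the
default 10/10/12/19 group sizes for the leave-one-out models, where
above-chance performance is summarised as the median of the mean of
sensitivity and specificity.

# Known limitations

* No automatic vessel segmentation or bifurcation detection: input is
  annotation-driven, as in the semi-manual workflow it reproduces.
  Alternative width estimators (kick-points, Gregson, 1-D/2-D
  Gaussian fits) are an extension point; only the rectangle half-height
  and FWHM estimators ship.
* Patient clustering is unmodelled in the comparative statistics (by
  design, see above); a mixed-model reanalysis would need a different
  tool.
* The grade models inherit the 0.5-threshold behaviour of maximum
  likelihood under class imbalance: with 41 retinopathy versus 10
  no-retinopathy patients the decision boundary shifts toward the
  minority class, which caps specificity well below sensitivity on
  cohorts of this shape even when the width effect is real — and
  distance matching, which discards about a third of the rows, widens
  the patient-mean spread further.
* Cross-visit width comparisons are excluded on principle (pixel
  widths are not comparable across acquisition systems); only the
  dimensionless angles and $\chi$ are compared across visits.

# A worked example

```{r example, eval = FALSE}
cohort <- generateCohort(seed = 1)
report <- runComparative(features(cohort), patients(cohort))
report$tables$all[report$tables$all$feature == "d0", ]

grade <- classifyGrades(features(cohort), patients(cohort), model = "one")
grade
```
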