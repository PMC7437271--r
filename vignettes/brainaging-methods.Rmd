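---
title: "Methods: aging slopes, bootstrap intervals and normative tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: aging slopes, bootstrap intervals and normative tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(brainaging)
```

## The problem

Most reference data on brain aging come from predominantly Caucasian
samples, yet regional brain volumes and their rates of age-related change
differ across populations. This package implements a cross-sectional
pipeline for quantifying those differences in cognitively normal elderly
cohorts (ages 65–85): per-group aging slopes with bootstrap uncertainty,
conservative group comparisons, APOE ε4 stratified effects, and normative
tables fine-grained enough to z-score an individual patient. Because the
cohorts that motivated the design are access-restricted, the package
ships a synthetic-cohort generator whose defaults encode the published
summary structure; every claim a test makes is a claim about that stated
world.

## Model and procedure

**Screening.** A subject is cognitively normal when MMSE ≥ 19 and no
cognitive-domain z-score (attention, language, visuospatial, memory,
frontal/executive) falls below −1.5. Both cuts are arguments; the
exclusion reason names the first failing criterion. Screening requires
complete neuropsychological data — how partially missing domain scores
should be handled is not defined by the source material, so we refuse
rather than guess.

**ICV normalization.** Age and intracranial volume are correlated in
elderly samples, so analyses use the relative volume
$r = 100 \cdot V / \mathrm{ICV}$ (% of ICV) rather than absolute mm³.

**Aging slope (APC).** Within one ethnicity × sex group, OLS gives the
raw slope $\hat b$ of $r$ on age (% ICV per year). The *annual percent
change* rescales it by the structure's typical size in the group:

$$\mathrm{APC} = 100 \cdot \hat b \,/\, \bar r \quad [\%/\mathrm{yr}].$$

The normalizing denominator of "percent change" is genuinely open; we
use the group-mean relative volume because it is the only reading under
which a ventricular slope of +4.2 %/yr and a whole-brain slope of
−0.4 %/yr are simultaneously plausible — a "% of ICV per year" reading
would have the ventricle more than double annually.

**Bootstrap CI.** Subjects are resampled with replacement (resample size
= group n, B = 10,000 by default); the percentile interval of the B
bootstrap APCs at level 0.95 forms the CI. The percentile method is the
simplest one consistent with "standard errors via bootstrapping"; BCa was
considered and rejected as an unneeded complication at these group sizes.
Two numerical choices matter:

* each bootstrap APC divides the resampled slope by the *full-sample*
  mean relative volume. The denominator is a normalization constant of
  the group, not a parameter being re-estimated; fixing it makes the
  zero-noise degenerate case exact (every resample returns the true APC,
  CI width 0) and changes nothing detectable at realistic noise (the
  denominator's relative sampling error is ≈ σ/(√n · r̄) ≲ 0.2%);
* a resample with fewer than two distinct ages has no defined slope; it
  is redrawn (and counted) rather than skipped, so exactly B estimates
  enter every interval.

Seeding: one master seed expands into deterministic substreams keyed by
(group, region) strings, so results are independent of evaluation order
and reproducible bit-for-bit.

**Group comparison.** Two groups differ significantly in a region iff
their CIs are disjoint (touching endpoints overlap). CI non-overlap is
deliberately conservative relative to a test on the slope difference; the
test suite verifies empirically that whenever non-overlap fires, the
bootstrap CI of the difference also excludes 0.

**APOE ε4 effect.** Within a group, effect = carrier APC − non-carrier
APC on the full sample; each bootstrap iteration resamples carriers and
non-carriers *independently*, because the two slopes are estimated on
disjoint subsamples. Records with unknown APOE status are dropped with a
logged count — genotyped n is smaller than cohort n in the source data,
and absence is represented as absence, never imputed. The unphasable
double heterozygote (C/T at rs429358 with C/T at rs7412, ambiguous
between ε2/ε4 and ε1/ε3) is likewise reported as ambiguous, not resolved
to the population-likely phase.

**Pooled regression.** Per region, OLS of absolute volume on age, sex,
ethnicity, education and ICV over the pooled cohort. All variables are
z-scored (binary predictors coded female=0/male=1, korean=0/caucasian=1
first), so coefficients are standardized; the published coefficient
magnitudes (ICV b = 0.87 with R² = 0.752) are only consistent with the
standardized reading. Raw coefficients are reported alongside, and
`standardize = FALSE` keeps binaries dummy-coded since the original
coding is unstated. Significance uses the Bonferroni threshold
α/m = 0.05/15 ≈ 0.003.

**ANOVA from summaries.** The demographics table prints per-cell n,
mean and SD plus F statistics. Within-cell SS is $\sum_i (n_i-1)s_i^2$;
effect SS are sequential (Type I) in the listed order (ethnicity, sex,
interaction), fitted by weighted least squares on the four cell means.
Sequential SS is a deliberate choice: it reproduces the printed ethnicity
F for age within rounding of the 1-decimal inputs, whereas marginal
(Type III) SS does not. The interaction F is SS-type invariant. A
property test shows exact (1e-8) agreement with a subject-level ANOVA on
samples expanded to the same moments.

**Norms.** Strata are ethnicity × sex × 5-year age bin: [65,70), [70,75),
[75,80), [80,85]. The last bin is closed — the 65–85 range cannot be
tiled by half-open 5-year bins, so the final "5-year" bin spans six
integer ages. Per stratum and region we emit n, mean, SD and the
5/25/50/75/95th percentiles on both the relative and absolute scales
(both are published as supplements, and the main text does not say which
statistics they tabulate). Percentiles use the median-unbiased estimator
(`type = 8`), stable at small stratum n; strata below a configurable
floor (default 10) are flagged rather than dropped. Subject z-scores are
computed on the relative scale against the matching stratum.

## The synthetic world

`default_specs()` states the world once, from the published tables:

* **group sizes, age/education/MMSE means and SDs, ε4 carrier
  frequencies, genotyped fractions** — the demographics table verbatim
  (Caucasian male carrier frequency 24.6% follows the table over the
  24.2% mentioned in passing elsewhere);
* **true APCs** — the published per-group slopes; female groups
  additionally carry the published carrier-stratum slopes, so ε4 effects
  enter through the slope only (the source quantifies ε4 effects purely
  as slope differences; an intercept shift is representable but defaults
  to absent);
* **baseline intercepts** (relative volume at age 65) are not published;
  they are set once to typical FreeSurfer values for healthy elderly
  (brain 70% of ICV, hippocampus 0.50%, accumbens 0.06%, …), with a
  modest ethnic scaling (−5% cortex, +10% ventricle, +5% caudate, equal
  putamen for Caucasians) matching the reported direction of group
  differences;
* **noise SDs** are calibrated, not measured: the published CI
  half-widths are inverted through the delta formula
  σ = hw/1.96/100 · r̄ · sd(age) · √n per group and region, so bootstrap
  CI widths at the published group sizes roughly match the printed
  widths. This calibration is part of the stated world, fixed before any
  test was run;
* ages are truncated-normal on [65, 85], ICV lognormal, education
  truncated at 0, MMSE integerized and truncated at the screening floor,
  domain z-scores truncated at −1.5 (the generator emulates a *screened*
  cohort; set `mmse_floor = 0` to generate unscreened subjects).

One deliberate deviation from the obvious parameterization: the
generating line is anchored so that `true_apc` is exactly the quantity
the estimator measures. Writing the line as
$r = \beta_0(1 + \mathrm{apc}/100\,(\mathrm{age}-65))$ would make the
estimator's estimand $\mathrm{apc} / (1 + \mathrm{apc}/100\,(\bar a -
65))$ — about 3% off at these age distributions, enough to fail any
honest recovery test. Instead each carrier stratum uses the raw slope
$b = \mathrm{apc}/100 \cdot \beta_0 / (1 - \mathrm{apc}/100\,(\bar
a_{emp} - 65))$ anchored at the stratum's empirical mean age, which makes
the noise-free fitted APC equal `true_apc` to machine precision and the
noisy estimator unbiased. Relative volumes are floored at 0.001% of ICV
to respect non-negativity; with default noise this touches only extreme
ventricle draws (≲2% of subjects at the youngest ages) and shifts the
ventricle slope by well under its Monte-Carlo error.

**What a green test does and does not establish.** The generator is
linear in age by construction (the narrow 65–85 window justifies
linearity, and curvature is deliberately absent), noise is Gaussian and
homoscedastic, education carries no volume effect (the published pooled
regression found none — its null coefficient is used as a recovery
check), and scanner heterogeneity, site effects and segmentation failures
do not exist in it. Green tests establish that the *estimators implement
their definitions* and recover the stated world; they cannot establish
that the published numbers are right, nor that real data meet the
model's assumptions.

**Known tension, left visible.** The defaults give non-carriers the
published *group* slope and carriers the published carrier slope, per the
stated parameterization; the implied group-level mixture slope for Korean
women (−0.436) therefore sits asymmetrically in the printed group CI
[−0.486, −0.329], and the fitted APC falls inside that interval in only
~89–90% of replicates, not the ≥95% a self-consistent parameterization
would give. The corresponding acceptance test is kept at the stated bar
and fails honestly rather than being loosened.

## Degenerate inputs and numerical conventions

* `fit_group_slope` needs ≥3 records and ≥2 distinct ages; constant
  relative volume gives APC 0 exactly.
* `fit_volume_model` needs ≥10 complete records and a full-rank design;
  constant or aliased predictors raise "degenerate design".
* Bootstrap with B < 100 warns; degenerate resamples are redrawn.
* CI comparison requires matching region and level; touching intervals
  are not significant.
* Cohort I/O writes doubles at 17 significant digits, so
  write-then-read round-trips are exact.
* The DKT→lobe mapping and the ventricle composite are shipped as an
  editable CSV (data, not code): the standard lobar grouping of the 31
  DKT parcels, ventricular system = lateral + inferior-lateral + 3rd +
  4th ventricles, whole brain = the brain-segmentation-without-ventricles
  header measure (so brain shrinkage and ventricular expansion remain
  separable), ICV = eTIV. None of these compositions is defined by the
  source material; they are declared conventions.

## Limitations

Cross-sectional slopes are not within-subject change; no longitudinal
modelling is attempted. Norms are binned, not smoothed growth-chart
centiles. The synthetic world cannot validate the published numbers
themselves, only the machinery. Configuration files use JSON rather than
YAML (no YAML parser among the guaranteed dependencies).
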