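---
title: "Methods: LE8 scoring and design-based trend estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LE8 scoring and design-based trend estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(le8trends)
```

# What the package computes

`le8trends` implements the American Heart Association's *Life's Essential 8*
(LE8) construct for quantifying cardiovascular health (CVH) in adults, and
the survey machinery needed to estimate its population trends from serial
cross-sectional examination surveys of the NHANES type. Eight metrics —
diet, physical activity, nicotine exposure, sleep health, body mass index,
blood lipids, blood glucose, and blood pressure — are each scored 0–100
from raw measurements via published points ladders, and the overall CVH
score is the arithmetic mean of the eight. Scores are categorized as poor
(0 to <50), intermediate (50 to <80), or high (80–100).

Population quantities are estimated with full design-based inference:
weighted means with Taylor-linearized standard errors over strata and
primary sampling units (PSUs), direct age standardization to a fixed
standard population, covariate-adjusted weighted linear regression on the
cycle index for trend testing, and Rao–Scott corrected chi-square tests for
demographic homogeneity across cycles.

# The scoring model

## HEI-2015 diet quality

Diet quality is the Healthy Eating Index-2015: 13 components scored
piecewise-linearly from dietary *densities* — amounts per 1,000 kcal for
the cup/oz/gram components, percent of energy for added sugars (16 kcal
per teaspoon) and saturated fat (9 kcal per gram), and the
(MUFA + PUFA)/SFA ratio for fatty-acid quality. Nine adequacy components
rise from 0 points at zero density to full points at the standard; four
moderation components fall from full points at or below the favorable
standard to zero at the unfavorable one. The total is the sum, bounded in
[0, 100]. Two useful identities follow directly and are exploited by the
tests: a recall meeting every adequacy standard and every favorable
moderation standard scores exactly 100, and a recall with positive energy
but zero intake of everything scores exactly 40 (the four moderation
maxima). The standards table ships as data
(`hei_standards()`, or `inst/extdata/hei2015_standards.json`), so other
HEI vintages are drop-in replacements.

Two conventions deserve note. With zero saturated fat the fatty-acid ratio
is taken as its limit: full points when any unsaturated fat is present,
zero points when there is no fat at all (which keeps the zero-intake
identity exact). Person-level HEI is the mean of the per-recall totals
over the available recalls, requiring `diet_min_recalls` (default 2;
setting 1 reproduces the one-recall sensitivity analysis). Averaging
intakes before scoring is available as `hei_method = "pooled"`; the
default averages totals because a recall is the natural scoring unit and
the alternative is not separately identified by the published analyses.

## The eight ladders

Every ladder and deduction lives in `scoring_tables()` as editable data.
Highlights of the conventions chosen where printed descriptions are
ambiguous at the boundaries:

* All continuous ladders are half-open: a value equal to a threshold falls
  in the higher interval. Categories likewise: poor `[0, 50)`,
  intermediate `[50, 80)`, high `[80, 100]`.
* Physical activity totals moderate plus twice vigorous minutes/week (the
  doubling is configurable via `vigorous_multiplier`).
* Diet is scored by weighted percentiles of person-level HEI in a
  reference population (25th/50th/75th/95th cutoffs mapping to
  0/25/50/80/100); a value equal to a cutoff takes the higher band, so a
  degenerate population with all-equal HEI scores 100 everywhere. The
  reference defaults to the pooled analyzed cohort across cycles
  (`diet_ref = "cycle"` switches to per-cycle references); the published
  analyses do not state which was used.
* Nicotine: never 100; former by quit duration 75/50/25; any inhaled
  product in the past 30 days is current use (0). Household secondhand
  smoke deducts 20 from a positive base. Non-inhaled tobacco is not
  counted by default.
* Blood pressure averages the 2nd and 3rd of three readings (1st and 2nd
  of two; the single reading if one), stages by the worse of SBP and DBP,
  and deducts 20 for antihypertensive treatment. Lipids deduct 20 for
  lipid-lowering treatment. Deductions never push a score below zero.
* Glucose: without diabetes, fasting glucose <100 scores 100 and 100–125
  scores 60, falling back to HbA1c (<5.7 / 5.7–6.4) when fasting glucose
  is missing. Diabetes — history, glucose-lowering medication, fasting
  glucose ≥126 mg/dL, or HbA1c ≥6.5% — is scored on HbA1c control
  (40/30/20/10/0 at <7/8/9/10/≥10). The printed ladder does not say how a
  person with diabetic-range glycemia but no history should score; we
  follow the AHA algorithm and treat them as having diabetes. With
  diabetes and a missing HbA1c the score is missing (such records are
  removed by the exclusion cascade).

## Exclusion cascade

`apply_exclusion_cascade()` applies ordered predicates — age >79, missing
any CVH-metric input, missing demographics, pregnancy, breastfeeding,
self-reported CVD history — excluding each record at its *first* failing
rule, so stage counts are sequential and mutually exclusive and the
conservation identity (initial − Σ excluded = final) is exact. "Missing a
CVH metric" is defined operationally: one of the eight scorers would
return missing on that record's inputs. This makes the cascade and the
scorers impossible to drift apart. Permuting the rules may move per-stage
counts but never changes the retained set, a property the tests check.

# Design-based estimation

The mean estimator is the weighted ratio $\bar y = \sum w_i y_i / \sum
w_i$. Its variance is estimated by Taylor linearization: residual
contributions $z_i = w_i (y_i - \bar y)/\sum_D w$ are totaled per PSU, and
within each stratum $h$ with $n_h$ PSUs the between-PSU sum of squares is
scaled by $n_h/(n_h - 1)$ and summed over strata. Subgroup (domain)
estimates zero the contributions outside the domain but keep the full PSU
structure, as survey practice requires. Confidence intervals use t with
df = PSUs − strata; the published analyses do not state their CI method,
and this is the standard survey convention. Strata with a single sampled
PSU fail by default; `lonely_psu = "collapse"` (merge with the adjacent
stratum) and `"center"` (deviations from the grand PSU-total mean) are
available.

Direct age standardization combines the three band estimates (20–39,
40–64, 65–79; standard weights 0.386/0.446/0.168, the 2018 US adult
distribution) as a fixed-weight linear combination. Its variance is the
weighted sum of band variances treating bands as independent — an
approximation (bands share strata), documented here as an assumption; the
published analyses do not state their variance method for standardized
estimates. Standardized category distributions standardize each category
indicator and renormalize to sum to one, logging the renormalization
delta.

Trends are tested person-level: survey-weighted least squares of the
outcome on the ordered cycle index (0…6) plus categorical covariate
indicators (sex, age group, race/ethnicity, education, marital status,
income category), with a stratum/PSU cluster-robust sandwich variance and
t inference on the design df. With two cycles and no covariates the slope
reduces exactly to the difference in weighted means, a tested identity.
No multiple-testing adjustment is applied, matching the published
analysis. The chi-square homogeneity test uses the Pearson statistic on
weighted proportions with a first-order Rao–Scott correction (the mean
generalized design effect of the cell proportions); without a design it
reduces to the classical Pearson test.

# The synthetic cohort generator

The generator exists so the whole pipeline is testable at desk scale with
known truth. Per cycle it draws:

* a stratified design (default 15 strata × 2 PSUs per cycle, balanced
  randomized allocation so every PSU is sampled — a 2-PSU stratum with an
  empty PSU would make the design inestimable); small PSU-level random
  effects on BMI, blood pressure and sleep create intra-cluster
  correlation;
* demographics from a *sampling* mix that oversamples minorities and
  older adults, with base weights equal to the population-to-sampling
  probability ratio times lognormal dispersion (`weight_dispersion`,
  default 0.3), so weighted compositions match the declared population
  mix;
* metric inputs from documented marginals approximating US adults
  (lognormal BMI around 28.3 kg/m², normal sleep around 7.1 h, normal
  non-HDL around 145 mg/dL, correlated SBP/DBP with three noisy readings,
  lognormal fasting glucose with linked HbA1c, zero-inflated lognormal
  activity minutes, lognormal dietary densities). Inputs are drawn
  independently of demographics: marginal realism suffices because the
  validation targets scoring and estimation machinery, not joint
  structure — which also means subgroup *differences* in synthetic data
  are pure noise, unlike real surveys;
* measurements rounded to instrument precision (integer mmHg, 0.1 kg,
  etc.), which incidentally makes CSV round trips exact;
* missingness, completely at random, at configurable rates (defaults:
  both recalls jointly missing 10%, each recall 5.5%, small laboratory
  and questionnaire rates), emulating the strong correlation of recall
  missingness in real data.

Trends are injected in two modes. Raw-scale slopes shift a measurement
additively per cycle; the implied score-scale ground truth is computed by
scoring a quasi-population (`gt_n`, default $10^6$) with common random
numbers across cycles, so zero-trend configurations have *exactly*
constant ground-truth means. Score-scale slopes are supported for BMI:
the expected ladder score of a lognormal BMI is available in closed form
in the location parameter, which `uniroot` inverts per cycle, so an
injected slope of, say, −1.0 score/cycle is exact with no Monte-Carlo
error. This closed form is what makes "recover the injected score slope"
a well-posed parameter-recovery experiment. The clamping of BMI to
[14, 70] does not disturb the closed form because the clamp points lie
inside the extreme ladder cells.

MCAR missingness, independence of metrics from demographics, and the
absence of nonresponse adjustment or raking are the main ways the
generator is *less* than real NHANES data; passing tests therefore
validate the algorithms and their implementation, not the
representativeness machinery of any particular survey.

# Problem sizes and numerical choices

The parameter-recovery experiment uses 7 cycles × 5,000 persons × 20
replicate seeds with an injected −1.0 score/cycle BMI trend, adjusted for
all six covariates; the estimate is compared with truth at 2 Monte-Carlo
standard errors. The size (type-I error) experiment uses 500 replicates
of a reduced design — the default 15-strata structure with 120 persons
per cycle, no missingness, unadjusted — chosen because cluster-robust
variances are known to be anti-conservative when strata are few, so the
reduced design thins the sample, not the design. Unit tests use smaller
cohorts (hundreds per cycle) and reduced quasi-populations; these sizes
are the package's chosen desk-scale experiment definitions.

Other numerical conventions: weighted percentiles take the smallest value
whose cumulative normalized weight reaches p (deterministic under ties,
with a 1e-12 guard against floating-point undershoot at p = 1); a zero
sandwich SE (exactly fitted outcome) with a numerically-zero coefficient
yields p = 1; collinear covariate blocks are reported by name rather than
silently aliased; the cascade treats an NA predicate as "not excluded"
(missingness is handled by the dedicated missing-input rule).

# Known limitations

* The weight column is a single configured analysis weight; the package
  does not construct fasting-subsample or day-2 dietary weights, and
  which weight is appropriate when fasting measures and two recalls are
  both required is genuinely ambiguous in serial NHANES practice — the
  name-mapping layer decides which source weight feeds the canonical
  column.
* Replicate-weight (BRR/jackknife) variance methods and raking are out of
  scope; variance estimation is Taylor linearization only.
* The independent-band variance approximation for standardized estimates
  slightly misstates SEs when bands share PSUs.
* Reporting age bands default to the 3-band standardization scheme; a
  finer band (e.g. 20–34) can be configured but is not the default.
* The generator's joint distribution is deliberately simplistic (see
  above).
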