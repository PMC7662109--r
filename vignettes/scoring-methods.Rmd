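---
title: "Scoring GLILD chest CT: methods, models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring GLILD chest CT: methods, models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glildscore)
```

## The problem

Granulomatous lymphocytic interstitial lung disease (GLILD) is a serious
complication of common variable immunodeficiency disorders (CVID),
radiologically characterised by ground-glass opacities (GGO), nodules and
reticulation, usually alongside airway disease (bronchiectasis, bronchial
wall thickening, mucus plugging). Monitoring it requires semi-quantitative
chest-CT scoring systems whose outputs can serve as study outcome
measures. `glildscore` implements the two scoring systems developed for
CVID — a fast whole-lung system (here called the *Baumann* method) and a
detailed lobe-wise system derived from the cystic-fibrosis CT score (the
*Hartmann* method) — together with everything needed to evaluate them:
component/composite scores, phenotyping, observer-agreement analysis,
longitudinal trend models, and a synthetic cohort generator with known
ground truth.

## The scoring schemas

Both methods treat the lingula as a sixth, separate lobe
(RUL, RML, RLL, LUL, lingula, LLL).

* **Baumann** scores 13 abnormalities for the whole lung. Extent is the
  number of affected lobes (0–6); severity grades exist for
  bronchiectasis (0, 1, 1.5, 2, 2.5, 3) and bronchial wall thickening
  (0–3); nodules get a three-level size category; reticulation and GGO
  subtypes and the largest lymph node (mm) are noted. 22 values per CT.
* **Hartmann** scores 13 abnormalities per lobe, each with an extent
  grade (0–3) and a severity grade (0–3, with half grades for
  bronchiectasis), 26 values per lobe, plus a single lymphadenopathy
  presence item (short-axis diameter ≥ 10 mm): 26 × 6 + 1 = 157 values
  per CT.

The original score sheets are not public. The canonical schemas shipped
with the package (`inst/extdata/schemas/`) are *reconstructions*
constrained by every published fact (item lists, scales, value totals of
22 and 157, separate emphysema/bullae/cysts rows, reticulation vs
distortion). Three Baumann qualifiers are not pinned down by the
published description; they are shipped as placeholders flagged
`reconstructed: true` in the YAML, so a corrected sheet replaces them via
configuration, not code. Traction bronchiectasis is excluded from
bronchiectasis by definition, and the schema validator rejects any
attempt to add it as an item.

```{r}
canonical_schema("baumann")
canonical_schema("hartmann")
```

## Component and composite scores

Every score is expressed as a percent of its maximum possible value, so
scores are bounded in [0, 100] regardless of method. For bronchiectasis
and bronchial wall thickening, extent is weighted by a severity
multiplier before normalisation:

| severity grade | 1.0 | 1.5 | 2.0 | 2.5 | 3.0 |
|---|---|---|---|---|---|
| bronchiectasis multiplier | 1.00 | 1.25 | 1.50 | 1.75 | 2.00 |
| wall-thickening multiplier | 1.00 | — | 1.25 | — | 1.50 |

Grade 0 contributes 0. The bronchiectasis grade domain carries the half
grades {1.5, 2.5} because the multiplier table enumerates five severity
levels; wall thickening has three.

For Baumann, raw = extent × multiplier(severity), max = 6 ×
multiplier(top grade); for Hartmann the products are summed over lobes,
max = 6 × 3 × multiplier(top grade). All other abnormalities use extent
only — the published weighting covers exactly these two airway items, and
we implement exactly what is printed; the remaining severity grades are
kept for reporting, never for weighting. Consequently the two methods are
*not* comparable one-to-one (the whole-lung score reflects the worst
airways, the lobe-wise score an average), and no operation in this
package mixes their values.

```{r}
sch <- canonical_schema("baumann")
sh <- sheet_from_values(sch, c(bronchiectasis_extent = 3,
                               bronchiectasis_severity = 2))
component_score(sh, "bronchiectasis", sch)   # 3 x 1.50 / (6 x 2.00) = 37.5%
```

Three composites are defined: **GLILD** = GGO + nodules + reticulation;
**airway disease** = bronchial wall thickening + bronchiectasis + mucus
plugging; **total disease** = all extent-scored abnormalities. Composite
raw and maximum scores are exact sums over constituents. Trapped air is
excluded by default (its assessment needs expiratory scans, which
retrospective cohorts rarely have); the exclusion is a runtime option.
Two further choices were genuinely open: the lymph-node measurement never
enters a composite (it is not an extent), while the Baumann
lymphadenopathy *extent* item does enter the total by default — both are
configurable via `exclusions`; and nodule size categories never weight
the nodules component (no published multiplier exists).

Phenotyping follows the composite definitions: a scan is GLILD-positive
iff any of GGO/nodules/reticulation has a positive score, and
airway-positive iff any airway constituent does. Enlarged lymphadenopathy
means measured mm ≥ 10 (threshold configurable) for Baumann and the
scored presence item for Hartmann. `cohort_report()` produces the four
standard cohort tables (prevalence ranking, maximal-severity distribution
among positives, median/IQR/range of each score, and the GGO × nodules ×
reticulation Venn partition of GLILD-positives). Reports round percents
to whole numbers (one decimal for score distributions); internal
computations keep full precision. Ties in most-recent-scan selection are
broken deterministically by lexicographically largest scan id.

## Observer agreement

Agreement uses the two-way mixed-effects, single-measurement,
*consistency* intraclass correlation, ICC(C,1): with subjects as rows and
raters as columns,

$$\mathrm{ICC}(C,1) = \frac{MS_\mathrm{rows} - MS_\mathrm{error}}
{MS_\mathrm{rows} + (k-1)\,MS_\mathrm{error}}$$

where the mean squares come from the two-way ANOVA without interaction.
Consistency is insensitive to an additive rater shift, which is the
appropriate relationship when observers may differ in calibration but
rank severity alike. Interpretation bands: < 0.40 poor, 0.40–0.59 fair,
0.60–0.74 good, ≥ 0.75 excellent. Two boundary choices are documented
here: the half-open interval [0.74, 0.75) is banded *good* (the printed
band edges leave it ambiguous), and negative estimates are reported as
computed, not truncated at zero — truncation would bias the
variance-component recovery checks. A table whose variance vanishes after
removing the rater effect has no defined ICC and raises an explicit
error; `agreement_study()` converts that into an `NA` row. The
absolute-agreement form ICC(A,1) is available behind
`icc_consistency(..., type = "agreement")` for sensitivity analysis,
never as a default.

`agreement_study()` pairs sheets by scan id across two rater labels. An
intra-observer design is expressed the same way: the re-scored batch is
given a second rater label for that observer. ICCs are computed on
percent scores (composites have no raw-scale common to both methods).

## Longitudinal trends

Score trajectories over repeated scans are modelled on the (possibly
transformed) percent scale as a linear function of months since the
patient's first analysed scan. Two engines are provided:

* **`engine = "lmm"`** (default): linear model with a patient-level
  random intercept, fit by REML; the slope is tested by a Wald test with
  Satterthwaite degrees of freedom. This engine supports the
  likelihood-ratio test below, which a purely estimating-equation
  approach does not.
* **`engine = "gee"`**: Gaussian generalized estimating equations with an
  exchangeable working correlation and robust (cluster sandwich)
  standard errors, implemented directly in the package; an independence
  structure is the `rho = 0` special case. On balanced synthetic data the
  two engines agree to within 1% on the slope (checked in the tests).

The square-root transform (`transform = "sqrt"`) is provided for scores
whose residual variance grows with the mean — bronchiectasis being the
classic case; the fitted curve is reported on the transformed scale.
Nonlinearity is assessed by a likelihood-ratio test comparing linear time
against a natural cubic spline in time with 3 degrees of freedom (knots
at the quantiles of observed times, `splines::ns`), both models fit by
maximum likelihood with a random intercept; the reference distribution is
chi-square with 2 df. Three df is the parsimonious choice given 2–9
visits per patient; more knots are not estimable at such visit counts.
Patients contribute from their second scan onward; the significance
threshold is 0.05 two-sided and no multiplicity correction is applied
across outcomes (the report notes this). Time zero is each patient's
first analysed scan.

Degenerate inputs are handled explicitly: exactly linear noise-free data
(zero residual variance) falls back to OLS with cluster-robust errors
rather than failing; a sqrt transform on negative values and datasets
with fewer than two multi-visit patients are errors.

## The synthetic cohort generator

`simulate_cohort()` emulates the *shape* of a retrospective GLILD CT
cohort, not any real patient data:

* **Cohort**: `study_like_config()` fixes 138 patients of whom exactly 81
  have ≥ 2 scans (the rest one), scans per patient on 1–9, log-normal
  inter-scan gaps with a 12-month median and an IQR near 5–24 months
  (`meanlog = log 12`, `sdlog = 1.03`, from matching the quartiles).
* **Disease**: per patient and abnormality, presence is Bernoulli with
  the configured prevalence (defaults chosen once to mirror a GLILD
  cohort: bronchiectasis 0.82, wall thickening 0.67, nodules 0.76, GGO
  0.70, reticulation 0.65, lymphadenopathy 0.50, the rest lower);
  severity comes from ordinal distributions concentrated on mild grades;
  lobes are involved independently with probability 0.5 (at least one).
* **Progression**: a latent drift per month acts on extent (lobe count or
  per-lobe grade) with rounding and reflection at the scale limits; the
  default drifts only bronchiectasis (0.02 lobes/month ≈ 1.2 lobes over
  five years), mirroring the one abnormality expected to progress
  detectably. Because grades are discrete, the drift is exactly linear
  only on the latent scale; `simulate_score_trajectories()` generates
  continuous-outcome trajectories under the random-intercept model for
  calibrating the longitudinal engines against an exactly known slope.
* **Observers**: disagreement is adjacent-grade confusion — with
  probability `confusion` an ordinal value moves one step up or down its
  allowed set (clipped at the ends); a per-observer bias shifts the
  up/down probability; mm measurements get rounded Gaussian noise.
  Varying `confusion` spans the ICC range reported for such scores
  (roughly 0.05–0.93). With all noise off, both observers emit the truth
  byte-for-byte, which anchors the zero-noise fidelity tests.
* **Determinism**: each patient has a substream seeded from
  `seed × 1000003 + patient index`, so the same seed reproduces the
  cohort exactly and growing the cohort never reshuffles earlier
  patients.

What the generator does **not** model: spatial correlation between lobes,
correlation between abnormalities (a patient's GGO and reticulation are
independent given prevalence), scanner/protocol heterogeneity,
treatment effects, and observer drift over time. Passing tests therefore
show that the *machinery* (scoring arithmetic, ICC estimation, trend
inference) is correct under known conditions — they do not certify
agreement or progression estimates on real cohorts, where the published
cohort-level values (prevalences, Table-style medians, ICCs, the
bronchiectasis slope) depend on the original CT scans and are explicitly
out of reach.

## Validation problem sizes

The test suite validates: score arithmetic against an independent naive
re-scorer on 1,000 random valid sheets per run; ICC against a textbook
ANOVA oracle to 1e-10 on small tables; observer-model ICC recovery at 100
subjects averaged over 200 replicates against a 4,000-subject Monte-Carlo
truth (±0.05); type-I error of the slope test at 5% over 200 simulated
null cohorts of 80 patients (binomial tolerance); slope recovery at the
study-like design (81 patients, 2–9 visits); and byte-identical artifacts
under a fixed seed. These sizes were chosen as the smallest at which the
Monte-Carlo error is well below each tolerance.

```{r, eval = FALSE}
co <- simulate_cohort(study_like_config(seed = 1))
rep <- cohort_report(most_recent_sheets(co$truth$sheets), co$schema)
head(rep$prevalence)
```

## Known limitations

* The canonical schemas are documented reconstructions; three Baumann
  qualifier items are placeholders awaiting the original sheet.
* ICCs are point estimates (no confidence intervals), matching how such
  agreement tables are usually reported; a bootstrap could be added.
* The GEE engine assumes Gaussian outcomes on the (transformed) percent
  scale; heavily zero-inflated scores are better served by the rank-free
  prevalence tables.
* Whether the original total-disease composite included lymphadenopathy
  is ambiguous in the source material; the default documented above is a
  package choice, not an assertion about the original analysis.
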