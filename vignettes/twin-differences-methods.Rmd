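---
title: "Methods: twin-differences specification curves for parenting and child antisocial behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: twin-differences specification curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the design answers

Lower parental nurturance reliably accompanies higher child antisocial
behavior (ASB), but a correlation in family data cannot say whether
parenting shapes the child, the child's (partly heritable) behavior
evokes the parenting, or family-wide confounds drive both. The
child-based twin-differences design separates these readings. Within a
monozygotic (MZ) pair, genes and shared environment are identical, so a
correlation between co-twin *differences* in nurturance and co-twin
differences in ASB can only reflect child-specific environmental
processes. Dizygotic (DZ) pairs share on average half their segregating
genes, so genetic mediation leaves a within-pair signal in DZ but not MZ
pairs. The inferential logic is the significance pattern across three
analyses:

| phenotypic | MZ diff | DZ diff | reading |
|---|---|---|---|
| sig | sig | sig | environmental pathway |
| sig | ns | sig | genetic (evocative rGE) |
| sig | ns | ns | genetic + shared-environmental confounds |
| ns | – | – | no association to decompose |
| sig | sig | ns | inconsistent (no coherent etiology) |

`classify_scenario()` implements exactly this mapping. The last row has
no biometric interpretation — a nonshared-environmental process must
appear in both zygosities — so it is labeled rather than forced into a
category.

## Generating model

`simulate_biometric_pairs()` draws each latent trait as
`a·A + c·C + e·E` from standard-normal factors with `a² + c² + e² = 1`.
Co-twins share A with weight 1 (MZ) or 0.5 (DZ; A is split into shared
and twin-specific halves of equal variance), share C fully, and have
independent E. Cross-trait correlations `r_A, r_C, r_E` are imposed
pairwise between like factors. This construction yields the closed
forms exposed as oracles (`expected_individual_cor()`,
`expected_diff_cor()`, `expected_cotwin_cor()`); the test suite holds
sampled correlations to within ±0.02 of them at 50,000 pairs per
zygosity, against an independent multivariate-normal construction of
the implied four-variable covariance matrix.

### Scenario presets

`scenario_preset()` fixes the variance shares and back-solves the
cross-trait correlation(s) so the individual-level correlation equals a
target (default magnitude 0.10, negative sign — the modest, negative
association typical of nurturance and ASB):

* parenting received: a² = 0.30, c² = 0.40, e² = 0.30 — close to
  meta-analytic estimates that roughly a quarter of the variance in
  parental warmth received by children is child-driven genetic and
  roughly 40% shared-environmental (Klahr & Burt, 2014);
* child ASB: a² = 0.55, c² = 0.25, e² = 0.20 — childhood ASB is strongly
  heritable with moderate shared environment;
* the purely genetic preset instead uses a² = e² = 0.5 and c = 0 for
  both traits, the textbook no-shared-environment case;
* the genetic + shared preset splits the target effect equally between
  the A and C routes.

These latent shares are interpreted net of measurement error, which the
measurement layer models separately. They are defaults of the
generator, chosen once; an infeasible combination (a back-solved
correlation exceeding 1 in magnitude) is rejected with an error.

## Measurement layer

`render_observed()` maps each latent trait to informant reports:
`sqrt(reliability)·latent + sqrt(1−reliability)·noise`, optionally
passed through `exp(skew·score)` and min–max rescaled into the
instrument's range, with reports deleted completely at random. Key
defaults (`default_measurement_models()`):

* **reliability 0.7** for every report. The moderate inter-informant
  correlations such instruments show (roughly 0.2–0.6) are consistent
  with single-informant validities near `sqrt(0.5)`–`sqrt(0.7)`; 0.7 is
  a round mid-range value and is a single argument if you disagree.
  Before any skew transform the observed cross-trait correlation is the
  latent one attenuated by `sqrt(rel_x · rel_y)` — a contract the tests
  check at reliability 0.64.
* **skew rate 0.6** for ASB scores only, which puts raw-score skewness
  in the 1.3–3.9 range typical of child ASB scales; `log_normalize()`
  (`log(1+x)`) then reduces it, as in real analyses.
* **missingness** mirrors typical informant coverage: ~99% mother, ~83%
  father and teacher, ~97–99% twin reports. It is missing completely at
  random, per report — the simplest mechanism consistent with coverage
  rates; informative missingness and rater bias are deliberately out of
  scope.
* **study scale**: 426 MZ and 604 DZ pairs, the size of a large
  middle-childhood registry sample combining population-based and
  under-resourced arms.

What the generator does *not* emulate: item-level structure (scale
scores only), rater-specific bias or halo effects, sibling
interaction/contrast effects, non-random missingness, and age/sex
structure. Passing tests therefore demonstrate correctness of the
machinery and adequate power under clean conditions, not robustness to
those real-data features.

## Analysis variables

`build_analysis_table()` derives every column of the specification
grid. Composites (*adults*, *family*, *all* for ASB; *adults*, *all*
for nurturance) average the members' **standardized** scores and are
restandardized. Members come from different instruments with different
ranges (parent checklist, teacher form, child interview), so averaging
raw scores would weight members by their scale variance; standardizing
first makes the "average across informants" rule coherent, and is
applied uniformly rather than only to mixed-instrument composites. When
only one member is available it is used; when none is, the composite is
missing. The twin's reports of maternal and paternal nurturance are
averaged into a single twin-perception score before use. All columns
are standardized over the pooled sample (both zygosities, both twins)
prior to analysis; whether standardization should precede composite
formation is not determined by the design, so the chosen convention is
documented here and localized in one function.

## Statistical primitives

**Difference correlations.** Twins are randomly labeled A/B per family
(`assign_twin_labels()`); `dx = x_A − x_B`, likewise `dy`; families
missing any of the four values are excluded (counts retained). Because
the labels are arbitrary, the population mean of a difference score is
exactly zero, so `diff_correlation()` computes the correlation **about
the origin**, `Σdxdy / sqrt(Σdx²·Σdy²)`. This makes every estimate
invariant — bitwise — to the A/B seed (each family's `(dx, dy)` flips
jointly), which the suite asserts; a mean-centered correlation would
wobble with the arbitrary labeling. Confidence intervals use the Fisher
transform (`atanh(r) ± 1.96/sqrt(n−3)`) and p-values the Fisher z
statistic; a pair-count below 4 is an error, and zero within-pair
variance (no discordance) yields a flagged, undefined estimate rather
than a number.

**Phenotypic models.** `mlm_phenotypic()` fits a random-intercept model
(`lme4::lmer`, maximum likelihood, no random slopes) of standardized
ASB on standardized nurturance, clustering twins in families; Wald CIs
and normal p-values are reported. With zero between-family variance the
estimate equals the pooled correlation to within 1e-6 (boundary fits
are accepted silently). One property worth knowing: the random-intercept
slope is a precision-weighted blend of within- and between-family
regressions, so when the generating etiology makes those differ (e.g.,
a purely genetic association has no MZ within-pair component) the
fixed-effect beta is attenuated relative to the marginal correlation.
This mirrors how such models behave on real data and is why the slope
recovery test uses a ±0.04 band around the generating −0.10 rather
than a tight one.

**Missing data** are handled by complete-pairs analysis (difference
level) and available-case analysis (phenotypic level), with exclusion
counts logged. Full-information likelihood with robust standard errors
would be the alternative; it is intentionally not reproduced here, and
per-specification sample sizes carry the information into the weights.

**p↔z conversion.** `p_to_signed_z()` maps a two-sided p to
`qnorm(p/2, lower.tail = FALSE)` with the effect's sign attached
(p = 0.05 ↔ |z| = 1.96; p = 1 ↔ 0). P-values are floored at 1e-15 so a
single extreme specification cannot contribute an infinite z to an
average.

**Dependent correlations.** `steiger_dependent_z()` implements the
pooled-estimate Z1* statistic for two correlations sharing a variable
(`rbar = (r12+r13)/2`, `psi = r23(1−2rbar²) − rbar²(1−2rbar²−r23²)/2`,
`s = psi/(1−rbar²)²`, `z = (z12−z13)·sqrt(n−3)/sqrt(2−2s)`). Rather
than trusting the formula, the suite checks its type-I error rate over
10,000 trivariate-normal replicates at the null (n = 200,
r12 = r13 = 0.2, r23 = 0.3), requiring it inside [0.04, 0.06] at
α = 0.05. Non-positive-semi-definite correlation triples and n < 4 are
rejected; identical correlations return z = 0 even when the structure
is otherwise degenerate.

## The multiverse and its aggregation

`enumerate_specifications()` couples the measure and informant axes:
checklist measures cross with six informant variants while the
interview is twin-reported only, giving `(2·6 + 1)·5·2 = 130`
phenotypic cells and 260 twin-difference cells (by zygosity). The order
is lexicographic and the function is pure.

`summarize_curve()` reports medians (unweighted) and sample-size-
weighted means of estimates and CI bounds, the median p, the percentage
of specifications with p strictly below 0.05, and the weighted mean of
signed z-scores. Weights are the per-specification analyzed sample
(twins for phenotypic models, complete pairs for difference
correlations) — the quantity that actually varies across informants.
Medians are left unweighted deliberately: weighting is an averaging
concept, and a weighted median would change the reported statistic's
meaning. `decide_significance()` then requires all four indicators
(mean CI excludes 0, median CI excludes 0, median p < 0.05,
|average z| > 1.96) — signed z-scores are averaged first and the
absolute value taken afterward, so consistently negative curves
qualify; disagreement is conservatively nonsignificant. The rule is
monotone: strengthening every piece of evidence can never flip a
significant aggregate to nonsignificant (property-tested).

`compare_parenting_dimensions()` applies the dependent-correlation test
per matched specification and to the median/mean summary correlations.
The correlation between the two parenting difference scores and the
per-comparison n are explicit inputs (they are not derivable from two
marginal result sets); the summary-level comparison uses the median
per-spec n — a documented choice where no convention exists.

## Problem sizes and numerical choices

The scenario-recovery study (`scenario_recovery()`) runs 100 replicates
per preset at study scale. The twin-difference side uses the full
260-cell grid (a family-difference matrix is precomputed once per
replicate, making each correlation microseconds); the phenotypic side
uses a two-cell grid (all-informant checklist composite and interview,
all-informant nurturance, raw scores), because the individual-level
effect is strongly powered at n ≈ 2000 twins and each mixed model is
five orders of magnitude more expensive than a difference correlation.
These sizes make the whole recovery study a few minutes of CPU; they
are the package's reference experiment, not a constraint of the method.
Under these conditions the purely environmental scenario is recovered
as *environmental* in roughly 85–95% of replicates, and the two
non-environmental scenarios are essentially never misread as
environmental (the MZ curve has expectation zero there, and the
four-indicator rule holds its aggregate false-positive rate well below
10%).

Other numerical conventions: standardization uses the sample SD
(n−1); skewness uses the adjusted Fisher–Pearson estimator; sampled
correlations are clamped to [−1, 1] before `atanh`; `lmer` is run with
derivative checks off and singular fits accepted; seeds for every
stochastic stage derive from one master seed via exact integer
arithmetic below 2^31 (`substream_seed()`), so datasets are
bit-reproducible.

## Limitations

The pipeline infers etiology from significance patterns, inheriting the
asymmetry of that logic: low power turns "genetic" into "genetic +
shared environmental" more easily than the reverse (visible in the
recovery rates for the purely genetic preset at DZ-level power).
Complete-pairs analysis assumes missingness uninformative for the
within-pair association. The dependent-correlation comparison treats
summary correlations as if they were single-sample correlations at the
median n, a pragmatic approximation. And all validation is against the
generator's own assumptions — clean ACE structure, linear measurement,
MCAR missingness; none of it certifies behavior under rater bias,
informative missingness, or item-level artifacts.
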