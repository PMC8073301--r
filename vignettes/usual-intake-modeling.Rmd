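---
title: "Usual nutrient intake estimation and breakfast scenario modeling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Usual nutrient intake estimation and breakfast scenario modeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietshift)
```

## The problem

A single 24-hour dietary recall is a noisy measurement of what a person
*usually* eats: day-to-day (within-person) variation is large relative to the
variation in long-run average intakes across people. Population questions —
what fraction of children falls below an Estimated Average Requirement (EAR),
how would the distribution shift if a food were added to a meal — therefore
cannot be answered from single-day data directly; the within-person noise
inflates the tails and biases any cut-point prevalence. dietshift implements
the standard remedy: a measurement-error random-effects model fitted to
repeated recalls, combined with food-pattern scenario modeling at the
breakfast occasion.

The pipeline has five stages, each usable on its own:

1. **simulate** — generate a synthetic recall cohort with the assumed
   statistical structure;
2. **classify** — determine, per child, whether eggs are habitually eaten at
   breakfast and whether the day-1 breakfast meets the USDA CACFP component
   rules;
3. **apply** — add 1 or 2 egg nutrient-profile equivalents to eligible
   breakfasts under one of five scenarios;
4. **usual** — estimate the population distribution of usual intake per
   nutrient;
5. **adequacy** — convert usual-intake distributions into % below EAR / %
   above AI and fixed-cutoff prevalences, with uncertainty and change flags.

## The measurement-error model

Let $x_{pd}$ be the observed intake of one nutrient for person $p$ on recall
day $d \in \{1,2\}$. The model operates on a transformed scale:

$$g(x_{pd}) = \mu + \beta_2 \, \mathbb{1}[d=2] + b_p + \epsilon_{pd},
\qquad b_p \sim N(0, \sigma^2_B), \quad \epsilon_{pd} \sim N(0, \sigma^2_W),$$

where $g$ is a shifted Box–Cox transform
$g(x) = ((x + s)^\lambda - 1)/\lambda$. The person effect $b_p$ carries the
real between-person differences; $\epsilon_{pd}$ is the day-to-day
measurement noise; $\beta_2$ absorbs the common day-sequence effect
(second recalls tend to differ systematically from first ones). A person's
usual intake is the expectation of the back-transform over the within-person
error:

$$U(b) = E_\epsilon\!\left[ g^{-1}(\mu + \tfrac{\beta_2}{2} + b + \epsilon) \right],$$

evaluated by Gauss–Hermite quadrature. This expectation is what makes the
estimator mean-preserving on skewed data: a naive plug-in back-transform
$g^{-1}(\mu + b)$ omits the Jensen term and systematically underestimates the
population mean (the test suite asserts both the preservation and the
failure of the naive version). The $\beta_2/2$ term centers the usual intake
midway between the two recall-day conditions.

### Estimation choices

* **Transform selection.** $\lambda$ is chosen on the grid
  $\{0.01, 0.05, 0.10, \dots, 1\}$ to minimize the absolute moment skewness
  of the transformed daily values. The floor at 0.01 keeps the transform
  strictly increasing and numerically stable while approximating the log for
  strongly skewed nutrients. The shift $s$ is 0 when all values are
  positive, else half the smallest positive value — just enough to admit the
  occasional zero day without distorting the bulk of the distribution.
* **Variance components by method of moments.** $\beta_2$ is the day-mean
  difference; $\sigma^2_W$ is half the mean squared within-person difference
  after removing $\beta_2$; $\sigma^2_B$ is the person-mean variance minus
  its expected within-person contribution, floored at zero. Closed forms
  make every estimate hand-checkable (the unit tests include a two-person
  worked ANOVA); a likelihood fit could replace this behind the same
  interface but would buy little at survey sample sizes.
* **Back-transformation.** 9-point Gauss–Hermite quadrature of
  $g^{-1}$; the node count is configurable, and 9 nodes are ample for the
  variance magnitudes seen in log-scale dietary data ($\sigma_W \lesssim 1$).
* **Monte-Carlo population.** The usual-intake distribution is represented
  by $n_{mc}$ pseudo-persons: observed persons resampled with their survey
  weights, ages and sexes attached, each assigned a fresh $b \sim N(0,
  \hat\sigma^2_B)$. All summaries (mean, percentiles, cut-point fractions)
  are weight-aware. Seeded draws make every summary reproducible.
* **One-part model.** There is no consumption-probability part: all 37
  tracked nutrients are consumed near-daily, so the episodic two-part
  machinery would add parameters without information.
* **Day-1 weights.** Point estimates use day-1 survey weights; day-2 data
  enter only through the variance decomposition.
* **Covariates.** Only the day-sequence effect is modeled. The reported
  tables are age-aggregated, so age/sex covariates in the measurement-error
  model would change little while complicating the person-effect draw; ages
  and sexes still matter downstream, where DRI cut-points are person-matched.

### Uncertainty

Standard errors come from a stratified PSU bootstrap: primary sampling units
are resampled with replacement within strata (a PSU drawn twice contributes
its persons twice, re-keyed), the full estimator is re-run per replicate, and
the replicate SD is the SE (default $B = 100$; replicate $b$ uses seed
$\texttt{seed}+b$, so the stream is prefix-stable). The bootstrap is
estimator-agnostic, which matters because the adequacy metrics are highly
nonlinear in the data; it is validated against the closed-form SE of a
weighted mean. Confidence intervals are normal, $\pm 1.96\,\mathrm{SE}$,
truncated to $[0,100]$ for percentages — this choice reproduces published
worked-example bounds such as $(92.0, 0.7) \to (90.6, 93.4)$. Two scenario
estimates are called *meaningfully different* when their 95% CIs are
disjoint (shared endpoints count as overlap).

## Breakfast classification and scenarios

The CACFP rule table (a versioned YAML resource) encodes the USDA breakfast
minimums: fluid milk of an allowed type (4 fl oz unflavored whole at age 1;
4/6/8 fl oz unflavored 1%-or-skim at ages 2, 3–5, 6–18, with flavored skim
also allowed at 6–18), fruit/vegetables (0.25 oz eq at 1–2, 0.5 at 3–18) and
grains (0.5 oz eq at 1–5, 1.0 at 6–18). Amounts sum across items of a
category within the breakfast; milk counts only over items whose fat level
and flavoring are allowed for the age band; 2% milk is never compliant.
Classification is monotone in amounts and is verified against an
independently hand-coded oracle on an exhaustive grid.

Five scenarios are modeled: baseline (S0); +1 or +2 eggs when the breakfast
is habitually egg-free (S1, S2); +1 or +2 eggs when the day-1 breakfast is
CACFP compliant (S3, S4). Design decisions the data did not dictate:

* **"Habitually consumes eggs at breakfast"** is read conservatively as eggs
  on *any* reliable recall day's breakfast. Such children are left at their
  observed intake in S1/S2 (the alternative — excluding them from the
  population — is not implemented as the default because population-level
  usual intake should describe all children).
* **CACFP eligibility uses day 1 only**, matching the day-1-weight analysis;
  egg detection uses both days because habit is a person-level property.
* **Eggs are added to every recall day's breakfast** of an eligible person,
  not only day 1, so both days inform the within-person variance of the
  modified intake.
* **Breakfast skippers** never gain an egg (there is no occasion to add it
  to) but remain in the population denominator. Together with habitual egg
  consumers this attenuates population-mean deltas well below the per-egg
  constants — the pipeline logs eligibility counts so the attenuation is
  auditable.
* Added eggs are tagged `egg_synthetic` so modeled intake is separable from
  observed intake; the per-egg profile (147 mg total choline, 250 mcg
  lutein + zeaxanthin, remaining components from a standard whole-egg
  composition) is an overridable YAML resource.

## Adequacy metrics

For nutrients with an EAR, the cut-point estimate of inadequacy is the
weighted fraction of the usual-intake pseudo-population below the
age/sex-matched EAR; for AI nutrients, the fraction above the AI. Two fixed
cutoffs are built in: usual sodium above 2300 mg/day, and usual
saturated-fat energy share above 10% of calories. The energy share is
computed as a ratio of usual intakes ($9 \cdot \text{satfat}/\text{energy}$)
paired by pseudo-person — a deliberate simplification of a bivariate
measurement-error model, adequate because both usual intakes are stable
person-level quantities and their ratio varies far less than daily ratios.

Change flags versus baseline use the published convention: `*` for a
relative increase of at least 10%, `**` for at least 20%, always computed on
unrounded means. The DRI resource (EARs for phosphorus, protein, riboflavin,
vitamins A and D; AIs for total choline and alpha-linolenic acid, with
protein g/kg collapsed to absolute grams via DRI reference weights) is
configuration, not a claim — swap the YAML to change reference values.

### A note on reproducing printed reference tables

The packaged worked-example tables reproduce a published set of usual-intake
means, flags, and adequacy CIs. Recomputing flags from the *printed* (i.e.
rounded) means reproduces the printed annotations in all but four cells
across the two tables; those four are consistent with flags having been
computed on unrounded means before rounding for print (e.g. a printed
selenium change of +8.6% carrying a `*`). Similarly, recomputing CI-overlap
calls from the printed 95% limits reproduces the published `*` pattern only
for total choline; for the EAR rows the printed 95% intervals overlap, while
non-overlap of $\pm 1$ SE intervals matches the published pattern exactly.
The package implements the stated rules (unrounded-mean flags; 95%-CI
disjointness) rather than reverse-engineering the annotations; the
discrepancies are recorded by the acceptance checks as agreement
percentages.

## What the generator does and does not emulate

`generate_recalls()` draws daily intakes as
$\exp(\mu_k + b_{pk} + \epsilon_{pdk})$ per nutrient $k$, with energy derived
from the macronutrients at 4/4/9 kcal/g so the saturated-fat energy share is
meaningful. Default log-scale SDs are $\sigma_B = 0.3$ and $\sigma_W = 0.5$
— typical magnitudes for nutrient intakes in children — and the $\mu_k$ are
calibrated so population means sit at realistic daily intakes for US
children (within roughly 20% of published national baselines). Breakfasts
receive a fixed 22% share of the day's nutrients, split across milk,
fruit/vegetable, grain and (for the ~20% of children drawn as habitual egg
consumers) egg items; 15% of person-days skip breakfast; CACFP component
amounts are drawn to hit a 1.7% compliance rate, the share implied by
published national counts for this age range. Survey weights default to
uniform, with a lognormal option to exercise weighted estimators; persons
are spread over 4 strata with 3 PSUs each.

Deliberately **not** emulated: nutrient–nutrient correlations (beyond the
energy identity), survey oversampling and nonresponse weighting, recall
instrument biases, episodic consumption, seasonal effects. Passing tests on
this generator therefore demonstrate that the estimators recover the model
they assume and respect their invariants — not that real recall data meet
those assumptions.

## Problem sizes and numerical tolerances

The test and acceptance workloads use cohorts of 40–2000 persons,
Monte-Carlo sizes of 2000–10000, and 10–20 simulation replicates — sizes at
which method-of-moments error, Monte-Carlo error and the documented
assertions (mean bias below 2%, between-SD bias below 10%, closed-form CDF
agreement within 3 binomial SEs) are cleanly separable. Degenerate inputs
are defined, not errors: zero variance components collapse the usual
distribution to a point; an empty cohort is an empty (valid) collection; a
day without breakfast contributes a zero breakfast vector. Genuine errors —
missing nutrient columns, negative amounts, uncovered DRI bands, single-PSU
strata — abort with classed conditions naming the offender.

## Known limitations

* The between-person SD is estimated on the Box–Cox scale with
  $\lambda \ge 0.01$; for exactly lognormal data this inflates the SD
  slightly relative to the log scale (a few percent at typical magnitudes) —
  visible in, and bounded by, the recovery diagnostics.
* The saturated-fat share uses the ratio-of-usuals approximation above.
* Bootstrap weights are not rescaled within replicates (no
  finite-population or nonresponse adjustment).
* CACFP classification covers the milk/fruit-vegetable/grain component
  rules only; yogurt sugar limits, cooking-method rules and the
  meat-alternative frequency cap are out of scope, as is mapping real survey
  occasion codes to "breakfast".

## A worked example

```{r example, eval = FALSE}
cfg <- pipeline_config(
  generator = generator_config(n_persons = 400, seed = 2),
  scenarios = c("S1_plus1", "S2_plus2"),
  nutrients = c("choline_mg", "vit_d_mcg", "sodium_mg", "sat_fat_g",
                "energy_kcal"),
  n_mc = 4000, seed = 2
)
bundle <- run_pipeline(cfg)
render_table(bundle, "table1")
bundle$adequacy
```
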