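---
title: "Methods behind the metric diet-quality index toolkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods behind the metric diet-quality index toolkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhei)
```

## The index

The toolkit scores diet quality on 13 components: nine adequacy
components (total fruits, whole fruits, total vegetables, greens and
beans, whole grains, dairy, total protein foods, seafood and plant
proteins, and the fatty-acid ratio) and four moderation components
(refined grains, sodium, added sugars, saturated fats). Every food-group
quantity is expressed as a density per 1000 kcal, which makes the score
invariant to total energy intake — a child's 1400 kcal day and an
athlete's 3500 kcal day are judged on composition, not quantity. An
adequacy component earns `max_points × min(1, density / standard)`; a
moderation component earns full points at or below one threshold, zero at
or above a second, with a linear ramp between; the fatty-acid component
applies the same ramp rising in the (PUFA+MUFA)/SFA ratio between 1.2 and
2.5. Linear proportional scoring between thresholds is the convention the
original index uses, and it is the only rule under which the built-in
imperial standards reproduce original totals. Component maxima (five or
ten points) sum to 100.

Two standards sets ship with the package. `hei2015_standards()` carries
the original cup/ounce-equivalent thresholds and expects densities already
in those units (e.g. from a food-pattern equivalents table — the package
deliberately does not compute cup equivalents from grams).
`mhei2015_standards()` carries the metric thresholds: g equivalents for
the food groups, mg calcium for dairy, g protein for the protein
components, and the nutrient thresholds unchanged because they are already
metric.

## Food coding

A five-digit code carries everything the scorer needs: component type
(`F`, `V`, `G`, `P`, `D`, or `X` for foods outside every component), a
group letter, a two-digit item number shared by a food's raw and processed
forms, and a processing-state digit (0 raw, 1 processed). Protein and
dairy codes stop after the group letter because their equivalents come
from protein and calcium content alone, and `X` stands alone. The group
alphabet in `food_code_groups()` covers every distinction the 13
components need (juice vs whole fruit, dark green vs other vegetables,
whole vs refined grains, seafood/nuts/soy/legumes vs other protein,
etc.); databases grouped differently can be remapped before coding, and
the alphabet is exposed precisely so that users can see what must be
distinguished.

Two allocation choices were genuinely open and are package decisions:

- **Legumes** carry a database-level switch. The default (`"all"`) counts
  legume vegetables toward total vegetables, greens and beans, *and* both
  protein components simultaneously, which is the original index's
  allocation; `"vegetables"` restricts them to the vegetable components.
- **Fruit juice** counts toward total fruits only, never whole fruits,
  and is treated as its own raw reference (factor 1): juices are sold and
  recorded in ready-to-drink form, so there is no meaningful "raw"
  counterpart to anchor an energy-density ratio.

## The equivalent principle

Processing changes energy density — drying an apple concentrates a given
fruit mass into fewer grams — so consumed grams of processed foods cannot
be credited at face value. The gram-equivalent factor compensates for
exactly this and nothing else (no moisture correction beyond energy
density): raw foods get factor 1; processed fruits, vegetables and grains
get the ratio of processed to raw energy density, resolved through the
shared item number. Legumes invert the roles: cooked legumes are scored
like raw vegetables, so the cooked form is the unity reference and dry
legumes receive a factor above 1. Protein foods and dairy skip factors
entirely — crediting grams of protein and milligrams of calcium already
absorbs densification, and it replaces the nine subcategory-specific
yield formulas an ounce-equivalent calculation would need. That
simplification is the point of the metric methodology; its one visible
consequence is that nuts and seeds are no longer up-weighted relative to
their protein content, which slightly lowers protein-component scores for
nut-heavy (e.g. vegetarian) menus relative to the imperial index.

Multi-ingredient menu items are decomposed through a recipe table of mass
fractions (summing to at most 1; the remainder is water or unclassified
mass). Where only paired cup-equivalent tables exist, the mass fraction
is reconstructed exactly as `menu cup-eq per 100 g ÷ ingredient cup-eq
per 100 g` — no estimation involved. `detect_recipe_discrepancies()`
compares a declared menu-level profile against the recipe-recomputed one
with a strict tolerance of 0.005 per value, i.e. half a rounding unit at
the two-decimal precision of published equivalents tables, so only
differences *not* attributable to rounding are flagged.

A processed food with no resolvable reference is flagged by
`validate_database()`; at conversion time it uses an explicit per-record
factor override if one is supplied, otherwise factor 1 with a logged
warning. Failing soft here keeps long scoring pipelines runnable while
the warning and the validation report make the gap visible.

## Densities and degenerate inputs

`component_densities()` pools a subject's days (summing intake and
energy — identical to a day-weighted average for densities), then divides
component totals by energy in units of 1000 kcal. Added sugars use
4 kcal/g, saturated fats 9 kcal/g, both as percent of total energy. The
fatty-acid ratio is computed from pooled fat grams; its limits are
handled explicitly: no fat at all gives ratio `NaN` and scores 0, zero
saturated fat with some unsaturated fat gives `Inf` and scores the
maximum (the limit of the ramp). Zero-energy records are flagged and
score 0 on every component rather than erroring, matching how reference
implementations treat empty recalls. Scores are kept unrounded
internally; rounding is a display concern.

Scoring is per-person ("simple" scoring); the population-ratio method
used in some surveillance contexts is out of scope, and per-person scores
are what a subject-level agreement analysis needs anyway.

## Calibration

Changing the unit system silently changes what "1.1 cup equivalents per
1000 kcal" means, so metric thresholds cannot be transcribed — they are
*calibrated*: assume the cohort's metric consumption of a component
fulfils the same proportion of its (unknown) metric standard as its
imperial consumption fulfils of the imperial standard, giving

```
metric standard = metric mean × imperial standard / imperial mean .
```

Implementation choices:

- Means are unweighted arithmetic means of per-subject densities (not the
  density of pooled cohort intake); the published worked example speaks
  of cohort-average cup equivalents per 1000 kcal, which is this
  estimator. Survey weighting is out of scope.
- Intermediates stay unrounded; rounding (half away from zero — base R's
  round-half-to-even would bias standards ending in .5) is applied once,
  to the final standard: whole gram equivalents for food-group
  components, one decimal for protein and dairy.
- The refined-grains minimum-score standard is the calibrated maximum
  scaled by the imperial min/max ratio, rounded to whole grams.
- Nutrient components pass through unchanged — they are already metric.

The calibration conserves the fulfillment proportion exactly
(pre-rounding) and is equivariant under rescaling the metric unit, both
of which are property-tested.

## Agreement analysis

`bland_altman()` uses differences A − B (A the reference index), bias =
mean difference, and limits of agreement at the literal `bias ± 1.96 ×
SD` of the differences with the sample (n−1) SD — 1.96, not a t
quantile, because that is the definition being matched. Confidence
intervals use the normal-theory formulas: `± t·SD/√n` for the bias and
`± t·SD·√(3/n)` for each limit (exact-variance formulas differ only in
the third decimal at cohort sizes where the intervals matter). Totals are
compared with Pearson's r; components with Spearman's rho using average
ranks, because component scores pile up on 0 and the maximum and are far
from normal. Zero-variance inputs yield `NA` with a flag rather than an
error. Summaries report mean, sample SD, median and the
linear-interpolation (type-7) IQR; IQR is quantile-method-dependent, so
the method is fixed and documented. The Bland–Altman plot is purely
presentational — every number on it comes from `bland_altman()` — and is
accompanied by a CSV of the plotted values.

## What the synthetic data does and does not emulate

The generators exist so that every module is testable end-to-end with no
external data; they aim at *structural*, not statistical, realism.

`make_food_db()` plants, deterministically under one seed, foods covering
every code group: fixed single-purpose "dial" foods whose compositions
make target profiles solvable in closed form (a 30 kcal/100 g fruit, a
120 mg-calcium/100 g milk, an 18 g-protein/100 g fish, pure
sugar/salt/fat/starch `X` foods clearly labelled synthetic), raw/processed
pairs with known energy-density ratios (including a 58→290 kcal dried
apple and a cooked/dry lentil pair), plus randomized extra foods per
group drawn from plausible nutrient ranges. The generating ratios are
emitted so tests can verify that the factor machinery recovers them.

`make_cohort()` composes daily intakes from the dials so each subject's
true densities are known analytically; the ground truth is accumulated
inside the generator from the planted grams and compositions,
independently of the scoring pipeline, and the two are required to agree
to 1e-9. Defaults are one 24-h record per subject (optionally two, split
60/40), energy normal with mean 2000 and SD 300 kcal (a typical adult
intake distribution), per-component lognormal noise with SD 0.15 (the
order of single-component day-to-day variation), and 50 subjects — small
enough that the full suite runs in seconds. `near_max` profiles sit 2%
beyond every maximum-score threshold so scores rest firmly on the cap
(total exactly 100); `near_min` profiles have no adequacy intake and
exceed every minimum-score threshold (total 0). Profiles whose dial
foods would exceed the energy budget are rescaled to fit for random and
pattern draws, and rejected for explicit profiles. One integer seed
drives everything through a stated stream-splitting rule
(`(seed × 1009 + offset) mod 2³¹−1`, one offset per generator).

`make_paired_consumption()` draws per-subject fulfillment proportions
(uniform 0.2–1.2 of the standard) and builds imperial and metric density
tables at the same proportion of their respective standards, optionally
with lognormal noise on the metric side. Noise-free tables recover
planted standards exactly after rounding; with 10% noise and 5000
subjects, recovery is within 2% (the lognormal mean bias at SD 0.1 is
0.5%). These are the problem sizes the acceptance checks use.

What passing these tests shows: the coding, conversion, scoring,
calibration and agreement arithmetic are correct, self-consistent and
scale-invariant. What they do not show: anything about real survey data —
the generator has no correlation structure between components, no
under-reporting, no food-frequency realism, and its recipes are shallow.
Cohort-level results on real data (means near 52, correlations above
0.9, a bias near zero) depend on those properties and must be established
on the survey data itself.

## Known limitations

- Imperial scoring expects pre-computed cup/ounce-equivalent densities;
  the package never converts grams to imperial units.
- No survey weights, no age-specific standards, no under-2-years
  exclusion logic (data-preparation concerns upstream of scoring).
- The group alphabet is a compatible stand-in for a full published code
  list, not a transcription of one; users can remap.
- Recipe decomposition is single-level (ingredients must be single
  foods).
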