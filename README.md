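# mhei — metric Healthy Eating Index-2015 scoring toolkit

`mhei` computes 13-component diet-quality index scores from **weighed
(gram) dietary records**. The original Healthy Eating Index-2015 is tied
to USDA cup- and ounce-equivalent tables, which makes it awkward to apply
to the metric food databases and weighed food records used in most of the
world. The metric methodology implemented here replaces those units with
quantities any metric food-composition database already carries:

- **gram equivalents** for fruits, vegetables and grains: consumed grams
  times a factor correcting for energy-density change through processing
  (`factor = 1` for raw foods, `factor = energy density processed / energy
  density raw` otherwise; for legumes the cooked form is the unity
  reference, so dry legumes get a factor above 1);
- **grams of protein** for the two protein components and **milligrams of
  calcium** for dairy, credited directly from nutrient content;
- unchanged metric thresholds for the nutrient components (sodium in
  g/1000 kcal, added sugars and saturated fats in % of energy, and the
  (PUFA+MUFA)/SFA ratio).

All food-group quantities are densities per 1000 kcal, so the score is
independent of total energy intake. Nine adequacy components score
`max_points × min(1, density / standard)`; four moderation components run
a descending ramp between a maximum-score and a minimum-score threshold;
totals run 0–100.

The package is aimed at nutritional epidemiologists who want to score
metric dietary data, calibrate country-specific standards, or quantify
agreement between two index variants. It covers:

- a five-digit **food coding system** (component type, group, item number,
  processing state) and database validation (`parse_food_code()`,
  `food_database()`, `validate_database()`);
- **gram-equivalent conversion** and recipe decomposition of
  multi-ingredient menu items, including reconstruction of ingredient mass
  fractions from paired cup-equivalent tables and detection of recipe
  discrepancies (`gram_equivalents()`, `menu_equivalents()`,
  `ingredient_fraction_from_cup_equivalents()`,
  `detect_recipe_discrepancies()`);
- the **13-component scorer** under metric (`mhei2015_standards()`) or
  imperial (`hei2015_standards()`) standards (`component_densities()`,
  `total_score()`, `score_cohort()`, `percent_of_standard()`);
- the **calibration** that derives metric standards from paired
  imperial/metric consumption data (`calibrate_component()`,
  `calibrate_all()`);
- **Bland–Altman agreement analysis** with 95% limits of agreement,
  Pearson/Spearman correlations and distributional summaries
  (`bland_altman()`, `score_correlations()`, `summarize_scores()`);
- **synthetic-data generators** for food databases and intake cohorts with
  analytically known densities (`make_food_db()`, `make_cohort()`,
  `make_paired_consumption()`), so the entire pipeline runs with no
  external data.

## Worked example

```r
library(mhei)

db     <- make_food_db(seed = 42)                       # synthetic food database
cohort <- make_cohort(cohort_spec(n_subjects = 3, seed = 42,
                                  profile = "random"), db)
scores <- score_cohort(cohort$intake, db, standards = "mhei2015")
scores[, c("subject_id", "total_fruits", "whole_grains",
           "dairy", "sodium", "total")]
#>   subject_id total_fruits whole_grains dairy sodium total
#> 1      S0001         1.89         5.66  7.21     10  72.6
#> 2      S0002         1.66         6.31  7.11     10  70.0
#> 3      S0003         4.34         8.40  5.01     10  71.7
```

Each row is one subject. `total_fruits = 1.89` means this subject's fruit
density (53.4 g equivalents per 1000 kcal, see below) earns 1.89 of the 5
available points — 37.9% of the 141 g equivalent standard. `sodium = 10`
means sodium stayed at or below 1.1 g/1000 kcal, the full-score threshold.
`total` is the 0–100 sum over all 13 components.

The underlying densities and their percent compliance:

```r
component_densities(cohort$intake[cohort$intake$subject_id == "S0001", ], db)
#> <component_densities> per 1000 kcal (total energy 1772 kcal)
#>   total_fruits  whole_fruits  total_vegetables  greens_beans ...
#>         53.405        53.405           198.140        11.222 ...
```

Calibrating metric standards from a paired cohort (here synthetic, with
10% noise) and recovering the planted standards:

```r
pc  <- make_paired_consumption(n_subjects = 200, noise_sd = 0.1, seed = 42)
cal <- calibrate_all(pc$imperial, pc$metric)
#> total_vegetables 162 g eq, total_protein_foods 15.7 g protein,
#> refined_grains 32 (min 76) — within noise of the planted 160/15.6/32
```

A command-line interface wrapping the same functions is installed at
`exec/mhei` (subcommands `build-equivalents`, `score`, `calibrate`,
`compare`, `simulate`; see `mhei_cli_main()`).

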