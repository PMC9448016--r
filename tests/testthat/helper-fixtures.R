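# Tiny in-code fixtures used across test files.

food_row <- function(food_id, code, energy = 0, protein = 0, calcium = 0,
                     pufa = 0, mufa = 0, sfa = 0, sugars = 0, sodium = 0,
                     name = food_id) {
  data.frame(food_id = food_id, name = name, code = code,
             energy_kcal = energy, protein_g = protein, calcium_mg = calcium,
             pufa_g = pufa, mufa_g = mufa, sfa_g = sfa,
             added_sugars_g = sugars, sodium_mg = sodium,
             stringsAsFactors = FALSE)
}

# apple raw/dried pair (factor 5), strawberry, lentil pair, seafood, milk
tiny_db <- function(...) {
  food_database(rbind(
    food_row("apple_raw", "FO010", energy = 58),
    food_row("apple_dried", "FO011", energy = 290),
    food_row("strawberry", "FC010", energy = 32),
    food_row("lentils_dry", "VL010", energy = 345, protein = 25),
    food_row("lentils_cooked", "VL011", energy = 115, protein = 9),
    food_row("cod", "PS", energy = 80, protein = 20),
    food_row("milk", "DM", energy = 45, calcium = 120),
    food_row("water", "X"),
    ...
  ))
}

# densities exactly at a standards table's maximum-score thresholds
densities_at_max <- function(standards) {
  tab <- standards$table
  as_component_densities(
    stats::setNames(tab$standard_for_max, tab$component),
    energy_kcal = 2000
  )
}

expect_component_names <- function(x) {
  expect_named(x, mhei_components()$component, ignore.order = TRUE)
}
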