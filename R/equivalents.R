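# Gram-equivalent conversion.
#
# The equivalent principle compensates for energy-density change through
# preparation: a processed fruit/vegetable/grain is converted back to its
# raw-form mass via the ratio of energy densities, so that dried, cooked or
# concentrated forms neither inflate nor deflate food-group intake. Protein
# foods and dairy are instead credited at the nutrient level (grams of
# protein, milligrams of calcium), with no processing factor.

#' Gram-equivalent factor for a raw/processed food pair
#'
#' For fruits, vegetables and grains, the factor converting consumed grams
#' into gram equivalents is 1 for the raw form and the ratio of energy
#' densities (processed over raw) for the processed form. The legume
#' vegetable group inverts the roles: the cooked form is the unity
#' reference (factor 1) and the uncooked form receives the ratio of its
#' energy density over the cooked form's, which exceeds 1 because drying
#' concentrates energy.
#'
#' @param processed The record (one-row data frame from a `food_db`, or a
#'   list with the same fields) whose factor is wanted.
#' @param raw Its unity-reference counterpart: the raw form, or for legumes
#'   the cooked form. Must share component type, group and item number.
#' @return A list of class `equivalent_factor` with `food_id`, `factor`
#'   (gram equivalents per gram consumed) and `basis` (`"raw_unity"` or
#'   `"energy_density_ratio"`).
#' @examples
#' raw <- list(food_id = "apple_raw", code = "FO010", component_type = "F",
#'             group = "O", item_number = 1L, processing_state = 0L,
#'             energy_kcal = 58)
#' dried <- list(food_id = "apple_dried", code = "FO011", component_type = "F",
#'               group = "O", item_number = 1L, processing_state = 1L,
#'               energy_kcal = 290)
#' processing_factor(dried, raw)$factor  # 5
#' processing_factor(raw, raw)$factor    # 1
# Coerce a record (list or one-row data frame) to a list with the parsed
# code fields present, deriving them from `code` when absent.
as_food_record <- function(rec) {
  rec <- as.list(rec)
  if (is.null(rec$component_type)) {
    code <- parse_food_code(rec$code)
    rec$component_type <- code$component_type
    rec$group <- code$group
    rec$item_number <- code$item_number
    rec$processing_state <- code$processing_state
  }
  rec
}

#' @export
processing_factor <- function(processed, raw) {
  p <- as_food_record(processed)
  r <- as_food_record(raw)
  if (p$component_type != r$component_type || p$group != r$group ||
      p$item_number != r$item_number) {
    mhei_abort(
      sprintf("foods '%s' and '%s' are not forms of the same item",
              p$food_id, r$food_id),
      "mhei_factor_pair_error"
    )
  }
  is_legume <- p$component_type == "V" && p$group == "L"
  unity_state <- if (is_legume) 1L else 0L
  if (p$processing_state == unity_state) {
    return(structure(list(food_id = p$food_id, factor = 1,
                          basis = "raw_unity"),
                     class = "equivalent_factor"))
  }
  if (r$processing_state != unity_state) {
    mhei_abort(
      sprintf("reference food '%s' is not the unity-reference form", r$food_id),
      "mhei_factor_pair_error"
    )
  }
  if (is.na(r$energy_kcal) || r$energy_kcal <= 0) {
    mhei_abort(
      sprintf("reference food '%s' has zero energy density; factor undefined",
              r$food_id),
      "mhei_factor_undefined_error"
    )
  }
  structure(
    list(food_id = p$food_id,
         factor = p$energy_kcal / r$energy_kcal,
         basis = "energy_density_ratio"),
    class = "equivalent_factor"
  )
}

# Factor for one record given the whole database: resolves the
# unity-reference counterpart, honours per-record overrides, and falls back
# to factor 1 with a warning when no reference exists (fail-soft).
equivalent_factor <- function(record, db) {
  rec <- as_food_record(record)
  if (!rec$component_type %in% c("F", "V", "G")) {
    return(structure(list(food_id = rec$food_id, factor = 1,
                          basis = "raw_unity"),
                     class = "equivalent_factor"))
  }
  is_legume <- rec$component_type == "V" && rec$group == "L"
  unity_state <- if (is_legume) 1L else 0L
  if (rec$processing_state == unity_state) {
    return(structure(list(food_id = rec$food_id, factor = 1,
                          basis = "raw_unity"),
                     class = "equivalent_factor"))
  }
  if (!is.null(db$factor_overrides) &&
      rec$food_id %in% names(db$factor_overrides)) {
    return(structure(list(food_id = rec$food_id,
                          factor = unname(db$factor_overrides[[rec$food_id]]),
                          basis = "override"),
                     class = "equivalent_factor"))
  }
  ref <- db_counterpart(db, rec, unity_state)
  if (is.null(ref)) {
    warning(sprintf(
      "food '%s' (code %s) has no unity-reference counterpart; using factor 1",
      rec$food_id, rec$code
    ), call. = FALSE)
    return(structure(list(food_id = rec$food_id, factor = 1,
                          basis = "raw_unity"),
                     class = "equivalent_factor"))
  }
  processing_factor(rec, ref)
}

empty_component_vector <- function() {
  stats::setNames(numeric(13), mhei_component_names())
}

#' Gram-equivalent contribution of a consumed amount
#'
#' Multiplies the consumed grams of a single fruit, vegetable or grain food
#' by its gram-equivalent factor and credits the result to every index
#' component the food's code maps to. Foods coded `X` contribute nothing;
#' protein and dairy foods are handled by [nutrient_equivalents()].
#'
#' @param amount_g Grams consumed (non-negative).
#' @param record A one-row record from a `food_db` (or equivalent list).
#' @param db The `food_db` (needed to resolve the unity-reference form).
#' @return Named numeric vector over all 13 components (gram equivalents in
#'   the food-group entries, zero elsewhere).
#' @examples
#' db <- make_food_db(seed = 1)
#' rec <- db$records[db$records$component_type == "F" &
#'                   db$records$processing_state == 0, ][1, ]
#' gram_equivalents(150, rec, db)
#' @export
gram_equivalents <- function(amount_g, record, db) {
  stopifnot(is.numeric(amount_g), amount_g >= 0)
  rec <- as_food_record(record)
  out <- empty_component_vector()
  if (!rec$component_type %in% c("F", "V", "G")) return(out)
  comps <- component_of(parse_food_code(rec$code), legumes = db$legumes)
  geq_comps <- intersect(comps, c("total_fruits", "whole_fruits",
                                  "total_vegetables", "greens_beans",
                                  "whole_grains", "refined_grains"))
  f <- equivalent_factor(rec, db)$factor
  out[geq_comps] <- amount_g * f
  out
}

#' Protein / calcium contribution of a consumed amount
#'
#' Protein foods are credited with grams of protein (to total protein
#' foods, and also to seafood and plant proteins for the seafood,
#' nuts/seeds, soy and legume groups); dairy foods with milligrams of
#' calcium. No processing factor applies: the nutrient content already
#' carries the densification information.
#'
#' @inheritParams gram_equivalents
#' @param record A record with component type `P` or `D`.
#' @return Named numeric vector over all 13 components.
#' @examples
#' milk <- list(food_id = "milk", code = "DM", component_type = "D",
#'              group = "M", calcium_mg = 120, protein_g = 3.4)
#' nutrient_equivalents(250, milk)[["dairy"]]  # 300 mg calcium
#' @export
nutrient_equivalents <- function(amount_g, record) {
  stopifnot(is.numeric(amount_g), amount_g >= 0)
  rec <- as_food_record(record)
  out <- empty_component_vector()
  if (rec$component_type == "P") {
    protein <- amount_g * rec$protein_g / 100
    out["total_protein_foods"] <- protein
    if (rec$group %in% c("S", "N", "Y", "L")) {
      out["seafood_plant_proteins"] <- protein
    }
  } else if (rec$component_type == "D") {
    out["dairy"] <- amount_g * rec$calcium_mg / 100
  } else {
    mhei_abort(
      sprintf("nutrient_equivalents applies to P/D foods, not code %s", rec$code),
      "mhei_equivalents_type_error"
    )
  }
  out
}

# Full contribution of `amount_g` of one database food: component credits
# plus energy and the moderation nutrients. Legume vegetables credit both
# their gram equivalents and (under the "all" allocation) their protein.
food_contributions <- function(amount_g, record, db) {
  rec <- as_food_record(record)
  comps <- empty_component_vector()
  type <- rec$component_type
  if (type %in% c("F", "V", "G")) {
    comps <- gram_equivalents(amount_g, rec, db)
    if (type == "V" && rec$group == "L" && db$legumes == "all") {
      protein <- amount_g * rec$protein_g / 100
      comps["total_protein_foods"] <- comps["total_protein_foods"] + protein
      comps["seafood_plant_proteins"] <- comps["seafood_plant_proteins"] + protein
    }
  } else if (type %in% c("P", "D")) {
    comps <- nutrient_equivalents(amount_g, rec)
  }
  list(
    components = comps,
    energy_kcal = amount_g * rec$energy_kcal / 100,
    sodium_mg = amount_g * rec$sodium_mg / 100,
    added_sugars_g = amount_g * rec$added_sugars_g / 100,
    pufa_g = amount_g * rec$pufa_g / 100,
    mufa_g = amount_g * rec$mufa_g / 100,
    sfa_g = amount_g * rec$sfa_g / 100
  )
}

zero_contributions <- function() {
  list(components = empty_component_vector(), energy_kcal = 0, sodium_mg = 0,
       added_sugars_g = 0, pufa_g = 0, mufa_g = 0, sfa_g = 0)
}

add_contributions <- function(a, b) {
  list(
    components = a$components + b$components,
    energy_kcal = a$energy_kcal + b$energy_kcal,
    sodium_mg = a$sodium_mg + b$sodium_mg,
    added_sugars_g = a$added_sugars_g + b$added_sugars_g,
    pufa_g = a$pufa_g + b$pufa_g,
    mufa_g = a$mufa_g + b$mufa_g,
    sfa_g = a$sfa_g + b$sfa_g
  )
}

scale_contributions <- function(a, k) {
  list(
    components = a$components * k, energy_kcal = a$energy_kcal * k,
    sodium_mg = a$sodium_mg * k, added_sugars_g = a$added_sugars_g * k,
    pufa_g = a$pufa_g * k, mufa_g = a$mufa_g * k, sfa_g = a$sfa_g * k
  )
}

#' Ingredient mass fraction from paired cup equivalents
#'
#' When a multi-ingredient menu item and its single-ingredient constituent
#' are both tabulated in cup equivalents per 100 g for the same component,
#' the ingredient's mass fraction in the menu item is their quotient — the
#' portions can be determined without estimating.
#'
#' @param menu_cupeq_per_100g Cup equivalents per 100 g of the menu item in
#'   the component (non-negative).
#' @param ingredient_cupeq_per_100g Cup equivalents per 100 g of the pure
#'   ingredient (strictly positive).
#' @return The mass fraction (a number in `[0, 1]` for physically
#'   consistent inputs).
#' @examples
#' # strawberry yogurt: 0.03 berry cup eq per 100 g; raw strawberries 0.69
#' ingredient_fraction_from_cup_equivalents(0.03, 0.69)  # 0.0435 = 4.3%
#' @export
ingredient_fraction_from_cup_equivalents <- function(menu_cupeq_per_100g,
                                                     ingredient_cupeq_per_100g) {
  stopifnot(is.numeric(menu_cupeq_per_100g), menu_cupeq_per_100g >= 0)
  if (!is.numeric(ingredient_cupeq_per_100g) ||
      ingredient_cupeq_per_100g <= 0) {
    mhei_abort(
      "ingredient cup equivalents must be > 0 to derive a mass fraction",
      "mhei_fraction_undefined_error"
    )
  }
  menu_cupeq_per_100g / ingredient_cupeq_per_100g
}

#' Construct a recipe table
#'
#' A recipe maps a multi-ingredient menu item to ingredient mass fractions.
#' Fractions must sum to at most 1 (any remainder is water or unclassified
#' mass).
#'
#' @param df Data frame with columns `menu_id`, `food_id`, `mass_fraction`.
#' @return A validated data frame of class `recipe_table`.
#' @export
recipe_table <- function(df) {
  need <- c("menu_id", "food_id", "mass_fraction")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    mhei_abort(
      paste0("recipe table missing columns: ", paste(missing_cols, collapse = ", ")),
      "mhei_recipe_schema_error"
    )
  }
  df <- as.data.frame(df)[need]
  df$menu_id <- as.character(df$menu_id)
  df$food_id <- as.character(df$food_id)
  if (any(df$mass_fraction < 0 | df$mass_fraction > 1)) {
    mhei_abort("recipe mass fractions must lie in [0, 1]",
               "mhei_recipe_fraction_error")
  }
  sums <- tapply(df$mass_fraction, df$menu_id, sum)
  bad <- names(sums)[sums > 1 + 1e-9]
  if (length(bad) > 0) {
    mhei_abort(
      paste0("recipe mass fractions exceed 1 for menu(s): ",
             paste(bad, collapse = ", ")),
      "mhei_recipe_fraction_error"
    )
  }
  class(df) <- c("recipe_table", "data.frame")
  df
}

#' Reconstruct recipes from paired cup-equivalent tables
#'
#' Applies [ingredient_fraction_from_cup_equivalents()] row-wise to a table
#' of paired menu/ingredient cup equivalents, yielding a [recipe_table()].
#'
#' @param df Data frame with columns `menu_id`, `ingredient_food_id`,
#'   `component`, `menu_cupeq_per_100g`, `ingredient_cupeq_per_100g`.
#' @return A `recipe_table`.
#' @export
recipes_from_cup_equivalents <- function(df) {
  need <- c("menu_id", "ingredient_food_id", "component",
            "menu_cupeq_per_100g", "ingredient_cupeq_per_100g")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    mhei_abort(
      paste0("cup-equivalent table missing columns: ",
             paste(missing_cols, collapse = ", ")),
      "mhei_recipe_schema_error"
    )
  }
  fractions <- mapply(ingredient_fraction_from_cup_equivalents,
                      df$menu_cupeq_per_100g, df$ingredient_cupeq_per_100g)
  recipe_table(data.frame(
    menu_id = df$menu_id,
    food_id = df$ingredient_food_id,
    mass_fraction = fractions,
    stringsAsFactors = FALSE
  ))
}

recipe_ingredients <- function(recipes, menu_id) {
  recipes[recipes$menu_id == menu_id, , drop = FALSE]
}

# contributions of 100 g of a menu item, via its recipe
menu_contributions_per_100g <- function(recipes, menu_id, db) {
  ing <- recipe_ingredients(recipes, menu_id)
  total <- zero_contributions()
  for (i in seq_len(nrow(ing))) {
    rec <- db_record(db, ing$food_id[i])
    if (is.null(rec)) {
      mhei_abort(
        sprintf("menu '%s': ingredient '%s' not found in food database",
                menu_id, ing$food_id[i]),
        "mhei_recipe_dangling_error"
      )
    }
    total <- add_contributions(
      total, food_contributions(100 * ing$mass_fraction[i], rec, db)
    )
  }
  total
}

#' Equivalent profile of a menu item per 100 g
#'
#' Decomposes a multi-ingredient menu item through its recipe: each
#' ingredient contributes its own per-100-g equivalents weighted by its
#' mass fraction, with processing states honoured. Menu items are scored
#' proportionally to their ingredients and are never themselves "processed".
#'
#' @param recipes A `recipe_table` (or data frame coercible to one).
#' @param menu_id The menu item to profile.
#' @param db A `food_db` resolving every ingredient.
#' @return Named list with the 13-entry `components` vector (per 100 g of
#'   the menu item) plus `energy_kcal`, `sodium_mg`, `added_sugars_g`,
#'   `pufa_g`, `mufa_g`, `sfa_g` per 100 g.
#' @examples
#' db <- make_food_db(seed = 1)
#' berry <- db$records[db$records$group == "C" &
#'                     db$records$processing_state == 0, ]$food_id[1]
#' rec <- recipe_table(data.frame(menu_id = "berry_yogurt",
#'                                food_id = berry, mass_fraction = 0.043))
#' menu_equivalents(rec, "berry_yogurt", db)$components[["whole_fruits"]]
#' @export
menu_equivalents <- function(recipes, menu_id, db) {
  if (!inherits(recipes, "recipe_table")) recipes <- recipe_table(recipes)
  menu_contributions_per_100g(recipes, menu_id, db)
}

#' Per-100-g equivalents table for a whole database
#'
#' One row per single food and per recipe menu item, with one column per
#' index component (amount per 100 g consumed) plus energy and the
#' moderation nutrients — the metric analogue of a food-pattern equivalents
#' table.
#'
#' @param db A `food_db`.
#' @param recipes Optional `recipe_table` of menu items to append.
#' @return A data frame, one row per food/menu.
#' @export
equivalents_table <- function(db, recipes = NULL) {
  rows <- list()
  for (i in seq_len(nrow(db$records))) {
    rec <- db$records[i, ]
    con <- food_contributions(100, rec, db)
    rows[[length(rows) + 1L]] <- c(
      list(id = rec$food_id, type = "food"),
      as.list(con$components),
      list(energy_kcal = con$energy_kcal, sodium_mg = con$sodium_mg,
           added_sugars_g = con$added_sugars_g, pufa_g = con$pufa_g,
           mufa_g = con$mufa_g, sfa_g = con$sfa_g)
    )
  }
  if (!is.null(recipes)) {
    if (!inherits(recipes, "recipe_table")) recipes <- recipe_table(recipes)
    for (mid in unique(recipes$menu_id)) {
      con <- menu_contributions_per_100g(recipes, mid, db)
      rows[[length(rows) + 1L]] <- c(
        list(id = mid, type = "menu"),
        as.list(con$components),
        list(energy_kcal = con$energy_kcal, sodium_mg = con$sodium_mg,
             added_sugars_g = con$added_sugars_g, pufa_g = con$pufa_g,
             mufa_g = con$mufa_g, sfa_g = con$sfa_g)
      )
    }
  }
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  rownames(out) <- NULL
  out
}

#' Detect discrepancies between a declared and a recomputed profile
#'
#' Compares a menu item's declared per-100-g component values against the
#' values recomputed from its recipe, flagging each component whose
#' absolute difference strictly exceeds `tol`. The default tolerance, 0.005,
#' is half a rounding unit at the two-decimal precision typical of published
#' equivalents tables, so differences attributable to rounding are not
#' flagged.
#'
#' @param declared Named numeric vector of declared per-100-g values.
#' @param recomputed Named numeric vector over the same components.
#' @param tol Strict threshold on the absolute difference.
#' @return Data frame with columns `component`, `declared`, `recomputed`,
#'   `difference`; zero rows when the profiles agree within `tol`.
#' @examples
#' detect_recipe_discrepancies(
#'   declared = c(dark_green = 0.00, other_veg = 0.91),
#'   recomputed = c(dark_green = 0.715, other_veg = 0.455)
#' )
#' @export
detect_recipe_discrepancies <- function(declared, recomputed, tol = 0.005) {
  comps <- union(names(declared), names(recomputed))
  d <- stats::setNames(rep(0, length(comps)), comps)
  r <- d
  d[names(declared)] <- declared
  r[names(recomputed)] <- recomputed
  diff <- d - r
  flagged <- abs(diff) > tol
  out <- data.frame(
    component = comps[flagged],
    declared = unname(d[flagged]),
    recomputed = unname(r[flagged]),
    difference = unname(diff[flagged]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}
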