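# Synthetic-data generators: a self-contained food database, intake
# cohorts with controllable dietary patterns and analytically known
# component densities, and paired imperial/metric consumption tables for
# exercising the calibration. One integer seed governs everything: each
# generator draws from its own stream derived as
# (seed * 1009 + stream offset) mod (2^31 - 1), offsets 1 (food db),
# 2 (cohorts), 3 (paired consumption).

derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 1009 + stream) %% 2147483647)
}

# Fixed "dial" foods with simple, single-purpose compositions; the cohort
# generator mixes these to hit target densities exactly. Values are per
# 100 g. Deliberately synthetic: each dial carries only the nutrient(s)
# its component needs, so target profiles solve in closed form.
dial_foods <- function() {
  f <- function(food_id, name, code, energy = 0, protein = 0, calcium = 0,
                pufa = 0, mufa = 0, sfa = 0, sugars = 0, sodium = 0) {
    data.frame(food_id = food_id, name = name, code = code,
               energy_kcal = energy, protein_g = protein,
               calcium_mg = calcium, pufa_g = pufa, mufa_g = mufa,
               sfa_g = sfa, added_sugars_g = sugars, sodium_mg = sodium,
               stringsAsFactors = FALSE)
  }
  rbind(
    f("fruit_dial", "Synthetic whole fruit (dial)", "FO010", energy = 30),
    f("apple_raw", "Apple, raw", "FO020", energy = 58),
    f("apple_dried", "Apple, dried", "FO021", energy = 290),
    f("berry_raw", "Strawberries, raw", "FC010", energy = 32),
    f("berry_canned", "Strawberries, canned", "FC011", energy = 96),
    f("juice_dial", "Fruit juice", "FJ010", energy = 45),
    f("veg_dial", "Synthetic other vegetable (dial)", "VO010", energy = 25),
    f("darkgreen_dial", "Synthetic dark-green vegetable (dial)", "VD010",
      energy = 25),
    f("redorange_dial", "Carrot, raw", "VR010", energy = 41),
    f("starchy_raw", "Potato, raw", "VS010", energy = 77),
    f("starchy_cooked", "Potato, boiled", "VS011", energy = 87),
    f("lentils_cooked", "Lentils, cooked", "VL011", energy = 115,
      protein = 9),
    f("lentils_raw", "Lentils, dry", "VL010", energy = 345, protein = 25),
    f("wholegrain_raw", "Whole-grain flour, dry", "GW010", energy = 340),
    f("wholegrain_cooked", "Whole-grain porridge", "GW011", energy = 130),
    f("refinedgrain_raw", "Refined flour, dry", "GR010", energy = 350),
    f("refinedgrain_cooked", "Refined grain, cooked", "GR011", energy = 140),
    f("meat_dial", "Beef, lean", "PM", energy = 250, protein = 26,
      sfa = 8, mufa = 9, pufa = 1, sodium = 70),
    f("poultry_dial", "Chicken breast", "PU", energy = 165, protein = 27,
      sfa = 1, mufa = 1.2, pufa = 0.8, sodium = 74),
    f("egg_dial", "Egg, whole", "PE", energy = 143, protein = 13,
      sfa = 3.3, mufa = 4, pufa = 1.9, sodium = 142),
    f("seafood_dial", "Synthetic white fish (dial)", "PS", energy = 80,
      protein = 18),
    f("nuts_dial", "Mixed nuts", "PN", energy = 600, protein = 21,
      pufa = 34, mufa = 24, sfa = 9),
    f("soy_dial", "Tofu", "PY", energy = 120, protein = 12),
    f("legume_protein_dial", "Lentils, as protein", "PL", energy = 115,
      protein = 9),
    f("milk_dial", "Synthetic skim milk (dial)", "DM", energy = 30,
      calcium = 120),
    f("yogurt_dial", "Yogurt, plain", "DY", energy = 60, calcium = 110,
      protein = 3.5, sfa = 1.5, sugars = 0, sodium = 50),
    f("cheese_dial", "Cheese, hard", "DC", energy = 390, calcium = 720,
      protein = 25, sfa = 19, mufa = 8, pufa = 1, sodium = 620),
    f("water", "Water", "X"),
    f("x_filler", "Synthetic carbohydrate filler (dial)", "X", energy = 400),
    f("x_syrup", "Synthetic added-sugar syrup (dial)", "X", energy = 400,
      sugars = 100),
    f("x_salt", "Salt blend", "X", sodium = 38000),
    f("x_oil_sat", "Synthetic saturated fat (dial)", "X", energy = 900,
      sfa = 100),
    f("x_oil_unsat", "Synthetic unsaturated oil (dial)", "X", energy = 900,
      mufa = 80, pufa = 20)
  )
}

#' Generate a synthetic food database
#'
#' Builds a deterministic food database covering every code group: fixed
#' single-purpose "dial" foods (used by [make_cohort()] to hit target
#' densities in closed form), raw/processed pairs with known energy-density
#' ratios, a cooked/uncooked legume pair, protein foods with known protein
#' content, dairy foods with known calcium, and `X` foods including pure
#' energy, added-sugar, sodium and fat sources. On top of the fixed foods,
#' `n_per_group` random raw/processed pairs are added per
#' fruit/vegetable/grain group and `n_per_group` random foods per
#' protein/dairy group, with nutrient values drawn from plausible ranges.
#'
#' @param seed Integer seed; the same seed yields a byte-identical
#'   database.
#' @param n_per_group Number of extra random foods per group.
#' @return A `food_db`. The attribute `generating_ratios` records, for
#'   every processed food, the energy-density ratio it was constructed
#'   with (the factor the equivalents machinery must recover).
#' @examples
#' db <- make_food_db(seed = 1)
#' nrow(validate_database(db))  # 0
#' @export
make_food_db <- function(seed = 1, n_per_group = 2) {
  stopifnot(n_per_group >= 1)
  set.seed(derive_seed(seed, 1L))
  dials <- dial_foods()
  ratios <- c(apple_dried = 290 / 58, berry_canned = 96 / 32,
              starchy_cooked = 87 / 77, lentils_raw = 345 / 115,
              wholegrain_cooked = 130 / 340, refinedgrain_cooked = 140 / 350)
  rows <- list(dials)
  groups <- food_code_groups()
  energy_range <- list(F = c(25, 90), V = c(15, 80), G = c(300, 380))
  for (type in c("F", "V", "G")) {
    for (grp in names(groups[[type]])) {
      for (k in seq_len(n_per_group)) {
        item <- 10L + k
        e_ref <- stats::runif(1, energy_range[[type]][1], energy_range[[type]][2])
        ratio <- stats::runif(1, 1.2, 5)
        is_legume <- type == "V" && grp == "L"
        protein <- if (is_legume) stats::runif(1, 6, 10) else 0
        id_ref <- sprintf("syn_%s%s%02d_%s", tolower(type), tolower(grp),
                          item, if (is_legume) "cooked" else "raw")
        id_proc <- sprintf("syn_%s%s%02d_%s", tolower(type), tolower(grp),
                           item, if (is_legume) "dry" else "proc")
        # legumes: cooked form (state 1) is the unity reference; the dry
        # form (state 0) is denser by `ratio`
        ref_state <- if (is_legume) 1L else 0L
        rows[[length(rows) + 1L]] <- data.frame(
          food_id = c(id_ref, id_proc),
          name = c(paste("Synthetic", id_ref), paste("Synthetic", id_proc)),
          code = c(sprintf("%s%s%02d%d", type, grp, item, ref_state),
                   sprintf("%s%s%02d%d", type, grp, item, 1L - ref_state)),
          energy_kcal = c(e_ref, e_ref * ratio),
          protein_g = c(protein, protein * ratio),
          calcium_mg = 0, pufa_g = 0, mufa_g = 0, sfa_g = 0,
          added_sugars_g = 0,
          sodium_mg = round(stats::runif(2, 0, 30), 1),
          stringsAsFactors = FALSE
        )
        ratios[id_proc] <- ratio
      }
    }
  }
  for (type in c("P", "D")) {
    for (grp in names(groups[[type]])) {
      for (k in seq_len(n_per_group)) {
        id <- sprintf("syn_%s%s_%02d", tolower(type), tolower(grp), k)
        rows[[length(rows) + 1L]] <- data.frame(
          food_id = id, name = paste("Synthetic", id),
          code = paste0(type, grp),
          energy_kcal = stats::runif(1, 50, 400),
          protein_g = if (type == "P") stats::runif(1, 8, 30) else stats::runif(1, 0, 10),
          calcium_mg = if (type == "D") stats::runif(1, 80, 800) else stats::runif(1, 0, 50),
          pufa_g = stats::runif(1, 0, 5), mufa_g = stats::runif(1, 0, 8),
          sfa_g = stats::runif(1, 0, 8), added_sugars_g = 0,
          sodium_mg = round(stats::runif(1, 0, 500), 1),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  db <- food_database(df)
  attr(db, "generating_ratios") <- ratios
  db
}

#' Specify a synthetic cohort
#'
#' @param n_subjects Number of subjects (default 50: small enough that the
#'   whole pipeline runs in seconds, large enough for rank statistics).
#' @param days Dietary-record days per subject, 1 or 2 (a 2-day subject's
#'   intake is split 60/40 across days; densities pool the days).
#' @param seed Integer seed.
#' @param profile Target dietary pattern: `"random"` (independent
#'   per-component fulfillment), `"near_max"` (every component exactly at
#'   its metric standard for maximum score), `"near_min"` (no adequacy
#'   intake, every moderation component beyond its minimum-score
#'   standard), or `"pattern"` (explicit `multipliers`).
#' @param multipliers Named per-component density multipliers relative to
#'   the metric standards (used by `"pattern"`; unnamed components default
#'   to 1).
#' @param noise_sd Lognormal multiplicative noise SD applied to the target
#'   densities (`"random"`/`"pattern"` only; default 0.15, roughly the
#'   day-to-day variation of a single component).
#' @param energy_mean,energy_sd Daily-energy distribution in kcal (normal,
#'   truncated at 500). Defaults 2000/300, a typical adult intake.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 50, days = 1, seed = 1,
                        profile = c("random", "near_max", "near_min", "pattern"),
                        multipliers = NULL, noise_sd = 0.15,
                        energy_mean = 2000, energy_sd = 300) {
  profile <- match.arg(profile)
  stopifnot(n_subjects >= 1, days %in% c(1, 2), noise_sd >= 0,
            energy_mean > 0, energy_sd >= 0)
  if (!is.null(multipliers)) {
    stopifnot(is.numeric(multipliers), !is.null(names(multipliers)),
              all(multipliers >= 0))
  }
  structure(
    list(n_subjects = as.integer(n_subjects), days = as.integer(days),
         seed = as.integer(seed), profile = profile,
         multipliers = multipliers, noise_sd = noise_sd,
         energy_mean = energy_mean, energy_sd = energy_sd),
    class = "cohort_spec"
  )
}

# per-gram properties of the dials the cohort builder uses
.dial_props <- list(
  fruit = list(id = "fruit_dial", kcal = 0.30, geq = 1),
  veg = list(id = "veg_dial", kcal = 0.25, geq = 1),
  darkgreen = list(id = "darkgreen_dial", kcal = 0.25, geq = 1),
  wholegrain = list(id = "wholegrain_raw", kcal = 3.40, geq = 1),
  refinedgrain = list(id = "refinedgrain_raw", kcal = 3.50, geq = 1),
  milk = list(id = "milk_dial", kcal = 0.30, ca = 1.2),
  seafood = list(id = "seafood_dial", kcal = 0.80, prot = 0.18),
  syrup = list(id = "x_syrup", kcal = 4.0, sugars = 1),
  salt = list(id = "x_salt", kcal = 0, sodium = 380),
  satfat = list(id = "x_oil_sat", kcal = 9.0, sfa = 1),
  unsat = list(id = "x_oil_unsat", kcal = 9.0, unsat = 1),
  filler = list(id = "x_filler", kcal = 4.0)
)

#' Generate a synthetic intake cohort with known densities
#'
#' Composes daily intakes from the database's dial foods so that every
#' subject's true per-1000-kcal component densities are known analytically
#' by construction; the ground truth is accumulated inside the generator
#' from the planted grams and compositions, independently of the scoring
#' pipeline, and emitted alongside the records. `near_max` cohorts land
#' exactly at the metric standards (total score 100), `near_min` cohorts
#' beyond every minimum-score standard (total score 0).
#'
#' If a drawn profile is so energy-dense that the dial foods would exceed
#' the subject's energy target (possible for extreme random draws), random
#' and pattern profiles are rescaled proportionally to fit and the ground
#' truth reflects the rescaled intake; explicit `near_max`/`near_min`
#' profiles raise an error instead, since their targets are the point.
#'
#' @param spec A [cohort_spec()].
#' @param db A `food_db` from [make_food_db()] (must contain the dial
#'   foods).
#' @return A list with `intake` (an `intake_table`), `ground_truth` (data
#'   frame: `subject_id`, the 13 per-1000-kcal densities, `energy_kcal`)
#'   and `spec`.
#' @examples
#' db <- make_food_db(seed = 1)
#' cohort <- make_cohort(cohort_spec(n_subjects = 3, seed = 7,
#'                                   profile = "near_max"), db)
#' score_cohort(cohort$intake, db)$total  # all 100
#' @export
make_cohort <- function(spec, db) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(db, "food_db"))
  p <- .dial_props
  missing_dials <- setdiff(vapply(p, `[[`, character(1), "id"),
                           db$records$food_id)
  if (length(missing_dials) > 0) {
    mhei_abort(
      paste0("database lacks dial foods: ", paste(missing_dials, collapse = ", ")),
      "mhei_cohort_spec_error"
    )
  }
  set.seed(derive_seed(spec$seed, 2L))
  std <- mhei2015_standards()$table
  std_max <- stats::setNames(std$standard_for_max, std$component)
  intake_rows <- list()
  truth_rows <- list()
  for (s in seq_len(spec$n_subjects)) {
    subject_id <- sprintf("S%04d", s)
    energy <- max(500, stats::rnorm(1, spec$energy_mean, spec$energy_sd))
    targets <- switch(
      spec$profile,
      # 2% beyond each maximum-score threshold so scores sit firmly on the
      # cap (adequacy above, moderation below the threshold)
      near_max = c(total_fruits = 1.02 * std_max[["total_fruits"]],
                   greens_beans = 1.02 * std_max[["greens_beans"]],
                   total_vegetables = 1.02 * std_max[["total_vegetables"]],
                   whole_grains = 1.02 * std_max[["whole_grains"]],
                   refined_grains = 0.98 * std_max[["refined_grains"]],
                   dairy = 1.02 * std_max[["dairy"]],
                   total_protein_foods = 1.02 * std_max[["total_protein_foods"]],
                   sodium = 0.98 * std_max[["sodium"]],
                   added_sugars = 0.98 * std_max[["added_sugars"]],
                   saturated_fats = 0.98 * std_max[["saturated_fats"]],
                   fatty_acids = 1.02 * std_max[["fatty_acids"]]),
      near_min = c(total_fruits = 0, greens_beans = 0, total_vegetables = 0,
                   whole_grains = 0, refined_grains = 100, dairy = 0,
                   total_protein_foods = 0, sodium = 3.0,
                   added_sugars = 30, saturated_fats = 18,
                   fatty_acids = 0.5),
      random = {
      m <- c(total_fruits = stats::runif(1, 0.05, 1.1),
             greens_beans = stats::runif(1, 0, 1.2),
             total_vegetables = stats::runif(1, 0.2, 1.2),
             whole_grains = stats::runif(1, 0, 1.2),
             refined_grains = stats::runif(1, 0.3, 1.8),
             dairy = stats::runif(1, 0.1, 1.2),
             total_protein_foods = stats::runif(1, 0.3, 1.3),
             sodium = stats::runif(1, 0.5, 2.2))
      tg <- std_max[names(m)] * m
      c(tg,
        added_sugars = stats::runif(1, 3, 15),
        saturated_fats = stats::runif(1, 4, 12),
        fatty_acids = stats::runif(1, 0.8, 2.2))
      },
      pattern = {
        m <- stats::setNames(rep(1, 11),
                             c("total_fruits", "greens_beans",
                               "total_vegetables", "whole_grains",
                               "refined_grains", "dairy",
                               "total_protein_foods", "sodium",
                               "added_sugars", "saturated_fats",
                               "fatty_acids"))
        user <- spec$multipliers[intersect(names(spec$multipliers), names(m))]
        m[names(user)] <- user
        std_like <- c(std_max[c("total_fruits", "greens_beans",
                                "total_vegetables", "whole_grains",
                                "refined_grains", "dairy",
                                "total_protein_foods", "sodium",
                                "added_sugars", "saturated_fats",
                                "fatty_acids")])
        std_like * m
      }
    )
    if (spec$noise_sd > 0 && spec$profile %in% c("random", "pattern")) {
      targets <- targets * exp(stats::rnorm(length(targets), 0, spec$noise_sd))
    }
    if (targets[["greens_beans"]] > targets[["total_vegetables"]]) {
      targets[["total_vegetables"]] <- targets[["greens_beans"]]
    }
    if (targets[["saturated_fats"]] >= 95) {
      mhei_abort("saturated-fat energy target exceeds total energy",
                 "mhei_cohort_spec_error")
    }
    per1000 <- energy / 1000
    sfa_g <- targets[["saturated_fats"]] / 100 * energy / 9
    grams <- c(
      fruit_dial = targets[["total_fruits"]] * per1000,
      darkgreen_dial = targets[["greens_beans"]] * per1000,
      veg_dial = (targets[["total_vegetables"]] - targets[["greens_beans"]]) * per1000,
      wholegrain_raw = targets[["whole_grains"]] * per1000,
      refinedgrain_raw = targets[["refined_grains"]] * per1000,
      milk_dial = targets[["dairy"]] * per1000 / p$milk$ca,
      seafood_dial = targets[["total_protein_foods"]] * per1000 / p$seafood$prot,
      x_salt = targets[["sodium"]] * 1000 * per1000 / p$salt$sodium,
      x_syrup = targets[["added_sugars"]] / 100 * energy / 4,
      x_oil_sat = sfa_g,
      x_oil_unsat = targets[["fatty_acids"]] * sfa_g
    )
    kcal_per_g <- c(fruit_dial = p$fruit$kcal, darkgreen_dial = p$darkgreen$kcal,
                    veg_dial = p$veg$kcal, wholegrain_raw = p$wholegrain$kcal,
                    refinedgrain_raw = p$refinedgrain$kcal,
                    milk_dial = p$milk$kcal, seafood_dial = p$seafood$kcal,
                    x_salt = 0, x_syrup = p$syrup$kcal,
                    x_oil_sat = p$satfat$kcal, x_oil_unsat = p$unsat$kcal)
    dial_energy <- sum(grams * kcal_per_g)
    if (dial_energy > 0.98 * energy) {
      if (spec$profile %in% c("near_max", "near_min")) {
        mhei_abort(
          sprintf("profile '%s' needs %.0f kcal of dial foods but the energy target is %.0f",
                  spec$profile, dial_energy, energy),
          "mhei_cohort_spec_error"
        )
      }
      grams <- grams * 0.98 * energy / dial_energy
      dial_energy <- 0.98 * energy
    }
    grams["x_filler"] <- (energy - dial_energy) / p$filler$kcal
    grams <- grams[grams > 0]
    # analytic ground truth from the planted grams
    g <- function(id) if (id %in% names(grams)) grams[[id]] else 0
    true_energy <- sum(vapply(names(grams), function(id) {
      g(id) * kcal_per_g_all(id)
    }, numeric(1)))
    tp1000 <- true_energy / 1000
    sug_g <- g("x_syrup") * 1
    sfa_tot <- g("x_oil_sat") * 1
    unsat_tot <- g("x_oil_unsat") * 1
    truth <- c(
      total_fruits = g("fruit_dial") / tp1000,
      whole_fruits = g("fruit_dial") / tp1000,
      total_vegetables = (g("veg_dial") + g("darkgreen_dial")) / tp1000,
      greens_beans = g("darkgreen_dial") / tp1000,
      whole_grains = g("wholegrain_raw") / tp1000,
      dairy = g("milk_dial") * p$milk$ca / tp1000,
      total_protein_foods = g("seafood_dial") * p$seafood$prot / tp1000,
      seafood_plant_proteins = g("seafood_dial") * p$seafood$prot / tp1000,
      fatty_acids = if (sfa_tot > 0) unsat_tot / sfa_tot
                    else if (unsat_tot > 0) Inf else NaN,
      refined_grains = g("refinedgrain_raw") / tp1000,
      sodium = g("x_salt") * p$salt$sodium / 1000 / tp1000,
      added_sugars = sug_g * 4 / true_energy * 100,
      saturated_fats = sfa_tot * 9 / true_energy * 100
    )
    day_split <- if (spec$days == 2) c(0.6, 0.4) else 1
    for (d in seq_len(spec$days)) {
      intake_rows[[length(intake_rows) + 1L]] <- data.frame(
        subject_id = subject_id, day = d, food_id = names(grams),
        grams = unname(grams) * day_split[d], stringsAsFactors = FALSE
      )
    }
    truth_rows[[length(truth_rows) + 1L]] <- as.data.frame(
      c(list(subject_id = subject_id), as.list(truth),
        list(energy_kcal = true_energy)),
      stringsAsFactors = FALSE
    )
  }
  intake <- intake_table(do.call(rbind, intake_rows))
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(intake = intake, ground_truth = truth, spec = spec)
}

# energy per gram for dial foods used by make_cohort (shared with the
# analytic ground-truth accumulation)
kcal_per_g_all <- function(id) {
  p <- .dial_props
  switch(id,
    fruit_dial = p$fruit$kcal, darkgreen_dial = p$darkgreen$kcal,
    veg_dial = p$veg$kcal, wholegrain_raw = p$wholegrain$kcal,
    refinedgrain_raw = p$refinedgrain$kcal, milk_dial = p$milk$kcal,
    seafood_dial = p$seafood$kcal, x_salt = 0, x_syrup = p$syrup$kcal,
    x_oil_sat = p$satfat$kcal, x_oil_unsat = p$unsat$kcal,
    x_filler = p$filler$kcal,
    stop("unknown dial food: ", id)
  )
}

#' Generate paired imperial/metric consumption tables
#'
#' For each subject and each calibrated component, draws a fulfillment
#' proportion (uniform on 0.2-1.2 of the standard), sets the imperial
#' density to that proportion of the imperial standard, and the metric
#' density to the same proportion of the planted "true" metric standard,
#' optionally perturbed by lognormal noise. With `noise_sd = 0`,
#' [calibrate_all()] applied to the output recovers the planted standards
#' exactly after rounding.
#'
#' @param n_subjects Number of subjects.
#' @param true_metric_standards A metric `scoring_standards` to plant
#'   (default the built-in metric standards).
#' @param imperial_standards The imperial standards (default built-in).
#' @param noise_sd Lognormal noise SD on the metric densities.
#' @param seed Integer seed.
#' @return A list with data frames `imperial` and `metric` (columns
#'   `subject_id` + one per calibrated component) and
#'   `true_metric_standards`.
#' @export
make_paired_consumption <- function(n_subjects = 50,
                                    true_metric_standards = mhei2015_standards(),
                                    imperial_standards = hei2015_standards(),
                                    noise_sd = 0, seed = 1) {
  stopifnot(n_subjects >= 1, noise_sd >= 0)
  true_metric_standards <- resolve_standards(true_metric_standards)
  imperial_standards <- resolve_standards(imperial_standards)
  set.seed(derive_seed(seed, 3L))
  reg <- mhei_components()
  comps <- reg$component[reg$calibrated]
  imp_std <- stats::setNames(imperial_standards$table$standard_for_max,
                             imperial_standards$table$component)
  met_std <- stats::setNames(true_metric_standards$table$standard_for_max,
                             true_metric_standards$table$component)
  subject_id <- sprintf("S%04d", seq_len(n_subjects))
  imperial <- data.frame(subject_id = subject_id, stringsAsFactors = FALSE)
  metric <- data.frame(subject_id = subject_id, stringsAsFactors = FALSE)
  for (comp in comps) {
    prop <- stats::runif(n_subjects, 0.2, 1.2)
    imperial[[comp]] <- prop * imp_std[[comp]]
    noise <- if (noise_sd > 0) exp(stats::rnorm(n_subjects, 0, noise_sd)) else 1
    metric[[comp]] <- prop * met_std[[comp]] * noise
  }
  list(imperial = imperial, metric = metric,
       true_metric_standards = true_metric_standards)
}
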