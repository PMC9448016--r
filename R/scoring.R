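# Scoring: pool a subject's intake over days, convert to per-1000-kcal
# component densities, and map densities to points under a standards set.

#' Construct an intake-record table
#'
#' Person-day rows of consumed foods: one row per (subject, day, food or
#' menu item, grams).
#'
#' @param df Data frame with columns `subject_id`, `day`, `food_id`,
#'   `grams`.
#' @return A validated data frame of class `intake_table`.
#' @export
intake_table <- function(df) {
  need <- c("subject_id", "day", "food_id", "grams")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    mhei_abort(
      paste0("intake table missing columns: ", paste(missing_cols, collapse = ", ")),
      "mhei_intake_schema_error"
    )
  }
  df <- as.data.frame(df)[need]
  df$subject_id <- as.character(df$subject_id)
  df$food_id <- as.character(df$food_id)
  if (any(df$grams < 0)) {
    mhei_abort("consumed grams must be non-negative", "mhei_intake_value_error")
  }
  if (any(df$day < 1)) {
    mhei_abort("day must be >= 1", "mhei_intake_value_error")
  }
  class(df) <- c("intake_table", "data.frame")
  df
}

#' Read an intake-record CSV
#'
#' @param path CSV with columns `subject_id`, `day`, `food_id`, `grams`.
#' @return An `intake_table`.
#' @export
read_intake <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character",
                                       food_id = "character"))
  intake_table(df)
}

new_component_densities <- function(components, energy_kcal,
                                    zero_energy = FALSE) {
  structure(
    list(components = components, energy_kcal = energy_kcal,
         zero_energy = zero_energy),
    class = "component_densities"
  )
}

#' Coerce a named vector to component densities
#'
#' Builds a `component_densities` object from per-1000-kcal values supplied
#' directly (for instance cup/ounce-equivalent densities from a
#' food-pattern equivalents table, for scoring under the imperial
#' standards). The `fatty_acids` entry is the (PUFA+MUFA)/SFA ratio,
#' `sodium` is grams per 1000 kcal, and `added_sugars`/`saturated_fats` are
#' percent of energy.
#'
#' @param x Named numeric vector covering all 13 components.
#' @param energy_kcal Total energy the densities were computed from
#'   (informational).
#' @return A `component_densities` object.
#' @export
as_component_densities <- function(x, energy_kcal = NA_real_) {
  comps <- empty_component_vector()
  missing_comps <- setdiff(names(comps), names(x))
  if (length(missing_comps) > 0) {
    mhei_abort(
      paste0("missing density entries: ", paste(missing_comps, collapse = ", ")),
      "mhei_densities_schema_error"
    )
  }
  comps[] <- x[names(comps)]
  new_component_densities(comps, energy_kcal)
}

#' @export
print.component_densities <- function(x, ...) {
  cat("<component_densities> per 1000 kcal",
      if (x$zero_energy) "(zero energy)" else
        sprintf("(total energy %.0f kcal)", x$energy_kcal), "\n")
  print(round(x$components, 3))
  invisible(x)
}

#' Per-1000-kcal component densities of a subject's intake
#'
#' Pools all of the subject's available days (summing intake and energy —
#' equivalent to a day-weighted average for densities), converts each food
#' or menu item through the equivalents machinery, and divides the
#' component totals by total energy in units of 1000 kcal. Added sugars
#' are expressed as percent of energy at 4 kcal/g, saturated fats at
#' 9 kcal/g; the fatty-acid entry is the ratio (PUFA+MUFA)/SFA of the
#' pooled fat grams; sodium is in grams per 1000 kcal.
#'
#' @param records An `intake_table` (or data frame) holding one subject's
#'   rows; if several subjects are present an error is raised — use
#'   [score_cohort()] for many subjects.
#' @param db A `food_db`.
#' @param recipes Optional `recipe_table` resolving menu-item ids that are
#'   not in the food database.
#' @return A `component_densities` object. If total energy is zero the
#'   `zero_energy` flag is set and densities are undefined (all zero); the
#'   scorer gives such records 0 points throughout.
#' @examples
#' db <- make_food_db(seed = 1)
#' cohort <- make_cohort(cohort_spec(n_subjects = 1, seed = 1,
#'                                   profile = "near_max"), db)
#' component_densities(cohort$intake, db)
#' @export
component_densities <- function(records, db, recipes = NULL) {
  if (!inherits(records, "intake_table")) records <- intake_table(records)
  if (length(unique(records$subject_id)) > 1) {
    mhei_abort("component_densities expects a single subject",
               "mhei_intake_schema_error")
  }
  total <- zero_contributions()
  for (i in seq_len(nrow(records))) {
    id <- records$food_id[i]
    g <- records$grams[i]
    rec <- db_record(db, id)
    if (!is.null(rec)) {
      total <- add_contributions(total, food_contributions(g, rec, db))
    } else if (!is.null(recipes) && id %in% recipes$menu_id) {
      per100 <- menu_contributions_per_100g(recipes, id, db)
      total <- add_contributions(total, scale_contributions(per100, g / 100))
    } else {
      mhei_abort(
        sprintf("intake item '%s' is neither a database food nor a recipe menu", id),
        "mhei_intake_dangling_error"
      )
    }
  }
  energy <- total$energy_kcal
  if (energy <= 0) {
    return(new_component_densities(empty_component_vector(), 0,
                                   zero_energy = TRUE))
  }
  per1000 <- energy / 1000
  comps <- total$components / per1000
  comps["sodium"] <- (total$sodium_mg / 1000) / per1000
  comps["added_sugars"] <- total$added_sugars_g * 4 / energy * 100
  comps["saturated_fats"] <- total$sfa_g * 9 / energy * 100
  unsat <- total$pufa_g + total$mufa_g
  comps["fatty_acids"] <- if (total$sfa_g > 0) {
    unsat / total$sfa_g
  } else if (unsat > 0) Inf else NaN
  new_component_densities(comps, energy)
}

#' Score an adequacy component
#'
#' Linear proportional scoring: points accrue proportionally with density
#' up to the standard for maximum score, then cap.
#'
#' @param density Consumption density per 1000 kcal (non-negative).
#' @param standard_for_max Density earning the full `max_points`.
#' @param max_points Maximum points for the component.
#' @return The component score in `[0, max_points]`.
#' @examples
#' score_adequacy(141, 141, 5)  # 5: at the standard
#' score_adequacy(70.5, 141, 5) # 2.5: half the standard
#' @export
score_adequacy <- function(density, standard_for_max, max_points) {
  stopifnot(standard_for_max > 0)
  max_points * pmin(1, pmax(0, density) / standard_for_max)
}

#' Score a moderation component
#'
#' Full points at or below the standard for maximum score, zero at or
#' above the standard for minimum score, linear in between.
#'
#' @param density Consumption density per 1000 kcal.
#' @param standard_for_max Density at/below which the full points are
#'   earned.
#' @param standard_for_min Density at/above which zero points are earned
#'   (must exceed `standard_for_max`).
#' @inheritParams score_adequacy
#' @return The component score in `[0, max_points]`.
#' @examples
#' score_moderation(32, 32, 76, 10)  # 10
#' score_moderation(54, 32, 76, 10)  # 5: midpoint
#' score_moderation(76, 32, 76, 10)  # 0
#' @export
score_moderation <- function(density, standard_for_max, standard_for_min,
                             max_points) {
  stopifnot(standard_for_min > standard_for_max, standard_for_max >= 0)
  frac <- (standard_for_min - density) / (standard_for_min - standard_for_max)
  max_points * pmin(1, pmax(0, frac))
}

#' Score the fatty-acid ratio component
#'
#' The (PUFA+MUFA)/SFA ratio earns full points at or above `ratio_max`
#' (2.5) and zero at or below `ratio_min` (1.2), linear in between. A
#' degenerate diet with no fat at all (ratio `NaN`) scores 0; no saturated
#' fat but some unsaturated fat (ratio `Inf`) scores the maximum.
#'
#' @param ratio (PUFA+MUFA)/SFA.
#' @param max_points Maximum points (10).
#' @param ratio_max,ratio_min Thresholds for full and zero points.
#' @return The component score.
#' @examples
#' score_fatty_acids(2.5)   # 10
#' score_fatty_acids(1.85)  # 5
#' score_fatty_acids(1.2)   # 0
#' @export
score_fatty_acids <- function(ratio, max_points = 10, ratio_max = 2.5,
                              ratio_min = 1.2) {
  if (is.nan(ratio)) return(0)
  if (is.infinite(ratio)) return(max_points)
  frac <- (ratio - ratio_min) / (ratio_max - ratio_min)
  max_points * min(1, max(0, frac))
}

#' Total index score
#'
#' Dispatches each of the 13 components to its scorer under the given
#' standards and sums to the 0-100 total. Zero-energy records score 0 on
#' every component.
#'
#' @param densities A `component_densities` object (or named vector
#'   accepted by [as_component_densities()]).
#' @param standards A `scoring_standards`, preset name, or standards file
#'   path (see [resolve_standards()]).
#' @return An object of class `index_score`: list with `components` (named
#'   numeric, unrounded), `total` and `standards_id`.
#' @examples
#' std <- mhei2015_standards()
#' at_max <- std$table$standard_for_max
#' names(at_max) <- std$table$component
#' total_score(as_component_densities(at_max), std)$total  # 100
#' @export
total_score <- function(densities, standards = mhei2015_standards()) {
  standards <- resolve_standards(standards)
  if (!inherits(densities, "component_densities")) {
    densities <- as_component_densities(densities)
  }
  tab <- standards$table
  reg <- mhei_components()
  scores <- stats::setNames(numeric(nrow(tab)), tab$component)
  if (!densities$zero_energy) {
    for (i in seq_len(nrow(tab))) {
      comp <- tab$component[i]
      kind <- reg$kind[reg$component == comp]
      d <- densities$components[[comp]]
      scores[comp] <- switch(
        kind,
        adequacy = score_adequacy(d, tab$standard_for_max[i], tab$max_points[i]),
        moderation = score_moderation(d, tab$standard_for_max[i],
                                      tab$standard_for_min[i], tab$max_points[i]),
        ratio = score_fatty_acids(d, tab$max_points[i],
                                  ratio_max = tab$standard_for_max[i],
                                  ratio_min = tab$standard_for_min[i])
      )
    }
  }
  structure(
    list(components = scores, total = sum(scores), standards_id = standards$id),
    class = "index_score"
  )
}

#' @export
print.index_score <- function(x, ...) {
  cat(sprintf("<index_score: %s> total %.1f / 100\n", x$standards_id, x$total))
  print(round(x$components, 1))
  invisible(x)
}

#' Percent of standard per component
#'
#' Compliance export for radar-style figures: for adequacy components,
#' 100 x min(1, density/standard); for moderation and fatty-acid
#' components, the score as a percent of maximum points. Overconsumption is
#' capped at 100.
#'
#' @inheritParams total_score
#' @return Named numeric vector of 13 percentages in `[0, 100]`.
#' @export
percent_of_standard <- function(densities, standards = mhei2015_standards()) {
  standards <- resolve_standards(standards)
  if (!inherits(densities, "component_densities")) {
    densities <- as_component_densities(densities)
  }
  tab <- standards$table
  reg <- mhei_components()
  out <- stats::setNames(numeric(nrow(tab)), tab$component)
  if (densities$zero_energy) {
    # moderation components still earn full compliance at zero density
    score <- total_score(new_component_densities(empty_component_vector(), 1),
                         standards)
    return(stats::setNames(
      100 * score$components / tab$max_points, tab$component
    ))
  }
  score <- total_score(densities, standards)
  for (i in seq_len(nrow(tab))) {
    comp <- tab$component[i]
    kind <- reg$kind[reg$component == comp]
    out[comp] <- if (kind == "adequacy") {
      100 * min(1, densities$components[[comp]] / tab$standard_for_max[i])
    } else {
      100 * score$components[[comp]] / tab$max_points[i]
    }
  }
  out
}

#' Score a cohort of intake records
#'
#' Computes densities and the index score for every subject in an intake
#' table.
#'
#' @param intake An `intake_table` (any number of subjects).
#' @param db A `food_db`.
#' @param standards Standards set, preset name, or file path.
#' @param recipes Optional `recipe_table`.
#' @return A data frame with one row per subject: `subject_id`, the 13
#'   unrounded component scores, `total` and `standards_id`.
#' @export
score_cohort <- function(intake, db, standards = mhei2015_standards(),
                         recipes = NULL) {
  if (!inherits(intake, "intake_table")) intake <- intake_table(intake)
  standards <- resolve_standards(standards)
  subjects <- unique(intake$subject_id)
  rows <- lapply(subjects, function(s) {
    d <- component_densities(intake[intake$subject_id == s, , drop = FALSE],
                             db, recipes)
    sc <- total_score(d, standards)
    as.data.frame(c(list(subject_id = s), as.list(sc$components),
                    list(total = sc$total, standards_id = sc$standards_id)),
                  stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
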