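# Registry of the 13 index components. Order here is the canonical order
# used by every density vector, score vector and CSV column layout.

.mhei_component_registry <- function() {
  data.frame(
    component = c(
      "total_fruits", "whole_fruits", "total_vegetables", "greens_beans",
      "whole_grains", "dairy", "total_protein_foods", "seafood_plant_proteins",
      "fatty_acids", "refined_grains", "sodium", "added_sugars",
      "saturated_fats"
    ),
    kind = c(
      "adequacy", "adequacy", "adequacy", "adequacy",
      "adequacy", "adequacy", "adequacy", "adequacy",
      "ratio", "moderation", "moderation", "moderation", "moderation"
    ),
    max_points = c(5, 5, 5, 5, 10, 10, 5, 5, 10, 10, 10, 10, 10),
    metric_unit = c(
      "g_eq_per_1000kcal", "g_eq_per_1000kcal", "g_eq_per_1000kcal",
      "g_eq_per_1000kcal", "g_eq_per_1000kcal", "mg_calcium_per_1000kcal",
      "g_protein_per_1000kcal", "g_protein_per_1000kcal", "ratio",
      "g_eq_per_1000kcal", "g_per_1000kcal", "pct_energy", "pct_energy"
    ),
    imperial_unit = c(
      "cup_eq_per_1000kcal", "cup_eq_per_1000kcal", "cup_eq_per_1000kcal",
      "cup_eq_per_1000kcal", "oz_eq_per_1000kcal", "cup_eq_per_1000kcal",
      "oz_eq_per_1000kcal", "oz_eq_per_1000kcal", "ratio",
      "oz_eq_per_1000kcal", "g_per_1000kcal", "pct_energy", "pct_energy"
    ),
    # components whose standards are derived by calibration (food groups,
    # protein and dairy); nutrient components pass through unchanged
    calibrated = c(rep(TRUE, 8), FALSE, TRUE, FALSE, FALSE, FALSE),
    # rounding applied to a calibrated standard: whole gram equivalents for
    # the food-group components, one decimal for protein and dairy
    rounding = c(
      "integer", "integer", "integer", "integer", "integer",
      "one_decimal", "one_decimal", "one_decimal", NA,
      "integer", NA, NA, NA
    ),
    stringsAsFactors = FALSE
  )
}

#' Index component registry
#'
#' Returns the registry of the 13 diet-quality index components in canonical
#' order: nine adequacy components (more is better, capped at the standard
#' for maximum score), the fatty-acid ratio, and four moderation components
#' (less is better, zero points at or above the standard for minimum score).
#'
#' @return A data frame with one row per component and columns `component`,
#'   `kind` (`"adequacy"`, `"ratio"` or `"moderation"`), `max_points`,
#'   `metric_unit`, `imperial_unit`, `calibrated` (whether the metric
#'   standard is derived by calibration) and `rounding` (rounding rule for a
#'   calibrated standard).
#' @examples
#' mhei_components()
#' @export
mhei_components <- function() {
  .mhei_component_registry()
}

# Canonical component name vector, for internal use.
mhei_component_names <- function() {
  .mhei_component_registry()$component
}

# Internal condition helper: all package validation errors carry a
# subclass so callers can distinguish them.
mhei_abort <- function(message, class, ...) {
  stop(errorCondition(message, ..., class = c(class, "mhei_error")))
}

# round half away from zero (base round() rounds half to even)
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
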