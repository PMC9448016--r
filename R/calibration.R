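# Calibration: derive metric standards for maximum score from paired
# imperial/metric consumption summaries. The assumption is fulfillment-
# proportion conservation: the cohort's metric consumption of a component
# meets the same proportion of its (unknown) metric standard as its
# imperial consumption meets of the imperial standard, so
#   metric standard = metric mean x imperial standard / imperial mean.

#' Calibrate one component's metric standard
#'
#' Applies the calibration formula to one component's paired cohort means.
#' For protein and dairy components the metric mean is in grams of protein
#' or milligrams of calcium; for food-group components in gram
#' equivalents; the imperial mean is in cup or ounce equivalents — the
#' formula is the same. Rounding (half away from zero) is applied once, to
#' the final standard: to the nearest whole gram equivalent for food-group
#' components, to one decimal for protein and dairy.
#'
#' @param pc A list or one-row data frame with `component`, `mean_imperial`
#'   (> 0), `mean_metric` (>= 0) and optionally `n_subjects`.
#' @param imperial_standard_for_max The imperial standard for maximum score
#'   of the component.
#' @param rounding `"integer"`, `"one_decimal"`, or `NULL` to look the rule
#'   up from the component registry.
#' @return A list of class `calibrated_standard` with `component`,
#'   `standard_for_max` (rounded), `standard_for_max_unrounded` and
#'   `rounding`.
#' @examples
#' # cohort means 0.71 cup eq and 103 g eq per 1000 kcal, standard 1.1:
#' calibrate_component(
#'   list(component = "total_vegetables", mean_imperial = 0.71,
#'        mean_metric = 103),
#'   imperial_standard_for_max = 1.1
#' )$standard_for_max  # 160
#' @export
calibrate_component <- function(pc, imperial_standard_for_max,
                                rounding = NULL) {
  pc <- as.list(pc)
  if (is.na(pc$mean_imperial) || pc$mean_imperial <= 0) {
    mhei_abort(
      sprintf("component '%s': imperial mean consumption is zero; cannot calibrate",
              pc$component),
      "mhei_calibration_error"
    )
  }
  if (is.null(rounding)) {
    reg <- mhei_components()
    rounding <- reg$rounding[reg$component == pc$component]
    if (length(rounding) != 1 || is.na(rounding)) rounding <- "integer"
  }
  raw_std <- pc$mean_metric * imperial_standard_for_max / pc$mean_imperial
  digits <- if (rounding == "one_decimal") 1L else 0L
  structure(
    list(component = pc$component,
         standard_for_max = round_half_away(raw_std, digits),
         standard_for_max_unrounded = raw_std,
         rounding = rounding),
    class = "calibrated_standard"
  )
}

#' Metric standard for minimum score of refined grains
#'
#' The only moderation food-group component needs a metric standard for
#' minimum score too; it is set from the calibrated metric maximum-score
#' standard scaled by the imperial minimum/maximum ratio, rounded to the
#' nearest whole gram equivalent.
#'
#' @param metric_standard_for_max Calibrated metric standard for maximum
#'   score (g equivalents per 1000 kcal).
#' @param imperial_min,imperial_max Imperial standards for minimum and
#'   maximum score (oz equivalents per 1000 kcal).
#' @return The metric standard for minimum score (integer grams).
#' @examples
#' calibrate_refined_grains_min(32, 4.3, 1.8)  # 76
#' @export
calibrate_refined_grains_min <- function(metric_standard_for_max,
                                         imperial_min, imperial_max) {
  stopifnot(metric_standard_for_max > 0, imperial_min > 0, imperial_max > 0)
  out <- round_half_away(metric_standard_for_max * imperial_min / imperial_max)
  if (imperial_min <= imperial_max) {
    warning("imperial minimum-score standard does not exceed the maximum-score standard; the calibrated moderation band is degenerate",
            call. = FALSE)
  }
  out
}

#' Calibrate a full metric standards set
#'
#' From per-subject per-component consumption densities under the imperial
#' and metric methodologies (same subjects, same cohort), computes the
#' unrounded cohort means, calibrates every food-group, protein and dairy
#' component, derives the refined-grains minimum-score standard, and copies
#' the nutrient-only components (fatty-acid ratio, sodium, added sugars,
#' saturated fats) unchanged from the imperial standards, since they are
#' already metric.
#'
#' @param imperial_densities Data frame: `subject_id` plus one column per
#'   calibrated component with imperial (cup/oz-equivalent) densities per
#'   1000 kcal.
#' @param metric_densities Data frame with the same layout holding metric
#'   densities (g equivalents, g protein, mg calcium per 1000 kcal).
#' @param imperial_standards The imperial `scoring_standards` (default the
#'   built-in).
#' @param id Identifier for the resulting standards set.
#' @return A metric `scoring_standards`.
#' @seealso [make_paired_consumption()] for generating test inputs.
#' @export
calibrate_all <- function(imperial_densities, metric_densities,
                          imperial_standards = hei2015_standards(),
                          id = "mhei-calibrated") {
  imperial_standards <- resolve_standards(imperial_standards)
  reg <- mhei_components()
  cal_comps <- reg$component[reg$calibrated]
  for (df_name in c("imperial", "metric")) {
    df <- if (df_name == "imperial") imperial_densities else metric_densities
    missing_cols <- setdiff(cal_comps, names(df))
    if (length(missing_cols) > 0) {
      mhei_abort(
        sprintf("%s density table missing component columns: %s",
                df_name, paste(missing_cols, collapse = ", ")),
        "mhei_calibration_error"
      )
    }
  }
  itab <- imperial_standards$table
  out <- itab
  out$unit <- reg$metric_unit[match(out$component, reg$component)]
  for (comp in cal_comps) {
    mean_imp <- mean(imperial_densities[[comp]])
    mean_met <- mean(metric_densities[[comp]])
    cs <- calibrate_component(
      list(component = comp, mean_imperial = mean_imp, mean_metric = mean_met,
           n_subjects = nrow(imperial_densities)),
      imperial_standard_for_max = itab$standard_for_max[itab$component == comp]
    )
    out$standard_for_max[out$component == comp] <- cs$standard_for_max
  }
  rg <- "refined_grains"
  out$standard_for_min[out$component == rg] <- calibrate_refined_grains_min(
    out$standard_for_max[out$component == rg],
    imperial_min = itab$standard_for_min[itab$component == rg],
    imperial_max = itab$standard_for_max[itab$component == rg]
  )
  scoring_standards(out, id = id)
}
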