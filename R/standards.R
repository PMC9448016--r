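# Scoring standards: per-component thresholds that map consumption density
# (per 1000 kcal) to points. Two built-ins: the metric standards and the
# original imperial standards they were calibrated against.

#' Construct a scoring-standards object
#'
#' @param df Data frame with columns `component`, `max_points`,
#'   `standard_for_max` and `standard_for_min` (`NA` for adequacy
#'   components; for the fatty-acid ratio both thresholds are present:
#'   `standard_for_max` is the ratio earning full points,
#'   `standard_for_min` the ratio earning zero), and `unit`.
#' @param id Identifier: `"mhei2015"`, `"hei2015"` or a custom label.
#' @return An object of class `scoring_standards`.
#' @seealso [mhei2015_standards()], [hei2015_standards()]
#' @export
scoring_standards <- function(df, id = "custom") {
  need <- c("component", "max_points", "standard_for_max",
            "standard_for_min", "unit")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    mhei_abort(
      paste0("standards table missing columns: ", paste(missing_cols, collapse = ", ")),
      "mhei_standards_schema_error"
    )
  }
  df <- as.data.frame(df)[need]
  reg <- mhei_components()
  if (!setequal(df$component, reg$component)) {
    mhei_abort("standards must cover exactly the 13 index components",
               "mhei_standards_schema_error")
  }
  df <- df[match(reg$component, df$component), , drop = FALSE]
  rownames(df) <- NULL
  if (sum(df$max_points) != 100) {
    mhei_abort("component max points must sum to 100",
               "mhei_standards_value_error")
  }
  if (any(df$standard_for_max <= 0, na.rm = TRUE)) {
    mhei_abort("standards for maximum score must be positive",
               "mhei_standards_value_error")
  }
  kind <- reg$kind[match(df$component, reg$component)]
  mod <- kind == "moderation"
  if (any(is.na(df$standard_for_min[mod])) ||
      any(df$standard_for_min[mod] <= df$standard_for_max[mod])) {
    mhei_abort(
      "moderation components need standard_for_min > standard_for_max",
      "mhei_standards_value_error"
    )
  }
  structure(list(table = df, id = id), class = "scoring_standards")
}

#' @export
print.scoring_standards <- function(x, ...) {
  cat(sprintf("<scoring_standards: %s>\n", x$id))
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Built-in metric scoring standards
#'
#' The metric standards for the 13 components, per 1000 kcal: gram
#' equivalents for the food-group components, milligrams of calcium for
#' dairy, grams of protein for the protein components, and unchanged
#' nutrient thresholds for sodium (g), added sugars and saturated fats (%
#' of energy) and the (PUFA+MUFA)/SFA ratio. These are the standards
#' obtained by calibrating the imperial standards against a national
#' 24-hour-recall cohort scored with both methodologies.
#'
#' @return A `scoring_standards` object with id `"mhei2015"`.
#' @examples
#' mhei2015_standards()
#' @export
mhei2015_standards <- function() {
  reg <- mhei_components()
  df <- data.frame(
    component = reg$component,
    max_points = reg$max_points,
    standard_for_max = c(141, 60, 160, 29, 31, 412, 15.6, 3.3,
                         2.5, 32, 1.1, 6.5, 8),
    standard_for_min = c(NA, NA, NA, NA, NA, NA, NA, NA,
                         1.2, 76, 2.0, 26, 16),
    unit = reg$metric_unit,
    stringsAsFactors = FALSE
  )
  scoring_standards(df, id = "mhei2015")
}

#' Built-in imperial scoring standards
#'
#' The original HEI-2015 standards, per 1000 kcal: cup equivalents for the
#' fruit, vegetable and dairy components, ounce equivalents for grains and
#' protein foods, and the same nutrient thresholds as the metric standards.
#' Densities fed to the scorer under these standards must already be in
#' cup/ounce equivalents (as from a food-pattern equivalents table).
#'
#' @return A `scoring_standards` object with id `"hei2015"`.
#' @examples
#' hei2015_standards()
#' @export
hei2015_standards <- function() {
  reg <- mhei_components()
  df <- data.frame(
    component = reg$component,
    max_points = reg$max_points,
    standard_for_max = c(0.8, 0.4, 1.1, 0.2, 1.5, 1.3, 2.5, 0.8,
                         2.5, 1.8, 1.1, 6.5, 8),
    standard_for_min = c(NA, NA, NA, NA, NA, NA, NA, NA,
                         1.2, 4.3, 2.0, 26, 16),
    unit = reg$imperial_unit,
    stringsAsFactors = FALSE
  )
  scoring_standards(df, id = "hei2015")
}

#' Resolve a standards preset or file
#'
#' @param x A `scoring_standards`, the name of a preset (`"mhei2015"` or
#'   `"hei2015"`), or a path to a standards JSON/YAML file.
#' @return A `scoring_standards`.
#' @export
resolve_standards <- function(x) {
  if (inherits(x, "scoring_standards")) return(x)
  if (is.character(x) && length(x) == 1) {
    if (x == "mhei2015") return(mhei2015_standards())
    if (x == "hei2015") return(hei2015_standards())
    if (file.exists(x)) return(read_standards(x))
  }
  mhei_abort(
    "standards must be a scoring_standards object, 'mhei2015', 'hei2015', or a file path",
    "mhei_standards_schema_error"
  )
}

#' Read / write scoring standards
#'
#' Standards are serialised as JSON (or YAML, by file extension) with the
#' schema `{id, components: [{component, max_points, standard_for_max,
#' standard_for_min, unit}]}`; `standard_for_min` is omitted or null for
#' adequacy components.
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_standards()` a `scoring_standards`; `write_standards()`
#'   the path, invisibly.
#' @export
read_standards <- function(path) {
  ext <- tolower(tools::file_ext(path))
  obj <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  comps <- obj$components
  df <- do.call(rbind, lapply(comps, function(c) {
    data.frame(
      component = c$component,
      max_points = c$max_points,
      standard_for_max = c$standard_for_max,
      standard_for_min = if (is.null(c$standard_for_min)) NA_real_ else c$standard_for_min,
      unit = c$unit,
      stringsAsFactors = FALSE
    )
  }))
  scoring_standards(df, id = if (is.null(obj$id)) "custom" else obj$id)
}

#' @rdname read_standards
#' @param standards A `scoring_standards`.
#' @export
write_standards <- function(standards, path) {
  stopifnot(inherits(standards, "scoring_standards"))
  comps <- lapply(seq_len(nrow(standards$table)), function(i) {
    row <- standards$table[i, ]
    out <- list(component = row$component, max_points = row$max_points,
                standard_for_max = row$standard_for_max, unit = row$unit)
    if (!is.na(row$standard_for_min)) out$standard_for_min <- row$standard_for_min
    out
  })
  obj <- list(id = standards$id, components = comps)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(obj, path)
  } else {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
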