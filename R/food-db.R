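# Food database: one row per food, per-100-g nutrient contents plus a
# five-digit code. Per-100-g is the canonical basis everywhere in the
# package; conversions happen at the edges.

FOOD_DB_COLUMNS <- c("food_id", "name", "code", "energy_kcal", "protein_g",
                     "calcium_mg", "pufa_g", "mufa_g", "sfa_g",
                     "added_sugars_g", "sodium_mg")

#' Construct a food database
#'
#' Builds a validated food database from a data frame with one row per food
#' and per-100-g contents. Codes are parsed eagerly (malformed codes are an
#' error); value-level problems (negative nutrients, missing raw
#' counterparts) are reported by [validate_database()], not raised here, so
#' that imperfect data can be inspected.
#'
#' @param records Data frame with columns `food_id`, `name`, `code`,
#'   `energy_kcal`, `protein_g`, `calcium_mg`, `pufa_g`, `mufa_g`, `sfa_g`,
#'   `added_sugars_g`, `sodium_mg` (all nutrient columns per 100 g).
#' @param factor_overrides Optional named numeric vector: explicit
#'   gram-equivalent factors by `food_id`, used for processed foods whose
#'   raw counterpart is absent from the database.
#' @param legumes Legume allocation switch, see [component_of()].
#' @return An object of class `food_db`.
#' @examples
#' db <- food_database(data.frame(
#'   food_id = "apple_raw", name = "Apple, raw", code = "FO010",
#'   energy_kcal = 58, protein_g = 0.3, calcium_mg = 6, pufa_g = 0.1,
#'   mufa_g = 0, sfa_g = 0, added_sugars_g = 0, sodium_mg = 1
#' ))
#' validate_database(db)
#' @export
food_database <- function(records, factor_overrides = NULL,
                          legumes = c("all", "vegetables")) {
  legumes <- match.arg(legumes)
  missing_cols <- setdiff(FOOD_DB_COLUMNS, names(records))
  if (length(missing_cols) > 0) {
    mhei_abort(
      paste0("food database missing columns: ", paste(missing_cols, collapse = ", ")),
      "mhei_db_schema_error"
    )
  }
  records <- as.data.frame(records)[FOOD_DB_COLUMNS]
  records$food_id <- as.character(records$food_id)
  records$name <- as.character(records$name)
  records$code <- toupper(trimws(as.character(records$code)))
  codes <- lapply(records$code, parse_food_code)
  records$component_type <- vapply(codes, function(c) c$component_type, character(1))
  records$group <- vapply(codes, function(c) c$group, character(1))
  records$item_number <- vapply(codes, function(c) c$item_number, integer(1))
  records$processing_state <- vapply(codes, function(c) c$processing_state, integer(1))
  if (!is.null(factor_overrides)) {
    stopifnot(is.numeric(factor_overrides), !is.null(names(factor_overrides)))
  }
  structure(
    list(records = records,
         factor_overrides = factor_overrides,
         legumes = legumes),
    class = "food_db"
  )
}

#' @export
print.food_db <- function(x, ...) {
  cat(sprintf("<food_db> %d foods (legume allocation: %s)\n",
              nrow(x$records), x$legumes))
  invisible(x)
}

#' Read / write a food database CSV
#'
#' The CSV has one row per food with the exact column set documented in
#' [food_database()]; all nutrient columns are per 100 g.
#'
#' @param path File path.
#' @param ... Passed on to [food_database()].
#' @return `read_food_db()` a `food_db`; `write_food_db()` the path,
#'   invisibly.
#' @export
read_food_db <- function(path, ...) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(food_id = "character", code = "character"))
  food_database(df, ...)
}

#' @rdname read_food_db
#' @param db A `food_db`.
#' @export
write_food_db <- function(db, path) {
  stopifnot(inherits(db, "food_db"))
  utils::write.csv(db$records[FOOD_DB_COLUMNS], path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

# Look up a record by food_id; NULL if absent.
db_record <- function(db, food_id) {
  i <- match(food_id, db$records$food_id)
  if (is.na(i)) return(NULL)
  db$records[i, , drop = FALSE]
}

# Counterpart of an F/V/G record at the given processing state
# (same component type, group and item number); NULL if absent.
db_counterpart <- function(db, record, state) {
  r <- db$records
  i <- which(r$component_type == record$component_type &
             r$group == record$group &
             r$item_number == record$item_number &
             r$processing_state == state)
  if (length(i) == 0) return(NULL)
  r[i[1], , drop = FALSE]
}

#' Validate a food database
#'
#' Checks record- and database-level invariants and returns every violation
#' as data (one row per issue), never as an exception. Rules checked:
#' unique `food_id`s; non-negative energy and nutrient contents; protein
#' plus fat mass at most 100 g per 100 g; every processed food of a
#' fruit/vegetable/grain group has a resolvable unity-reference counterpart
#' (raw form, or cooked form for the legume group) unless a per-record
#' factor override is supplied.
#'
#' @param db A `food_db`.
#' @return A data frame with columns `food_id`, `rule`, `message`, ordered
#'   by `food_id`; zero rows when the database is clean.
#' @seealso [write_validation_report()]
#' @export
validate_database <- function(db) {
  stopifnot(inherits(db, "food_db"))
  r <- db$records
  issues <- list()
  add <- function(food_id, rule, message) {
    issues[[length(issues) + 1L]] <<- data.frame(
      food_id = food_id, rule = rule, message = message,
      stringsAsFactors = FALSE
    )
  }
  dup <- r$food_id[duplicated(r$food_id)]
  for (id in unique(dup)) {
    add(id, "duplicate_id", sprintf("food_id '%s' appears more than once", id))
  }
  nutrient_cols <- c("energy_kcal", "protein_g", "calcium_mg", "pufa_g",
                     "mufa_g", "sfa_g", "added_sugars_g", "sodium_mg")
  for (i in seq_len(nrow(r))) {
    row <- r[i, ]
    for (col in nutrient_cols) {
      v <- row[[col]]
      if (is.na(v) || v < 0) {
        add(row$food_id, "range",
            sprintf("%s = %s must be a non-negative number", col, format(v)))
      }
    }
    mass <- row$protein_g + row$pufa_g + row$mufa_g + row$sfa_g
    if (!is.na(mass) && mass > 100) {
      add(row$food_id, "mass_balance",
          sprintf("protein + fat mass %.1f g exceeds 100 g per 100 g", mass))
    }
    if (row$component_type %in% c("F", "V", "G") &&
        !is.na(row$processing_state)) {
      is_legume <- row$component_type == "V" && row$group == "L"
      ref_state <- if (is_legume) 1L else 0L
      needs_ref <- row$processing_state != ref_state
      if (needs_ref) {
        ref <- db_counterpart(db, row, ref_state)
        has_override <- !is.null(db$factor_overrides) &&
          row$food_id %in% names(db$factor_overrides)
        if (is.null(ref) && !has_override) {
          add(row$food_id, "no_raw_reference",
              sprintf("no %s counterpart for code %s; factor 1 will be assumed",
                      if (is_legume) "cooked (unity-reference)" else "raw",
                      row$code))
        } else if (!is.null(ref) && ref$energy_kcal <= 0) {
          add(row$food_id, "zero_reference_energy",
              sprintf("unity-reference food '%s' has zero energy density", ref$food_id))
        }
      }
    }
  }
  if (length(issues) == 0) {
    return(data.frame(food_id = character(0), rule = character(0),
                      message = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, issues)
  out <- out[order(out$food_id, out$rule), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a validation report as JSON lines
#'
#' One issue per line, each a JSON object with `food_id`, `rule` and
#' `message`.
#'
#' @param report Data frame from [validate_database()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_validation_report <- function(report, path) {
  lines <- vapply(seq_len(nrow(report)), function(i) {
    jsonlite::toJSON(as.list(report[i, ]), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
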