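# Five-digit food coding system.
#
# A code carries everything needed to allocate a food to index components
# and to pick its gram-equivalent factor:
#   digit 1: component type, one of F V G P D X
#   digit 2: group within the type (alphabet below)
#   digits 3-4: item number 00-99; a raw food and its processed forms share it
#   digit 5: processing state, 0 = raw, 1 = processed
# "X" stands alone (the food contributes to no component); P and D codes
# stop after the group letter because their equivalents come from protein
# and calcium content alone.

#' Group alphabet of the food coding system
#'
#' The second code character depends on the component type. The alphabet
#' covers every distinction the 13-component scorer needs; users with a
#' differently-grouped database can remap before coding.
#'
#' @return A named list: for each component type (`F`, `V`, `G`, `P`, `D`) a
#'   named character vector mapping group letter to a human-readable label.
#' @examples
#' food_code_groups()$V
#' @export
food_code_groups <- function() {
  list(
    F = c(J = "fruit juice", C = "citrus/melons/berries", O = "other whole fruit"),
    V = c(D = "dark green vegetables", R = "red/orange vegetables",
          L = "legumes", S = "starchy vegetables", O = "other vegetables"),
    G = c(W = "whole grains", R = "refined grains"),
    P = c(M = "meat", U = "poultry", E = "eggs", S = "seafood",
          N = "nuts/seeds", Y = "soy", L = "legumes as protein"),
    D = c(M = "milk", Y = "yogurt", C = "cheese", O = "other dairy")
  )
}

#' Parse a food code
#'
#' Parses and validates a code of the five-digit food coding system. Codes
#' are case-insensitive on input; the canonical form (from
#' [format_food_code()]) is upper case. The grammar is: `"X"` alone; a
#' component type in `F`/`V`/`G` followed by a group letter, a two-digit
#' item number and a processing-state digit (0 raw, 1 processed); or `P`/`D`
#' followed by a group letter only.
#'
#' @param text A single 1-5 character string.
#' @return An object of class `food_code`: a list with `component_type`,
#'   `group`, `item_number` and `processing_state` (the latter three `NA`
#'   where the grammar omits them).
#' @examples
#' parse_food_code("FC010")  # a raw berry-group fruit
#' parse_food_code("PS")     # a seafood protein food
#' parse_food_code("X")      # contributes to no component
#' @seealso [format_food_code()], [component_of()]
#' @export
parse_food_code <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    mhei_abort("food code must be a single string", "mhei_code_length_error")
  }
  raw <- toupper(trimws(text))
  n <- nchar(raw)
  if (n < 1L || n > 5L) {
    mhei_abort(
      sprintf("food code '%s' has %d characters; expected 1-5", text, n),
      "mhei_code_length_error"
    )
  }
  type <- substr(raw, 1L, 1L)
  if (!type %in% c("F", "V", "G", "P", "D", "X")) {
    mhei_abort(
      sprintf("position 1 of code '%s': unknown component type '%s'", text, type),
      "mhei_code_component_error"
    )
  }
  if (type == "X") {
    if (n != 1L) {
      mhei_abort(
        sprintf("code '%s': 'X' codes carry no further digits", text),
        "mhei_code_length_error"
      )
    }
    return(new_food_code("X", NA_character_, NA_integer_, NA_integer_))
  }
  groups <- food_code_groups()[[type]]
  if (n < 2L) {
    mhei_abort(
      sprintf("code '%s': missing group character at position 2", text),
      "mhei_code_length_error"
    )
  }
  grp <- substr(raw, 2L, 2L)
  if (!grp %in% names(groups)) {
    mhei_abort(
      sprintf("position 2 of code '%s': unknown group '%s' for component type %s",
              text, grp, type),
      "mhei_code_group_error"
    )
  }
  if (type %in% c("P", "D")) {
    if (n != 2L) {
      mhei_abort(
        sprintf("code '%s': %s codes carry only the component type and group", text, type),
        "mhei_code_length_error"
      )
    }
    return(new_food_code(type, grp, NA_integer_, NA_integer_))
  }
  # F, V, G: full five characters
  if (n != 5L) {
    mhei_abort(
      sprintf("code '%s': %s codes need 5 characters (type, group, 2-digit item, state)",
              text, type),
      "mhei_code_length_error"
    )
  }
  item <- substr(raw, 3L, 4L)
  if (!grepl("^[0-9]{2}$", item)) {
    mhei_abort(
      sprintf("positions 3-4 of code '%s': item number '%s' is not two digits", text, item),
      "mhei_code_item_error"
    )
  }
  state <- substr(raw, 5L, 5L)
  if (!state %in% c("0", "1")) {
    mhei_abort(
      sprintf("position 5 of code '%s': processing state '%s' not in {0,1}", text, state),
      "mhei_code_state_error"
    )
  }
  new_food_code(type, grp, as.integer(item), as.integer(state))
}

new_food_code <- function(type, group, item, state) {
  structure(
    list(component_type = type, group = group,
         item_number = item, processing_state = state),
    class = "food_code"
  )
}

#' Format a food code
#'
#' Inverse of [parse_food_code()]: renders the canonical upper-case string.
#'
#' @param code A `food_code` object.
#' @return A single string.
#' @export
format_food_code <- function(code) {
  stopifnot(inherits(code, "food_code"))
  if (code$component_type == "X") return("X")
  if (code$component_type %in% c("P", "D")) {
    return(paste0(code$component_type, code$group))
  }
  sprintf("%s%s%02d%d", code$component_type, code$group,
          code$item_number, code$processing_state)
}

#' @export
print.food_code <- function(x, ...) {
  cat("<food_code>", format_food_code(x), "\n")
  invisible(x)
}

#' @export
format.food_code <- function(x, ...) format_food_code(x)

#' Index components a food can contribute to
#'
#' Deterministic allocation from a food code to the set of index components
#' it can credit. Fruit-juice groups count toward total fruits only; whole
#' fruits count toward both fruit components; dark-green vegetables toward
#' total vegetables and greens and beans; seafood, nuts/seeds, soy and
#' legume protein groups toward both protein components. Legume vegetable
#' codes follow the database-level allocation switch: with `legumes =
#' "all"` (the HEI-2015 convention and default) they count toward total
#' vegetables, greens and beans, and both protein components
#' simultaneously; with `legumes = "vegetables"` only the two vegetable
#' components.
#'
#' @param code A `food_code` object (or code string, parsed on the fly).
#' @param legumes Allocation for the legume vegetable group, `"all"` or
#'   `"vegetables"`.
#' @return Character vector of component names (possibly empty, for `X`).
#' @examples
#' component_of("FC010")  # whole fruit: both fruit components
#' component_of("FJ010")  # juice: total fruits only
#' component_of("X")      # none
#' @export
component_of <- function(code, legumes = c("all", "vegetables")) {
  if (is.character(code)) code <- parse_food_code(code)
  stopifnot(inherits(code, "food_code"))
  legumes <- match.arg(legumes)
  type <- code$component_type
  grp <- code$group
  if (type == "X") return(character(0))
  if (type == "F") {
    if (grp == "J") return("total_fruits")
    return(c("total_fruits", "whole_fruits"))
  }
  if (type == "V") {
    if (grp == "D") return(c("total_vegetables", "greens_beans"))
    if (grp == "L") {
      if (legumes == "all") {
        return(c("total_vegetables", "greens_beans",
                 "total_protein_foods", "seafood_plant_proteins"))
      }
      return(c("total_vegetables", "greens_beans"))
    }
    return("total_vegetables")
  }
  if (type == "G") {
    if (grp == "W") return("whole_grains")
    return("refined_grains")
  }
  if (type == "P") {
    if (grp %in% c("S", "N", "Y", "L")) {
      return(c("total_protein_foods", "seafood_plant_proteins"))
    }
    return("total_protein_foods")
  }
  # dairy
  "dairy"
}

# Enumerate every valid code (one item number / both states for F/V/G),
# used by tests and the synthetic generator.
all_valid_codes <- function() {
  groups <- food_code_groups()
  out <- "X"
  for (type in c("F", "V", "G")) {
    for (grp in names(groups[[type]])) {
      for (state in 0:1) {
        out <- c(out, sprintf("%s%s%02d%d", type, grp, 1L, state))
      }
    }
  }
  for (type in c("P", "D")) {
    out <- c(out, paste0(type, names(groups[[type]])))
  }
  out
}
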