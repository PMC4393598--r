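# Unit-cost table: the priced resource dictionary driving all costing.

UNIT_COST_CATEGORIES <- c("appointment", "test", "regimen", "antibiotic")

# Names of the biochemistry profiles priced jointly at one weighted-average
# cost in the reference table.
BIOCHEM_PROFILES <- c("patient", "ward", "bone", "renal_bone",
                      "patient_lipid", "patient_lipoprotein",
                      "urea_electrolytes_creatinine", "liver_function_tests")

#' Validate a unit-cost table
#'
#' A unit-cost table prices appointments (EUR per scheduled appointment,
#' one price per each of the eight [appointment_types()]), diagnostic
#' tests (EUR per test, including weighted-average catch-all entries
#' `BIOCHEM_PROFILE` and `OTHER_TEST`), HAART regimens (EUR per month
#' dispensed, with an `OTHER_REGIMEN` catch-all) and prophylactic
#' antibiotics (EUR per dose).
#'
#' @param unit_costs Data frame with columns `category`, `code`,
#'   `unit_cost_eur`.
#' @return A validated `unit_cost_table` tibble.
#' @export
validate_unit_costs <- function(unit_costs) {
  unit_costs <- check_columns(unit_costs, c("category", "code", "unit_cost_eur"),
                              "unit_costs")
  check_levels(unit_costs$category, UNIT_COST_CATEGORIES, "category",
               "unit_costs")
  unit_costs$unit_cost_eur <- as.numeric(unit_costs$unit_cost_eur)
  if (any(is.na(unit_costs$unit_cost_eur)) || any(unit_costs$unit_cost_eur < 0)) {
    abort("unit_cost_eur must be a non-negative number for every row.",
          class = "ambu_validation_error")
  }
  dup <- duplicated(unit_costs[c("category", "code")])
  if (any(dup)) {
    abort("Duplicate (category, code) rows in the unit-cost table.",
          class = "ambu_uniqueness_error")
  }
  appt <- unit_costs$code[unit_costs$category == "appointment"]
  missing <- setdiff(appointment_types(), appt)
  if (length(missing)) {
    abort(sprintf("Unit-cost table is missing appointment type price(s): %s.",
                  paste(missing, collapse = ", ")),
          class = "ambu_completeness_error")
  }
  class(unit_costs) <- c("unit_cost_table", class(unit_costs))
  unit_costs
}

#' Read a unit-cost table from CSV
#'
#' @param path Path to a CSV with columns `category,code,unit_cost_eur`.
#' @return A validated `unit_cost_table` tibble.
#' @export
read_unit_costs <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Unit-cost file not found: %s.", path),
          class = "ambu_io_error")
  }
  validate_unit_costs(readr::read_csv(path, show_col_types = FALSE))
}

#' Packaged 2012 unit costs
#'
#' The unit-cost table of the reference 2012 Irish regional HIV clinic
#' analysis: staff cost per appointment for the eight appointment types
#' (from a micro-costing of staff time), cost per diagnostic test
#' (including weighted-average prices for biochemistry profiles and all
#' other tests), monthly cost per HAART regimen and cost per
#' prophylactic-antibiotic dose. All prices are 2012 euros.
#'
#' @return A `unit_cost_table` tibble with 23 rows (8 appointment, 5 test,
#'   7 regimen, 3 antibiotic prices).
#' @export
ambu_unit_costs <- function() {
  read_unit_costs(system.file("extdata", "unit_costs_2012.csv",
                              package = "ambucost", mustWork = TRUE))
}

#' Packaged 2012 resource-use counts
#'
#' Aggregate 2012 resource quantities of the reference cohort (326
#' patients, 3659 patient-months): number of appointments of each type
#' (1315 scheduled in total), number of diagnostic tests by code, months
#' of each HAART regimen dispensed (3322 in total) and antibiotic doses.
#' Keyed identically to [ambu_unit_costs()] so the two join row for row.
#'
#' @return Tibble with columns `category`, `code`, `quantity`.
#' @export
ambu_resource_use <- function() {
  out <- readr::read_csv(system.file("extdata", "resource_use_2012.csv",
                                     package = "ambucost", mustWork = TRUE),
                         show_col_types = FALSE)
  check_columns(out, c("category", "code", "quantity"), "resource_use")
}

#' Patient-month denominator of the packaged 2012 cohort
#'
#' @return 3659, the total patient-months of follow-up of the reference
#'   cohort.
#' @export
ambu_reference_patient_months <- function() 3659

# Resolve a vector of test codes against the unit-cost table. Unknown
# biochemistry profile names collapse to BIOCHEM_PROFILE; any other
# unknown code falls back to the OTHER_TEST weighted-average price with a
# warning (an error in strict mode).
resolve_test_codes <- function(codes, unit_costs, strict = FALSE) {
  if (length(codes) == 0) return(character(0))
  priced <- unit_costs$code[unit_costs$category == "test"]
  out <- ifelse(codes %in% priced, codes,
                ifelse(tolower(codes) %in% BIOCHEM_PROFILES,
                       "BIOCHEM_PROFILE", "OTHER_TEST"))
  unknown <- unique(codes[out == "OTHER_TEST" & codes != "OTHER_TEST"])
  if (length(unknown)) {
    msg <- sprintf("Test code(s) priced at the 'all other tests' average: %s.",
                   paste(unknown, collapse = ", "))
    if (strict) abort(msg, class = "ambu_pricing_error") else warn(msg)
  }
  if (!"OTHER_TEST" %in% priced && any(out == "OTHER_TEST")) {
    abort("No 'OTHER_TEST' fallback price in the unit-cost table.",
          class = "ambu_pricing_error")
  }
  out
}

resolve_regimen_codes <- function(codes, unit_costs, strict = FALSE) {
  if (length(codes) == 0) return(character(0))
  priced <- unit_costs$code[unit_costs$category == "regimen"]
  out <- ifelse(codes %in% priced, codes, "OTHER_REGIMEN")
  unknown <- unique(codes[out == "OTHER_REGIMEN" & codes != "OTHER_REGIMEN"])
  if (length(unknown)) {
    msg <- sprintf("Regimen(s) priced at the 'all other regimens' average: %s.",
                   paste(unknown, collapse = ", "))
    if (strict) abort(msg, class = "ambu_pricing_error") else warn(msg)
  }
  if (!"OTHER_REGIMEN" %in% priced && any(out == "OTHER_REGIMEN")) {
    abort("No 'OTHER_REGIMEN' fallback price in the unit-cost table.",
          class = "ambu_pricing_error")
  }
  out
}

unit_price <- function(unit_costs, category, codes) {
  tab <- unit_costs[unit_costs$category == category, ]
  idx <- match(codes, tab$code)
  if (anyNA(idx)) {
    abort(sprintf("No %s price for code(s): %s.", category,
                  paste(unique(codes[is.na(idx)]), collapse = ", ")),
          class = "ambu_pricing_error")
  }
  tab$unit_cost_eur[idx]
}
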