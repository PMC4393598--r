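# Domain model: table schemas, validation, readers and writers for the
# five input tables (patients, appointments, tests, dispensing, unit costs).

#' Factor levels of the patient-record categorical fields
#'
#' Returns the legal levels of each categorical column of the patients
#' table. `risk_factor` uses the surveillance categories of the source
#' clinic (COHP = person from a country of high HIV prevalence with no
#' other identified risk factor; IDU = injecting drug user).
#'
#' @return Named list of character vectors, one per categorical column.
#' @export
patient_levels <- function() {
  list(
    sex          = c("male", "female"),
    age_group    = c("under_50", "50_plus"),
    risk_factor  = c("COHP", "heterosexual", "MSM_bisexual", "IDU",
                     "other", "unknown"),
    patient_type = c("existing", "new_diagnosed_2012", "new_transfer"),
    years_band   = c("11_plus", "6_10", "1_5", "diagnosed_2012"),
    late_dx      = c("no", "unknown", "yes"),
    cd4_band     = c("ge500", "350_499", "200_349", "50_199", "lt50"),
    tx_vl_status = c("on_haart_suppressed", "on_haart_not_suppressed",
                     "on_haart_undetermined", "started_stopped",
                     "not_on_haart")
  )
}

#' The eight appointment types
#'
#' Every scheduled appointment is classified into exactly one of eight
#' types by three binary attributes: attended vs missed (DNA, "did not
#' attend"), clinic (routine HIV clinic vs joint antenatal-HIV clinic vs
#' a new patient's baseline visit) and whether the patient was on HAART
#' on the appointment date.
#'
#' @return Character vector of the eight type codes.
#' @export
appointment_types <- function() {
  c("DNA_offHAART", "DNA_onHAART",
    "HIV_offHAART", "HIV_onHAART",
    "ANC_offHAART", "ANC_onHAART",
    "BASE_offHAART", "BASE_onHAART")
}

patients_schema <- c("patient_id", "sex", "age_group", "risk_factor",
                     "patient_type", "years_band", "late_dx", "cd4_band",
                     "tx_vl_status")
appointments_schema <- c("patient_id", "date", "clinic", "attended",
                         "is_baseline")
tests_schema <- c("patient_id", "date", "test_code", "modality")
dispensing_schema <- c("patient_id", "item_kind", "item_code",
                       "regimen_class", "quantity", "coverage_start",
                       "coverage_stop")

check_columns <- function(df, schema, what) {
  missing <- setdiff(schema, names(df))
  if (length(missing)) {
    abort(sprintf("%s table is missing column(s): %s.",
                  what, paste(missing, collapse = ", ")),
          class = "ambu_schema_error")
  }
  as_tibble(df)[schema]
}

check_levels <- function(x, levels, column, table) {
  bad <- setdiff(unique(as.character(x[!is.na(x)])), levels)
  if (length(bad)) {
    abort(sprintf("%s$%s contains unknown level(s): %s.",
                  table, column, paste(bad, collapse = ", ")),
          class = "ambu_validation_error")
  }
}

check_dates_in_window <- function(dates, window, table, rows_label = "date") {
  d <- tryCatch(suppressWarnings(as.Date(dates)),
                error = function(e) rep(as.Date(NA), length(dates)))
  if (any(is.na(d) & !is.na(dates))) {
    abort(sprintf("%s contains unparseable %s value(s).", table, rows_label),
          class = "ambu_format_error")
  }
  out <- which(!is.na(d) & (d < window[1] | d > window[2]))
  if (length(out)) {
    abort(sprintf("%s row(s) %s have %s outside the study window [%s, %s].",
                  table, paste(head(out, 5), collapse = ", "), rows_label,
                  window[1], window[2]),
          class = "ambu_validation_error")
  }
  d
}

check_patient_ids <- function(ids, known, table) {
  bad <- which(!ids %in% known)
  if (length(bad)) {
    abort(sprintf(
      "%s row(s) %s reference patient_id(s) not in the patients table: %s.",
      table, paste(head(bad, 5), collapse = ", "),
      paste(unique(head(ids[bad], 5)), collapse = ", ")),
      class = "ambu_integrity_error")
  }
}

#' Validate a patients table
#'
#' Checks the schema, the categorical levels, uniqueness of `patient_id`
#' and the coupling between patient type and years-since-diagnosis band
#' (only patients newly diagnosed in the study year may carry the
#' `diagnosed_2012` band, and must).
#'
#' @param patients Data frame with the `patients.csv` schema.
#' @return The validated tibble (columns coerced to character/factor-free).
#' @export
validate_patients <- function(patients) {
  patients <- check_columns(patients, patients_schema, "patients")
  patients <- mutate(patients, across(dplyr::everything(), as.character))
  dup <- patients$patient_id[duplicated(patients$patient_id)]
  if (length(dup)) {
    abort(sprintf("Duplicate patient_id(s): %s.",
                  paste(unique(dup), collapse = ", ")),
          class = "ambu_uniqueness_error")
  }
  lv <- patient_levels()
  for (col in names(lv)) check_levels(patients[[col]], lv[[col]], col, "patients")
  newly <- patients$patient_type == "new_diagnosed_2012"
  banded <- patients$years_band == "diagnosed_2012"
  if (any(newly != banded)) {
    abort(paste("years_band 'diagnosed_2012' must be used for, and only for,",
                "patients with patient_type 'new_diagnosed_2012'."),
          class = "ambu_validation_error")
  }
  patients
}

#' Validate an appointments table
#'
#' @param appointments Data frame with the `appointments.csv` schema.
#' @param patients Validated patients table (for referential integrity).
#' @param study_window Two ordered dates bounding all event dates.
#' @return Validated tibble with `date` as a `Date` column and logical
#'   `attended`/`is_baseline`.
#' @export
validate_appointments <- function(appointments, patients,
                                  study_window = STUDY_WINDOW_DEFAULT) {
  study_window <- check_study_window(study_window)
  appointments <- check_columns(appointments, appointments_schema, "appointments")
  appointments$date <- check_dates_in_window(appointments$date, study_window,
                                             "appointments")
  check_levels(appointments$clinic, c("hiv", "antenatal_hiv"), "clinic",
               "appointments")
  appointments$attended <- as.logical(appointments$attended)
  appointments$is_baseline <- as.logical(appointments$is_baseline)
  if (any(is.na(appointments$attended)) || any(is.na(appointments$is_baseline))) {
    abort("appointments$attended and $is_baseline must be TRUE/FALSE.",
          class = "ambu_validation_error")
  }
  check_patient_ids(appointments$patient_id, patients$patient_id, "appointments")
  if (any(appointments$is_baseline & !appointments$attended)) {
    abort("A baseline appointment must be attended.",
          class = "ambu_validation_error")
  }
  nb <- table(appointments$patient_id[appointments$is_baseline])
  if (any(nb > 1)) {
    abort(sprintf("More than one baseline appointment for patient(s): %s.",
                  paste(names(nb)[nb > 1], collapse = ", ")),
          class = "ambu_validation_error")
  }
  appointments
}

#' Validate a diagnostic-tests table
#'
#' @param tests Data frame with the `tests.csv` schema.
#' @inheritParams validate_appointments
#' @return Validated tibble with `date` as a `Date` column.
#' @export
validate_tests <- function(tests, patients,
                           study_window = STUDY_WINDOW_DEFAULT) {
  study_window <- check_study_window(study_window)
  tests <- check_columns(tests, tests_schema, "tests")
  tests$date <- check_dates_in_window(tests$date, study_window, "tests")
  check_levels(tests$modality, c("laboratory", "radiology", "cardiology"),
               "modality", "tests")
  check_patient_ids(tests$patient_id, patients$patient_id, "tests")
  tests
}

#' Validate a dispensing table
#'
#' HAART rows carry months dispensed (positive real, fractional months
#' allowed) and a regimen class; prophylactic-antibiotic rows carry whole
#' doses. Coverage dates are optional and ordered when both present.
#'
#' @param dispensing Data frame with the `dispensing.csv` schema.
#' @inheritParams validate_appointments
#' @return Validated tibble with `Date` coverage columns.
#' @export
validate_dispensing <- function(dispensing, patients,
                                study_window = STUDY_WINDOW_DEFAULT) {
  study_window <- check_study_window(study_window)
  dispensing <- check_columns(dispensing, dispensing_schema, "dispensing")
  check_levels(dispensing$item_kind, c("haart_regimen", "prophylactic_antibiotic"),
               "item_kind", "dispensing")
  check_levels(dispensing$regimen_class[dispensing$item_kind == "haart_regimen"],
               c("NNRTI", "PI", "other"), "regimen_class", "dispensing")
  dispensing$quantity <- as.numeric(dispensing$quantity)
  if (any(is.na(dispensing$quantity)) || any(dispensing$quantity <= 0)) {
    abort("dispensing$quantity must be a positive number.",
          class = "ambu_validation_error")
  }
  abx <- dispensing$item_kind == "prophylactic_antibiotic"
  if (any(abx & dispensing$quantity != round(dispensing$quantity))) {
    abort("Antibiotic doses must be whole numbers.",
          class = "ambu_validation_error")
  }
  dispensing$coverage_start <- suppressWarnings(as.Date(dispensing$coverage_start))
  dispensing$coverage_stop <- suppressWarnings(as.Date(dispensing$coverage_stop))
  both <- !is.na(dispensing$coverage_start) & !is.na(dispensing$coverage_stop)
  if (any(dispensing$coverage_start[both] > dispensing$coverage_stop[both])) {
    abort("dispensing coverage_start must not be after coverage_stop.",
          class = "ambu_validation_error")
  }
  check_patient_ids(dispensing$patient_id, patients$patient_id, "dispensing")
  dispensing
}

#' Assemble and validate a cohort event bundle
#'
#' Bundles the four validated event tables with their study window into a
#' `cohort_bundle`, the input object of the costing engine. Each event
#' table may be empty (a warning is issued), but every event must
#' reference a known patient.
#'
#' @param patients,appointments,tests,dispensing The four event tables.
#' @inheritParams validate_appointments
#' @return A `cohort_bundle`: a named list of the four validated tibbles
#'   with a `study_window` attribute.
#' @export
cohort_bundle <- function(patients, appointments, tests, dispensing,
                          study_window = STUDY_WINDOW_DEFAULT) {
  study_window <- check_study_window(study_window)
  patients <- validate_patients(patients)
  appointments <- validate_appointments(appointments, patients, study_window)
  tests <- validate_tests(tests, patients, study_window)
  dispensing <- validate_dispensing(dispensing, patients, study_window)
  for (nm in c("appointments", "tests", "dispensing")) {
    if (nrow(get(nm)) == 0) warn(sprintf("The %s table is empty.", nm))
  }
  structure(
    list(patients = patients, appointments = appointments,
         tests = tests, dispensing = dispensing),
    study_window = study_window,
    class = "cohort_bundle"
  )
}

#' @export
print.cohort_bundle <- function(x, ...) {
  sw <- attr(x, "study_window")
  cat(sprintf(
    "<cohort_bundle> %d patients, %d appointments, %d tests, %d dispensing rows\n",
    nrow(x$patients), nrow(x$appointments), nrow(x$tests), nrow(x$dispensing)))
  cat(sprintf("  study window: %s to %s\n", sw[1], sw[2]))
  invisible(x)
}

#' Read the four event tables from CSV files
#'
#' Reads `patients.csv`, `appointments.csv`, `tests.csv` and
#' `dispensing.csv` (exact headers documented in the README), validates
#' them and reports row counts.
#'
#' @param patients,appointments,tests,dispensing Paths to the four CSV
#'   files.
#' @inheritParams validate_appointments
#' @return A validated [cohort_bundle()] with a `load_log` attribute
#'   recording per-table row counts.
#' @export
read_event_tables <- function(patients, appointments, tests, dispensing,
                              study_window = STUDY_WINDOW_DEFAULT) {
  paths <- c(patients = patients, appointments = appointments,
             tests = tests, dispensing = dispensing)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    abort(sprintf("Input file(s) not found: %s.",
                  paste(missing, collapse = ", ")),
          class = "ambu_io_error")
  }
  read1 <- function(p) readr::read_csv(p, show_col_types = FALSE,
                                       col_types = readr::cols(.default = "c"))
  bundle <- cohort_bundle(read1(patients), read1(appointments), read1(tests),
                          read1(dispensing), study_window)
  log <- sprintf("loaded %s: %d rows", names(paths),
                 vapply(bundle, nrow, 0L))
  inform(log)
  attr(bundle, "load_log") <- log
  bundle
}

#' Write a cohort bundle back to CSV files
#'
#' Writes the four event tables using the same schemas `read_event_tables()`
#' reads, with ISO-8601 dates, so a read/write cycle is lossless.
#'
#' @param bundle A [cohort_bundle()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_event_tables <- function(bundle, dir) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, paste0(names(bundle), ".csv"))
  names(paths) <- names(bundle)
  for (nm in names(bundle)) readr::write_csv(bundle[[nm]], paths[[nm]])
  invisible(paths)
}
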