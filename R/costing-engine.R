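# Costing engine: HAART status, appointment classification, test-to-
# appointment linkage, censored follow-up and the priced cost ledger.

#' HAART status of one patient on given dates
#'
#' A patient is "on" HAART on a date if it falls in the union of that
#' patient's dispensing coverage intervals. Intervals are half-open
#' `[coverage_start, coverage_stop)`: the start date itself counts as on
#' treatment, the stop date does not — except when the stop is the study
#' end date, which is read as treatment ongoing through the last study
#' day. An absent start is read as the study start, an absent stop as
#' the study end; patients with no HAART dispensing rows are "off"
#' everywhere.
#'
#' @param dispensing Dispensing rows of a single patient.
#' @param dates Vector of dates to evaluate.
#' @param study_window Two ordered dates substituted for absent coverage
#'   endpoints.
#' @param stop_inclusive If `TRUE`, treat intervals as closed
#'   `[start, stop]` instead of the default half-open convention.
#' @return Character vector, `"on"` or `"off"`, one per date.
#' @export
haart_status_at <- function(dispensing, dates,
                            study_window = STUDY_WINDOW_DEFAULT,
                            stop_inclusive = FALSE) {
  study_window <- check_study_window(study_window)
  dates <- as.Date(dates)
  h <- dispensing[dispensing$item_kind == "haart_regimen", , drop = FALSE]
  if (nrow(h) == 0) return(rep("off", length(dates)))
  starts <- as.Date(ifelse(is.na(h$coverage_start), study_window[1],
                           h$coverage_start))
  stops <- as.Date(ifelse(is.na(h$coverage_stop), study_window[2],
                          h$coverage_stop))
  on <- vapply(dates, function(d) {
    any(d >= starts & (if (stop_inclusive) d <= stops else d < stops |
                         d == stops & stops == study_window[2]))
  }, logical(1))
  ifelse(on, "on", "off")
}

# Vectorised on/off status across patients: one row per (patient, date)
# query. Used by the classifier.
haart_status_many <- function(dispensing, patient_ids, dates, study_window,
                              stop_inclusive = FALSE) {
  h <- dispensing[dispensing$item_kind == "haart_regimen", , drop = FALSE]
  out <- rep("off", length(patient_ids))
  if (nrow(h) == 0) return(out)
  by_patient <- split(h, h$patient_id)
  idx <- split(seq_along(patient_ids), patient_ids)
  for (pid in names(idx)) {
    rows <- by_patient[[pid]]
    if (is.null(rows)) next
    out[idx[[pid]]] <- haart_status_at(rows, dates[idx[[pid]]], study_window,
                                       stop_inclusive)
  }
  out
}

#' Classify scheduled appointments into the eight types
#'
#' Each scheduled appointment receives exactly one of the eight
#' [appointment_types()]: a new patient's first attended visit is a
#' baseline appointment regardless of clinic; a missed appointment is a
#' DNA; otherwise the type follows the clinic (HIV vs antenatal-HIV);
#' and each carries the patient's on/off HAART status on the appointment
#' date. A baseline flag at the antenatal clinic is a classification
#' conflict (no such priced appointment exists).
#'
#' @param appointments Validated appointments table.
#' @param patients Validated patients table.
#' @param dispensing Validated dispensing table (for HAART status).
#' @inheritParams haart_status_at
#' @return The appointments tibble with an `appointment_type` column.
#' @export
classify_appointments <- function(appointments, patients, dispensing,
                                  study_window = STUDY_WINDOW_DEFAULT,
                                  stop_inclusive = FALSE) {
  study_window <- check_study_window(study_window)
  if (nrow(appointments) == 0) {
    return(mutate(appointments, appointment_type = character(0)))
  }
  conflict <- appointments$is_baseline & appointments$clinic == "antenatal_hiv"
  if (any(conflict)) {
    abort(sprintf(
      "Baseline appointment at the antenatal-HIV clinic (row %s) cannot be classified.",
      paste(which(conflict), collapse = ", ")),
      class = "ambu_classification_error")
  }
  status <- haart_status_many(dispensing, appointments$patient_id,
                              appointments$date, study_window, stop_inclusive)
  base <- dplyr::case_when(
    !appointments$attended ~ "DNA",
    appointments$is_baseline ~ "BASE",
    appointments$clinic == "antenatal_hiv" ~ "ANC",
    TRUE ~ "HIV"
  )
  mutate(appointments,
         appointment_type = paste0(base, "_", if_else(status == "on",
                                                      "onHAART", "offHAART")))
}

#' Link diagnostic tests to attended appointments
#'
#' Laboratory tests link to an attended appointment of the same patient
#' on the same date. Radiology and cardiology tests, which need not fall
#' on the visit date, link to the patient's nearest attended appointment
#' on or before the test date. Tests with no qualifying appointment stay
#' unlinked (they are still costed).
#'
#' @param tests Validated tests table.
#' @param appointments Validated appointments table.
#' @return Tibble with one row per test: `test_row`, `patient_id`,
#'   `date`, `modality`, `appointment_row` (row index into
#'   `appointments`, `NA` if unlinked).
#' @export
link_tests <- function(tests, appointments) {
  att <- which(appointments$attended)
  out <- tibble(test_row = seq_len(nrow(tests)),
                patient_id = tests$patient_id, date = tests$date,
                modality = tests$modality,
                appointment_row = NA_integer_)
  if (nrow(tests) == 0 || length(att) == 0) return(out)
  app <- tibble(row = att, patient_id = appointments$patient_id[att],
                date = appointments$date[att])
  by_patient <- split(app, app$patient_id)
  for (i in seq_len(nrow(tests))) {
    cand <- by_patient[[tests$patient_id[i]]]
    if (is.null(cand)) next
    if (tests$modality[i] == "laboratory") {
      hit <- cand$row[cand$date == tests$date[i]]
      if (length(hit)) out$appointment_row[i] <- hit[1]
    } else {
      prior <- cand[cand$date <= tests$date[i], , drop = FALSE]
      if (nrow(prior)) {
        out$appointment_row[i] <- prior$row[which.max(prior$date)]
      }
    }
  }
  out
}

#' Censored follow-up windows and patient-month denominators
#'
#' Care starts on the study start date for existing patients and on the
#' date of the first attended appointment for new patients. A patient is
#' in care to the study end if any of their events (appointments or
#' tests) falls in the second half of the study year; otherwise
#' follow-up is censored at the date of their last scheduled
#' appointment. Patient-months count both endpoint days and divide by
#' 30.4375 (365.25/12). Patients with no attended appointment fail the
#' eligibility rule: they are excluded and reported via the
#' `"excluded"` attribute.
#'
#' @param bundle A [cohort_bundle()].
#' @return Tibble `patient_id`, `start`, `end`, `patient_months`;
#'   attribute `excluded` lists ineligible patient ids.
#' @export
compute_follow_up <- function(bundle) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  sw <- attr(bundle, "study_window")
  mid <- as.Date(format(sw[1], "%Y-07-01"))
  app <- bundle$appointments
  att <- app[app$attended, , drop = FALSE]
  eligible <- unique(att$patient_id)
  excluded <- setdiff(bundle$patients$patient_id, eligible)
  if (length(excluded)) {
    inform(sprintf("%d patient(s) with no attended appointment excluded: %s",
                   length(excluded),
                   paste(head(excluded, 5), collapse = ", ")))
  }
  pts <- bundle$patients[bundle$patients$patient_id %in% eligible, ,
                         drop = FALSE]
  if (nrow(pts) == 0) {
    out <- tibble(patient_id = character(), start = as.Date(character()),
                  end = as.Date(character()), patient_months = numeric())
    attr(out, "excluded") <- excluded
    return(out)
  }
  first_att <- att |> group_by(.data$patient_id) |>
    summarise(first_attended = min(.data$date), .groups = "drop")
  last_sched <- app |> group_by(.data$patient_id) |>
    summarise(last_scheduled = max(.data$date), .groups = "drop")
  events <- bind_rows(select(app, "patient_id", "date"),
                      select(bundle$tests, "patient_id", "date"))
  active_h2 <- events |> filter(.data$date >= mid) |>
    distinct(.data$patient_id) |> mutate(active_h2 = TRUE)
  out <- pts |> select("patient_id", "patient_type") |>
    left_join(first_att, by = "patient_id") |>
    left_join(last_sched, by = "patient_id") |>
    left_join(active_h2, by = "patient_id") |>
    mutate(
      start = if_else(.data$patient_type == "existing", sw[1],
                      .data$first_attended),
      end = if_else(!is.na(.data$active_h2), sw[2], .data$last_scheduled),
      patient_months = date_to_months(.data$start, .data$end)
    ) |>
    select("patient_id", "start", "end", "patient_months")
  attr(out, "excluded") <- excluded
  out
}

#' Build the priced cost ledger
#'
#' The micro-costing step: every resource quantity is multiplied by its
#' unit cost. Each scheduled appointment yields one `staff` cost line
#' priced by its appointment type; each diagnostic test one `diagnostic`
#' line; each dispensing row one `drug` line (months times monthly
#' regimen price, or doses times per-dose antibiotic price — months
#' dispensed rather than coverage days, so wastage from regimen
#' switching is captured). Only eligible patients (at least one attended
#' appointment) are costed.
#'
#' @param bundle A [cohort_bundle()].
#' @param unit_costs A `unit_cost_table` (default the packaged 2012
#'   table).
#' @param strict If `TRUE`, unknown test/regimen codes are errors instead
#'   of falling back to the catch-all weighted-average prices.
#' @inheritParams haart_status_at
#' @return A `cost_ledger`: list of `cost_lines`, `follow_up` and
#'   `linkage` tibbles, carrying the study window.
#' @export
build_ledger <- function(bundle, unit_costs = ambu_unit_costs(),
                         strict = FALSE, stop_inclusive = FALSE) {
  stopifnot(inherits(bundle, "cohort_bundle"))
  unit_costs <- validate_unit_costs(unit_costs)
  sw <- attr(bundle, "study_window")
  follow_up <- compute_follow_up(bundle)
  keep <- follow_up$patient_id

  app <- classify_appointments(bundle$appointments, bundle$patients,
                               bundle$dispensing, sw, stop_inclusive) |>
    filter(.data$patient_id %in% keep)
  staff <- tibble(
    patient_id = app$patient_id, component = "staff",
    source = app$appointment_type, date = app$date, quantity = 1,
    unit_cost_eur = if (nrow(app)) unit_price(unit_costs, "appointment",
                                              app$appointment_type) else numeric(0)
  )

  tst <- filter(bundle$tests, .data$patient_id %in% keep)
  codes <- resolve_test_codes(tst$test_code, unit_costs, strict)
  diagnostic <- tibble(
    patient_id = tst$patient_id, component = "diagnostic", source = codes,
    date = tst$date, quantity = 1,
    unit_cost_eur = if (nrow(tst)) unit_price(unit_costs, "test", codes)
                    else numeric(0)
  )

  disp <- filter(bundle$dispensing, .data$patient_id %in% keep)
  is_haart <- disp$item_kind == "haart_regimen"
  drug_code <- character(nrow(disp))
  drug_price <- numeric(nrow(disp))
  if (any(is_haart)) {
    drug_code[is_haart] <- resolve_regimen_codes(disp$item_code[is_haart],
                                                 unit_costs, strict)
    drug_price[is_haart] <- unit_price(unit_costs, "regimen",
                                       drug_code[is_haart])
  }
  if (any(!is_haart)) {
    drug_code[!is_haart] <- disp$item_code[!is_haart]
    drug_price[!is_haart] <- unit_price(unit_costs, "antibiotic",
                                        disp$item_code[!is_haart])
  }
  drug <- tibble(
    patient_id = disp$patient_id, component = "drug", source = drug_code,
    date = disp$coverage_start, quantity = disp$quantity,
    unit_cost_eur = drug_price
  )

  cost_lines <- bind_rows(staff, diagnostic, drug) |>
    mutate(amount_eur = .data$quantity * .data$unit_cost_eur)

  linkage <- link_tests(bundle$tests, bundle$appointments)
  structure(list(cost_lines = cost_lines, follow_up = follow_up,
                 linkage = linkage),
            study_window = sw, class = "cost_ledger")
}

#' @export
print.cost_ledger <- function(x, ...) {
  cat(sprintf(
    "<cost_ledger> %d cost lines, %d patients, %.1f patient-months, total %s\n",
    nrow(x$cost_lines), nrow(x$follow_up), sum(x$follow_up$patient_months),
    format_eur(ledger_total(x))))
  invisible(x)
}

#' Total cost of a ledger
#'
#' @param ledger A `cost_ledger`.
#' @param component Optional component filter (`"staff"`, `"diagnostic"`,
#'   `"drug"`).
#' @return Total EUR over the (filtered) cost lines.
#' @export
ledger_total <- function(ledger, component = NULL) {
  lines <- ledger$cost_lines
  if (!is.null(component)) lines <- lines[lines$component %in% component, ]
  sum(lines$amount_eur)
}

format_eur <- function(x) {
  paste0("€", formatC(round(x), format = "d", big.mark = ","))
}

#' Export a ledger to CSV files
#'
#' Writes `cost_lines.csv`, `follow_up.csv` and `linkage.csv`.
#'
#' @param ledger A `cost_ledger`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_ledger <- function(ledger, dir) {
  stopifnot(inherits(ledger, "cost_ledger"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, c("cost_lines.csv", "follow_up.csv", "linkage.csv"))
  readr::write_csv(ledger$cost_lines, paths[1])
  readr::write_csv(ledger$follow_up, paths[2])
  readr::write_csv(mutate(ledger$linkage,
                          appointment_row = if_else(
                            is.na(.data$appointment_row), "UNLINKED",
                            as.character(.data$appointment_row))),
                   paths[3])
  invisible(paths)
}
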