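# Hand-built fixtures and independent brute-force oracles used across
# the suite.

patient_row <- function(patient_id, sex = "male", age_group = "under_50",
                        risk_factor = "MSM_bisexual",
                        patient_type = "existing", years_band = "6_10",
                        late_dx = "no", cd4_band = "ge500",
                        tx_vl_status = "not_on_haart") {
  tibble::tibble(patient_id = patient_id, sex = sex, age_group = age_group,
                 risk_factor = risk_factor, patient_type = patient_type,
                 years_band = years_band, late_dx = late_dx,
                 cd4_band = cd4_band, tx_vl_status = tx_vl_status)
}

appt_row <- function(patient_id, date, clinic = "hiv", attended = TRUE,
                     is_baseline = FALSE) {
  tibble::tibble(patient_id = patient_id, date = as.Date(date),
                 clinic = clinic, attended = attended,
                 is_baseline = is_baseline)
}

test_row <- function(patient_id, date, test_code = "CD4",
                     modality = "laboratory") {
  tibble::tibble(patient_id = patient_id, date = as.Date(date),
                 test_code = test_code, modality = modality)
}

disp_row <- function(patient_id, item_code = "EFV_FTC_TDF",
                     item_kind = "haart_regimen", regimen_class = "NNRTI",
                     quantity = 1, coverage_start = NA, coverage_stop = NA) {
  tibble::tibble(patient_id = patient_id, item_kind = item_kind,
                 item_code = item_code, regimen_class = regimen_class,
                 quantity = quantity,
                 coverage_start = as.Date(coverage_start),
                 coverage_stop = as.Date(coverage_stop))
}

empty_tests <- function() test_row(character(0), as.Date(character(0)))[0, ]
empty_disp <- function() disp_row(character(0))[0, ]

# Three-patient bundle exercising the follow-up rules: an existing
# patient active all year, a new patient starting 1 July, and an
# existing patient censored at a 15 March appointment.
tiny_bundle <- function() {
  patients <- dplyr::bind_rows(
    patient_row("P1", tx_vl_status = "on_haart_suppressed"),
    patient_row("P2", patient_type = "new_diagnosed_2012",
                years_band = "diagnosed_2012", sex = "female"),
    patient_row("P3")
  )
  appointments <- dplyr::bind_rows(
    appt_row("P1", "2012-02-01"),
    appt_row("P1", "2012-08-10"),
    appt_row("P2", "2012-07-01", is_baseline = TRUE),
    appt_row("P2", "2012-11-15"),
    appt_row("P3", "2012-02-10"),
    appt_row("P3", "2012-03-15", attended = FALSE)
  )
  tests <- dplyr::bind_rows(
    test_row("P1", "2012-02-01"),
    test_row("P1", "2012-08-10", "VL"),
    test_row("P1", "2012-08-20", "OTHER_TEST", modality = "radiology")
  )
  dispensing <- disp_row("P1", quantity = 12,
                         coverage_start = "2012-01-01",
                         coverage_stop = "2012-12-31")
  cohort_bundle(patients, appointments, tests, dispensing)
}

# Brute-force HAART status by per-day enumeration of coverage intervals:
# a day is on treatment when it lies in [start, stop), with the stop day
# itself counting only when coverage runs to the study end.
oracle_haart_status <- function(dispensing, date, sw = as.Date(c("2012-01-01",
                                                                 "2012-12-31"))) {
  h <- dispensing[dispensing$item_kind == "haart_regimen", , drop = FALSE]
  if (nrow(h) == 0) return("off")
  on_days <- as.Date(character(0))
  for (i in seq_len(nrow(h))) {
    s <- if (is.na(h$coverage_start[i])) sw[1] else h$coverage_start[i]
    e <- if (is.na(h$coverage_stop[i])) sw[2] else h$coverage_stop[i]
    days <- seq(s, e, by = "day")
    if (e != sw[2]) days <- days[days < e]
    on_days <- c(on_days, days)
  }
  if (as.Date(date) %in% on_days) "on" else "off"
}

# Brute-force test-appointment linkage following the stated rules, by
# exhaustive search over all appointments.
oracle_link <- function(tests, appointments) {
  out <- rep(NA_integer_, nrow(tests))
  for (i in seq_len(nrow(tests))) {
    best <- NA_integer_
    best_date <- as.Date("1900-01-01")
    for (j in seq_len(nrow(appointments))) {
      if (!appointments$attended[j]) next
      if (appointments$patient_id[j] != tests$patient_id[i]) next
      if (tests$modality[i] == "laboratory") {
        if (appointments$date[j] == tests$date[i] && is.na(best)) best <- j
      } else {
        if (appointments$date[j] <= tests$date[i] &&
            appointments$date[j] > best_date) {
          best <- j
          best_date <- appointments$date[j]
        }
      }
    }
    out[i] <- best
  }
  out
}
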