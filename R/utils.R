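# Internal helpers shared across the package.

# Average month length in days used for all patient-month denominators.
DAYS_PER_MONTH <- 30.4375

STUDY_WINDOW_DEFAULT <- as.Date(c("2012-01-01", "2012-12-31"))

# Days between two dates counting both endpoints (an existing patient in
# care for all of 2012 contributes 366 days, 2012 being a leap year).
days_inclusive <- function(start, end) {
  as.numeric(as.Date(end) - as.Date(start)) + 1
}

date_to_months <- function(start, end) {
  days_inclusive(start, end) / DAYS_PER_MONTH
}

# Deterministic per-patient RNG substream: a fixed function of the master
# seed and the patient index, so adding patients never perturbs the
# streams already generated.
patient_seed <- function(seed, i) {
  (abs(as.numeric(seed)) %% 1e6) * 2011 + 7919 * i
}

assert_date_scalar <- function(x, what) {
  d <- tryCatch(as.Date(x), error = function(e) NA)
  if (length(d) != 1 || is.na(d)) {
    abort(sprintf("`%s` must be a single parseable date, got %s.",
                  what, paste(format(x), collapse = ", ")),
          class = "ambu_format_error")
  }
  d
}

check_study_window <- function(study_window) {
  sw <- as.Date(study_window)
  if (length(sw) != 2 || any(is.na(sw)) || sw[1] > sw[2]) {
    abort("`study_window` must be two ordered dates.",
          class = "ambu_validation_error")
  }
  sw
}
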