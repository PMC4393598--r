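# Seeded synthetic-cohort generator. Emulates the statistical structure
# of one year of ambulatory HIV care in a regional clinic: categorical
# patient mix, scheduled-appointment streams with missed appointments
# (DNAs), routine monitoring tests linked to attended appointments, HAART
# coverage and dispensing, and mid-year censoring of patients who leave
# care.

REGIMEN_CLASSES <- c(
  EFV_FTC_TDF = "NNRTI", FTC_TDF_NVP = "NNRTI",
  FTC_TDF_DRV_RTV = "PI", FTC_TDF_ATV_RTV = "PI",
  FTC_TDF_LPV_RTV = "PI", AZT_3TC_LPV_RTV = "PI",
  OTHER_REGIMEN = "other"
)

default_marginals <- function() {
  list(
    sex = c(male = 192, female = 134) / 326,
    age_group = c(under_50 = 284, `50_plus` = 42) / 326,
    risk_factor = c(COHP = 133, heterosexual = 63, MSM_bisexual = 95,
                    IDU = 18, other = 8, unknown = 9) / 326,
    patient_type = c(existing = 300, new_diagnosed_2012 = 17,
                     new_transfer = 9) / 326,
    years_band = c(`11_plus` = 95, `6_10` = 107, `1_5` = 100,
                   diagnosed_2012 = 17) / 319,
    late_dx = c(no = 135, unknown = 77, yes = 114) / 326,
    cd4_band = c(ge500 = 168, `350_499` = 85, `200_349` = 52,
                 `50_199` = 14, lt50 = 7) / 326,
    tx_vl_status = c(on_haart_suppressed = 211, on_haart_not_suppressed = 37,
                     on_haart_undetermined = 7, started_stopped = 49,
                     not_on_haart = 22) / 326
  )
}

default_monitoring <- function() {
  # Tests per attended appointment, from 2012 counts over 1156 attended
  # appointments. OTHER_TEST pools every assay outside the four routine
  # monitoring panels (its rate exceeds 1: several per visit is common).
  c(CD4 = 1013, VL = 995, FBC = 1036, BIOCHEM_PROFILE = 1042,
    OTHER_TEST = 1262) / 1156
}

default_regimen_mix <- function() {
  # Months dispensed by regimen in the reference year (3322 in total).
  c(EFV_FTC_TDF = 1515, FTC_TDF_DRV_RTV = 864, FTC_TDF_ATV_RTV = 389,
    FTC_TDF_LPV_RTV = 99, FTC_TDF_NVP = 75, AZT_3TC_LPV_RTV = 53,
    OTHER_REGIMEN = 327) / 3322
}

check_prob_map <- function(p, what) {
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort(sprintf("`%s` must be non-negative probabilities summing to 1.", what),
          class = "ambu_validation_error")
  }
}

#' Configuration for the synthetic-cohort generator
#'
#' Defaults reproduce the reference 2012 cohort's observed structure:
#' 326 patients with the published categorical mix; a mean of 1315/326
#' scheduled appointments per patient; a 159/1315 probability that a
#' scheduled appointment is missed (DNA); monitoring-test rates per
#' attended appointment from the published test counts; the published
#' months-dispensed regimen mix with a 45/304 regimen-switch
#' probability; and a small probability that a patient leaves care
#' before July, exercising the censoring rule.
#'
#' @param n_patients Number of patients to generate.
#' @param seed Master seed; each patient draws from an independent
#'   substream derived from it, so enlarging the cohort never perturbs
#'   already-generated patients.
#' @param marginals Named list of probability vectors for each
#'   categorical patient field (see [patient_levels()]).
#' @param appointment_rate Mean scheduled appointments per patient-year.
#' @param dna_prob Probability a scheduled appointment is missed.
#' @param antenatal_prob Overall share of scheduled appointments held at
#'   the joint antenatal-HIV clinic (applied to women only).
#' @param monitoring Named vector of expected tests per attended
#'   appointment by test code.
#' @param regimen_mix Named probability vector over regimen codes
#'   (months-dispensed shares).
#' @param switch_prob Probability an on-HAART patient switches regimen
#'   during the year.
#' @param antibiotic_prob Probability a patient receives prophylactic
#'   antibiotics; `antibiotic_dose_rate` is the mean doses dispensed to
#'   such a patient.
#' @param antibiotic_dose_rate Mean antibiotic doses per recipient.
#' @param censor_prob Probability a patient drops out of care at a
#'   uniform date before 1 July.
#' @param study_window Two ordered dates; defaults to calendar 2012.
#' @return A validated `cohort_config` list.
#' @export
cohort_config <- function(n_patients = 326, seed = 1,
                          marginals = default_marginals(),
                          appointment_rate = 1315 / 326,
                          dna_prob = 159 / 1315,
                          antenatal_prob = 44 / 1315,
                          monitoring = default_monitoring(),
                          regimen_mix = default_regimen_mix(),
                          switch_prob = 45 / 304,
                          antibiotic_prob = 0.15,
                          antibiotic_dose_rate = 56,
                          censor_prob = 0.05,
                          study_window = STUDY_WINDOW_DEFAULT) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 0 ||
      n_patients != round(n_patients)) {
    abort("`n_patients` must be a non-negative integer.",
          class = "ambu_validation_error")
  }
  lv <- patient_levels()
  for (nm in names(lv)) {
    p <- marginals[[nm]]
    if (is.null(p) || !setequal(names(p), lv[[nm]])) {
      abort(sprintf("`marginals$%s` must name exactly the levels: %s.",
                    nm, paste(lv[[nm]], collapse = ", ")),
            class = "ambu_validation_error")
    }
    check_prob_map(p, paste0("marginals$", nm))
  }
  check_prob_map(regimen_mix, "regimen_mix")
  if (!setequal(names(regimen_mix), names(REGIMEN_CLASSES))) {
    abort("`regimen_mix` must be named by the priced regimen codes.",
          class = "ambu_validation_error")
  }
  rates <- c(appointment_rate = appointment_rate, dna_prob = dna_prob,
             antenatal_prob = antenatal_prob, switch_prob = switch_prob,
             antibiotic_prob = antibiotic_prob,
             antibiotic_dose_rate = antibiotic_dose_rate,
             censor_prob = censor_prob, monitoring)
  if (any(rates < 0)) {
    abort("All rates and probabilities must be non-negative.",
          class = "ambu_validation_error")
  }
  for (p in c(dna_prob, antenatal_prob, switch_prob, antibiotic_prob,
              censor_prob)) {
    if (p > 1) abort("Probabilities must not exceed 1.",
                     class = "ambu_validation_error")
  }
  structure(list(
    n_patients = as.integer(n_patients), seed = seed, marginals = marginals,
    appointment_rate = appointment_rate, dna_prob = dna_prob,
    antenatal_prob = antenatal_prob, monitoring = monitoring,
    regimen_mix = regimen_mix, switch_prob = switch_prob,
    antibiotic_prob = antibiotic_prob,
    antibiotic_dose_rate = antibiotic_dose_rate,
    censor_prob = censor_prob,
    study_window = check_study_window(study_window)
  ), class = "cohort_config")
}

sample_level <- function(p) sample(names(p), 1, prob = p)

rtrunc_pois <- function(lambda) {
  # Poisson truncated to >= 1 by inverse-CDF on the conditional law.
  if (lambda <= 0) return(1L)
  u <- runif(1)
  k <- stats::qpois(stats::ppois(0, lambda) + u * stats::ppois(0, lambda,
                                                               lower.tail = FALSE),
                    lambda)
  max(1L, k)
}

generate_patient <- function(i, cfg) {
  set.seed(patient_seed(cfg$seed, i))
  m <- cfg$marginals
  sw <- cfg$study_window
  id <- sprintf("P%04d", i)

  patient_type <- sample_level(m$patient_type)
  years_band <- if (patient_type == "new_diagnosed_2012") {
    "diagnosed_2012"
  } else {
    p <- m$years_band[setdiff(names(m$years_band), "diagnosed_2012")]
    sample_level(p / sum(p))
  }
  sex <- sample_level(m$sex)
  tx <- sample_level(m$tx_vl_status)
  patient <- tibble(
    patient_id = id, sex = sex,
    age_group = sample_level(m$age_group),
    risk_factor = sample_level(m$risk_factor),
    patient_type = patient_type, years_band = years_band,
    late_dx = sample_level(m$late_dx),
    cd4_band = sample_level(m$cd4_band),
    tx_vl_status = tx
  )

  is_new <- patient_type != "existing"
  start <- if (is_new) {
    sw[1] + floor(runif(1, 0, as.numeric(sw[2] - sw[1]) - 30))
  } else sw[1]

  # Censoring: drop out at a uniform date before 1 July (only sensible
  # for patients whose care starts early enough).
  jul1 <- as.Date(format(sw[1], "%Y-07-01"))
  censored <- runif(1) < cfg$censor_prob && start < (jul1 - 45)
  win_end <- if (censored) {
    start + floor(runif(1, 30, as.numeric(jul1 - start)))
  } else sw[2]

  frac <- as.numeric(win_end - start + 1) / as.numeric(sw[2] - sw[1] + 1)
  n_appt <- rtrunc_pois(cfg$appointment_rate * frac)
  days <- seq(start, win_end, by = "day")
  dates <- sort(sample(days, min(n_appt, length(days))))
  n_appt <- length(dates)

  attended <- runif(n_appt) >= cfg$dna_prob
  if (is_new) attended[1] <- TRUE              # baseline must be attended
  if (!any(attended)) attended[sample.int(n_appt, 1)] <- TRUE
  # Patients still in care must register activity in the second half-year.
  if (!censored && max(dates) < jul1) {
    dates[n_appt] <- jul1 + floor(runif(1, 0, as.numeric(sw[2] - jul1)))
  }
  if (is_new) start <- dates[1]

  p_anc <- if (sex == "female") min(1, cfg$antenatal_prob * 326 / 134) else 0
  clinic <- ifelse(runif(n_appt) < p_anc, "antenatal_hiv", "hiv")
  is_baseline <- rep(FALSE, n_appt)
  if (is_new) {
    is_baseline[1] <- TRUE
    clinic[1] <- "hiv"                         # baseline visits are priced
  }                                            # for the HIV clinic only
  appointments <- tibble(patient_id = id, date = dates, clinic = clinic,
                         attended = attended, is_baseline = is_baseline)

  # HAART coverage intervals per treatment status.
  dispensing <- tibble(patient_id = character(), item_kind = character(),
                       item_code = character(), regimen_class = character(),
                       quantity = numeric(), coverage_start = as.Date(character()),
                       coverage_stop = as.Date(character()))
  cov <- NULL
  if (tx %in% c("on_haart_suppressed", "on_haart_not_suppressed",
                "on_haart_undetermined")) {
    cov <- c(start, win_end)
  } else if (tx == "started_stopped") {
    span <- as.numeric(win_end - start)
    if (span > 30) {
      cut <- start + floor(runif(1, 15, span - 14))
      cov <- if (runif(1) < 0.5) c(start, cut) else c(cut, win_end)
    } else cov <- c(start, win_end)
  }
  if (!is.null(cov)) {
    segs <- list(cov)
    if (runif(1) < cfg$switch_prob && as.numeric(cov[2] - cov[1]) > 60) {
      mid <- cov[1] + floor(runif(1, 30, as.numeric(cov[2] - cov[1]) - 29))
      segs <- list(c(cov[1], mid), c(mid + 1, cov[2]))
    }
    regs <- sample(names(cfg$regimen_mix), length(segs),
                   replace = length(segs) > length(cfg$regimen_mix),
                   prob = cfg$regimen_mix)
    if (length(segs) == 2 && regs[1] == regs[2]) {
      alt <- setdiff(names(cfg$regimen_mix), regs[1])
      regs[2] <- sample(alt, 1, prob = cfg$regimen_mix[alt] /
                          sum(cfg$regimen_mix[alt]))
    }
    dispensing <- purrr::map2(segs, regs, function(sg, rg) {
      tibble(patient_id = id, item_kind = "haart_regimen", item_code = rg,
             regimen_class = unname(REGIMEN_CLASSES[rg]),
             quantity = date_to_months(sg[1], sg[2]),
             coverage_start = sg[1], coverage_stop = sg[2])
    }) |> bind_rows()
  }
  if (runif(1) < cfg$antibiotic_prob) {
    abx <- sample(c("AZITHROMYCIN", "SULFAMETHOXAZOLE_TRIMETHOPRIM", "DAPSONE"),
                  1, prob = c(330, 2047, 344))
    dispensing <- bind_rows(dispensing, tibble(
      patient_id = id, item_kind = "prophylactic_antibiotic", item_code = abx,
      regimen_class = NA_character_,
      quantity = max(1, rpois(1, cfg$antibiotic_dose_rate)),
      coverage_start = as.Date(NA), coverage_stop = as.Date(NA)))
  }

  # Monitoring tests ride on attended appointments: the four routine
  # panels at most once per visit, pooled other tests Poisson-many; a
  # fifth of "other" tests are radiology/cardiology performed within two
  # weeks after the visit.
  att_dates <- dates[attended]
  n_att <- length(att_dates)
  panel_codes <- c("CD4", "VL", "FBC", "BIOCHEM_PROFILE")
  panel_date <- rep(att_dates, length(panel_codes))
  panel_code <- rep(panel_codes, each = n_att)
  panel_keep <- runif(length(panel_date)) <
    pmin(1, cfg$monitoring[panel_code])
  n_other <- rpois(n_att, cfg$monitoring[["OTHER_TEST"]])
  other_date <- rep(att_dates, n_other)
  rad <- runif(length(other_date)) < 0.2
  other_date[rad] <- pmin(win_end, other_date[rad] +
                            sample(0:14, sum(rad), replace = TRUE))
  tests <- tibble(
    patient_id = id,
    date = c(panel_date[panel_keep], other_date),
    test_code = c(panel_code[panel_keep],
                  rep("OTHER_TEST", length(other_date))),
    modality = c(rep("laboratory", sum(panel_keep)),
                 ifelse(rad, sample(c("radiology", "cardiology"),
                                    length(other_date), replace = TRUE),
                        "laboratory"))
  ) |> arrange(.data$date, .data$test_code)

  list(patients = patient, appointments = appointments, tests = tests,
       dispensing = dispensing)
}

#' Generate a synthetic cohort event bundle
#'
#' Draws a full four-table event bundle (patients, appointments, tests,
#' dispensing) from a [cohort_config()]. Generation is deterministic for
#' a fixed seed, each patient uses an independent RNG substream, and the
#' generated streams are mutually consistent: tests occur on (laboratory)
#' or shortly after (radiology/cardiology) attended appointments, HAART
#' dispensing coverage matches the patient's treatment status, baseline
#' appointments occur only for new patients, and every patient has at
#' least one attended appointment (the study's eligibility rule).
#'
#' @param config A [cohort_config()].
#' @return A validated [cohort_bundle()].
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (config$n_patients == 0) {
    warn("n_patients is 0; returning an empty bundle.")
    empty_date <- as.Date(character())
    return(suppressWarnings(cohort_bundle(
      tibble(patient_id = character(), sex = character(),
             age_group = character(), risk_factor = character(),
             patient_type = character(), years_band = character(),
             late_dx = character(), cd4_band = character(),
             tx_vl_status = character()),
      tibble(patient_id = character(), date = empty_date, clinic = character(),
             attended = logical(), is_baseline = logical()),
      tibble(patient_id = character(), date = empty_date,
             test_code = character(), modality = character()),
      tibble(patient_id = character(), item_kind = character(),
             item_code = character(), regimen_class = character(),
             quantity = numeric(), coverage_start = empty_date,
             coverage_stop = empty_date),
      config$study_window)))
  }
  parts <- purrr::map(seq_len(config$n_patients), generate_patient, cfg = config)
  cohort_bundle(
    purrr::map(parts, "patients") |> bind_rows(),
    purrr::map(parts, "appointments") |> bind_rows(),
    purrr::map(parts, "tests") |> bind_rows(),
    purrr::map(parts, "dispensing") |> bind_rows(),
    config$study_window
  )
}
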