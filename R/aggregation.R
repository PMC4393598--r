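# Aggregation: weighted cost-per-patient-month summaries, subgroup
# stratification, one-way sensitivity analysis and the aggregate
# replication mode that reprices published resource counts.

PPM_COMPONENTS <- c("staff", "diagnostic", "drug", "non_drug", "total")

# Per-patient component costs joined to the follow-up denominators;
# patients with no lines in a component contribute zero cost but their
# full patient-months.
patient_component_costs <- function(ledger) {
  wide <- ledger$cost_lines |>
    group_by(.data$patient_id, .data$component) |>
    summarise(cost = sum(.data$amount_eur), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "component", values_from = "cost",
                       values_fill = 0)
  for (comp in c("staff", "diagnostic", "drug")) {
    if (!comp %in% names(wide)) wide[[comp]] <- 0
  }
  ledger$follow_up |>
    left_join(wide, by = "patient_id") |>
    mutate(across(c("staff", "diagnostic", "drug"),
                  ~ tidyr::replace_na(.x, 0)),
           non_drug = .data$staff + .data$diagnostic,
           total = .data$non_drug + .data$drug)
}

# Weighted-mean ppm with months as weights. The point estimate is total
# cost over total months; the normal-approximation CI uses the weighted
# variance of patient-level ppm with an effective-sample-size correction.
weighted_ppm_ci <- function(cost, months, conf_level = 0.95) {
  w <- months / sum(months)
  mean_ppm <- sum(cost) / sum(months)
  r <- cost / months
  n_eff <- 1 / sum(w^2)
  if (length(cost) < 2 || n_eff <= 1) {
    return(c(mean = mean_ppm, low = NA_real_, high = NA_real_))
  }
  v <- sum(w * (r - mean_ppm)^2) * n_eff / (n_eff - 1)
  se <- sqrt(v / n_eff)
  z <- qnorm(1 - (1 - conf_level) / 2)
  c(mean = mean_ppm, low = mean_ppm - z * se, high = mean_ppm + z * se)
}

bootstrap_ppm_ci <- function(cost, months, conf_level = 0.95, reps = 2000,
                             seed = 1) {
  mean_ppm <- sum(cost) / sum(months)
  if (length(cost) < 2) return(c(mean = mean_ppm, low = NA, high = NA))
  set.seed(seed)
  n <- length(cost)
  stat <- vapply(seq_len(reps), function(r) {
    idx <- sample.int(n, n, replace = TRUE)
    sum(cost[idx]) / sum(months[idx])
  }, numeric(1))
  qs <- quantile(stat, c((1 - conf_level) / 2, 1 - (1 - conf_level) / 2),
                 names = FALSE)
  c(mean = mean_ppm, low = qs[1], high = qs[2])
}

#' Weighted cost-per-patient-month summary
#'
#' The headline statistic: for each cost component, total cost over all
#' patients divided by total patient-months of follow-up — equivalently
#' the month-weighted mean of patient-level ppm values, so patients with
#' longer follow-up weigh more. `non_drug` is staff plus diagnostic;
#' `total` adds drugs. Confidence intervals use a month-weighted normal
#' approximation by default, or a seeded patient-level bootstrap.
#'
#' @param ledger A `cost_ledger` from [build_ledger()].
#' @param components Components to report (default all five).
#' @param conf_level Confidence level for the interval.
#' @param ci_method `"normal"` (weighted normal approximation with
#'   effective-sample-size correction) or `"bootstrap"` (patient-level
#'   resampling).
#' @param boot_reps,boot_seed Bootstrap resamples and seed.
#' @param stratum Label for the summary rows (default `"overall"`).
#' @return A `ppm_summary` tibble: `stratum`, `component`, `n_patients`,
#'   `patient_months`, `total_cost_eur`, `mean_ppm_eur`, `ci95_low_eur`,
#'   `ci95_high_eur`. Single-patient strata get a degenerate (`NA`) CI.
#' @export
cost_ppm_summary <- function(ledger, components = PPM_COMPONENTS,
                             conf_level = 0.95,
                             ci_method = c("normal", "bootstrap"),
                             boot_reps = 2000, boot_seed = 1,
                             stratum = "overall") {
  stopifnot(inherits(ledger, "cost_ledger"))
  ci_method <- match.arg(ci_method)
  components <- match.arg(components, PPM_COMPONENTS, several.ok = TRUE)
  pc <- patient_component_costs(ledger)
  if (nrow(pc) == 0 || sum(pc$patient_months) <= 0) {
    abort("Total patient-months must be positive.",
          class = "ambu_denominator_error")
  }
  rows <- purrr::map(components, function(comp) {
    ci <- if (ci_method == "normal") {
      weighted_ppm_ci(pc[[comp]], pc$patient_months, conf_level)
    } else {
      bootstrap_ppm_ci(pc[[comp]], pc$patient_months, conf_level,
                       boot_reps, boot_seed)
    }
    tibble(stratum = stratum, component = comp, n_patients = nrow(pc),
           patient_months = sum(pc$patient_months),
           total_cost_eur = sum(pc[[comp]]),
           mean_ppm_eur = ci[["mean"]], ci95_low_eur = ci[["low"]],
           ci95_high_eur = ci[["high"]])
  })
  out <- bind_rows(rows)
  class(out) <- c("ppm_summary", class(out))
  out
}

#' Cost ppm by patient subgroup
#'
#' Stratifies the ppm summary by one categorical patient field. Levels
#' with no eligible patients are omitted with a warning. The
#' month-weighted mean of the stratum ppm values always reproduces the
#' overall ppm (the decomposition identity).
#'
#' @param ledger A `cost_ledger`.
#' @param patients Validated patients table.
#' @param by Name of a categorical patient field (see
#'   [patient_levels()]).
#' @inheritParams cost_ppm_summary
#' @return A `ppm_summary` tibble with one block of component rows per
#'   level of `by`.
#' @export
stratified_summary <- function(ledger, patients,
                               by, components = c("drug", "non_drug", "total"),
                               conf_level = 0.95,
                               ci_method = c("normal", "bootstrap"),
                               boot_reps = 2000, boot_seed = 1) {
  stopifnot(inherits(ledger, "cost_ledger"))
  lv <- patient_levels()
  if (!by %in% names(lv)) {
    abort(sprintf("`by` must be a patient category: %s.",
                  paste(names(lv), collapse = ", ")),
          class = "ambu_config_error")
  }
  ci_method <- match.arg(ci_method)
  groups <- split(patients$patient_id, patients[[by]])
  empty <- setdiff(lv[[by]], names(groups))
  out <- purrr::map(names(groups), function(level) {
    sub <- subset_ledger(ledger, groups[[level]])
    if (nrow(sub$follow_up) == 0) return(NULL)
    cost_ppm_summary(sub, components, conf_level, ci_method, boot_reps,
                     boot_seed, stratum = level)
  })
  dropped <- c(empty, names(groups)[vapply(out, is.null, logical(1))])
  if (length(dropped)) {
    warn(sprintf("Level(s) of %s with no eligible patients omitted: %s.",
                 by, paste(dropped, collapse = ", ")))
  }
  out <- bind_rows(out)
  class(out) <- c("ppm_summary", class(out))
  attr(out, "by") <- by
  out
}

subset_ledger <- function(ledger, patient_ids) {
  structure(list(
    cost_lines = filter(ledger$cost_lines, .data$patient_id %in% patient_ids),
    follow_up = filter(ledger$follow_up, .data$patient_id %in% patient_ids),
    linkage = ledger$linkage
  ), study_window = attr(ledger, "study_window"), class = "cost_ledger")
}

#' Default one-way sensitivity scenarios
#'
#' Base case plus a low scenario (staff time −20%, diagnostic unit costs
#' −60%) and a high scenario (+20% / +60%), reflecting the measurement
#' uncertainty of timed staff input and of diagnostic unit prices.
#'
#' @return Tibble `scenario`, `staff_multiplier`,
#'   `diagnostic_multiplier`.
#' @export
sensitivity_scenarios <- function() {
  tibble(scenario = c("base", "low", "high"),
         staff_multiplier = c(1, 0.8, 1.2),
         diagnostic_multiplier = c(1, 0.4, 1.6))
}

scale_ledger <- function(ledger, staff_multiplier, diagnostic_multiplier) {
  if (staff_multiplier <= 0 || diagnostic_multiplier <= 0) {
    abort("Sensitivity multipliers must be positive.",
          class = "ambu_validation_error")
  }
  mult <- c(staff = staff_multiplier, diagnostic = diagnostic_multiplier,
            drug = 1)
  lines <- ledger$cost_lines |>
    mutate(unit_cost_eur = .data$unit_cost_eur * mult[.data$component],
           amount_eur = .data$quantity * .data$unit_cost_eur)
  structure(list(cost_lines = lines, follow_up = ledger$follow_up,
                 linkage = ledger$linkage),
            study_window = attr(ledger, "study_window"),
            class = "cost_ledger")
}

#' One-way sensitivity analysis of cost ppm
#'
#' Rescales staff cost lines by `staff_multiplier` and diagnostic lines
#' by `diagnostic_multiplier` (drug lines untouched) for each scenario,
#' and recomputes the ppm summary.
#'
#' @param ledger A `cost_ledger`.
#' @param scenarios Tibble of scenarios (see [sensitivity_scenarios()]).
#' @inheritParams cost_ppm_summary
#' @return A `ppm_sensitivity` tibble: the `ppm_summary` columns plus
#'   `scenario`, `staff_multiplier`, `diagnostic_multiplier`.
#' @export
sensitivity_analysis <- function(ledger, scenarios = sensitivity_scenarios(),
                                 components = PPM_COMPONENTS,
                                 conf_level = 0.95,
                                 ci_method = c("normal", "bootstrap")) {
  stopifnot(inherits(ledger, "cost_ledger"))
  ci_method <- match.arg(ci_method)
  out <- purrr::pmap(scenarios, function(scenario, staff_multiplier,
                                         diagnostic_multiplier, ...) {
    scaled <- scale_ledger(ledger, staff_multiplier, diagnostic_multiplier)
    cost_ppm_summary(scaled, components, conf_level, ci_method) |>
      mutate(scenario = scenario, staff_multiplier = staff_multiplier,
             diagnostic_multiplier = diagnostic_multiplier,
             .before = 1)
  }) |> bind_rows()
  class(out) <- c("ppm_sensitivity", class(out))
  out
}

#' Component ppm from aggregate resource counts
#'
#' Replication mode: prices a resource-count table (quantity per priced
#' code) against a unit-cost table and divides by a given patient-month
#' denominator. This reproduces a published aggregate analysis exactly
#' from its printed unit costs and frequencies, with no patient-level
#' data.
#'
#' @param unit_costs A `unit_cost_table`.
#' @param counts Tibble `category`, `code`, `quantity`.
#' @param patient_months Positive total patient-months denominator.
#' @return A `ppm_summary` tibble (components staff, diagnostic, drug,
#'   non_drug, total; no CIs, which need patient-level data).
#' @export
ppm_from_aggregate_counts <- function(unit_costs, counts, patient_months) {
  unit_costs <- validate_unit_costs(unit_costs)
  counts <- check_columns(counts, c("category", "code", "quantity"), "counts")
  counts$quantity <- as.numeric(counts$quantity)
  if (!is.numeric(patient_months) || patient_months <= 0) {
    abort("`patient_months` must be positive.",
          class = "ambu_denominator_error")
  }
  priced <- counts |>
    mutate(unit_cost_eur = unit_price(unit_costs, .data$category[1],
                                      .data$code),
           .by = "category") |>
    mutate(component = dplyr::case_match(.data$category,
                                         "appointment" ~ "staff",
                                         "test" ~ "diagnostic",
                                         .default = "drug"),
           amount_eur = .data$quantity * .data$unit_cost_eur)
  comp <- priced |>
    group_by(.data$component) |>
    summarise(total_cost_eur = sum(.data$amount_eur), .groups = "drop")
  get_total <- function(nm) {
    v <- comp$total_cost_eur[comp$component == nm]
    if (length(v)) v else 0
  }
  totals <- c(staff = get_total("staff"), diagnostic = get_total("diagnostic"),
              drug = get_total("drug"))
  totals <- c(totals, non_drug = unname(totals["staff"] + totals["diagnostic"]))
  totals <- c(totals, total = unname(totals["non_drug"] + totals["drug"]))
  out <- tibble(stratum = "overall", component = names(totals),
                n_patients = NA_integer_, patient_months = patient_months,
                total_cost_eur = unname(totals),
                mean_ppm_eur = unname(totals) / patient_months,
                ci95_low_eur = NA_real_, ci95_high_eur = NA_real_)
  class(out) <- c("ppm_summary", class(out))
  out
}

#' Benchmark ppm under a flat appointment price
#'
#' What the cost ppm would be if every scheduled appointment were priced
#' at a single flat rate (e.g. a national average outpatient price) and
#' nothing else were counted.
#'
#' @param flat_price_eur Price per appointment.
#' @param n_appointments Number of scheduled appointments.
#' @param patient_months Patient-month denominator.
#' @return Cost per patient-month in EUR.
#' @export
benchmark_ppm <- function(flat_price_eur, n_appointments, patient_months) {
  if (any(c(flat_price_eur, n_appointments, patient_months) <= 0)) {
    abort("All benchmark inputs must be positive.",
          class = "ambu_denominator_error")
  }
  flat_price_eur * n_appointments / patient_months
}

#' Replay the packaged 2012 aggregate cost analysis
#'
#' Runs the replication mode end to end from the packaged fixtures: the
#' 2012 unit costs ([ambu_unit_costs()]), resource-use counts
#' ([ambu_resource_use()]) and the 3659 patient-month denominator, plus
#' the one-way sensitivity scenarios and the flat national-average
#' appointment-price benchmark (EUR 130.56 per appointment in 2012).
#'
#' @param scenarios Sensitivity scenarios (default
#'   [sensitivity_scenarios()]).
#' @param national_appointment_price_eur Flat benchmark price per
#'   appointment.
#' @return List with `base_and_sensitivity` (a `ppm_sensitivity` tibble:
#'   component ppm under base/low/high scenarios) and `benchmark_ppm_eur`.
#' @export
replicate_reference_costing <- function(scenarios = sensitivity_scenarios(),
                                        national_appointment_price_eur = 130.56) {
  unit_costs <- ambu_unit_costs()
  counts <- ambu_resource_use()
  months <- ambu_reference_patient_months()
  grid <- purrr::pmap(scenarios, function(scenario, staff_multiplier,
                                          diagnostic_multiplier, ...) {
    uc <- unit_costs |>
      mutate(unit_cost_eur = .data$unit_cost_eur *
               dplyr::case_match(.data$category,
                                 "appointment" ~ staff_multiplier,
                                 "test" ~ diagnostic_multiplier,
                                 .default = 1))
    ppm_from_aggregate_counts(uc, counts, months) |>
      mutate(scenario = scenario, staff_multiplier = staff_multiplier,
             diagnostic_multiplier = diagnostic_multiplier, .before = 1)
  }) |> bind_rows()
  class(grid) <- c("ppm_sensitivity", class(grid))
  n_appts <- sum(counts$quantity[counts$category == "appointment"])
  list(base_and_sensitivity = grid,
       benchmark_ppm_eur = benchmark_ppm(national_appointment_price_eur,
                                         n_appts, months))
}
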