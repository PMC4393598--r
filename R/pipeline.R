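# End-to-end orchestration: one call from a run configuration to the
# full report bundle (cohort profile, priced resource use, base and
# sensitivity ppm, subgroup costs, regression results, run log).

#' Pipeline run configuration
#'
#' Exactly one input source must be supplied: either the four event-table
#' CSV paths (`input_paths`) or a synthetic [cohort_config()]
#' (`synthetic`).
#'
#' @param input_paths Named list/vector with elements `patients`,
#'   `appointments`, `tests`, `dispensing`.
#' @param synthetic A [cohort_config()].
#' @param unit_costs_path Path to a unit-cost CSV; `NULL` uses the
#'   packaged 2012 table.
#' @param scenarios Sensitivity scenarios (see
#'   [sensitivity_scenarios()]).
#' @param ci_method `"normal"` or `"bootstrap"` for ppm intervals.
#' @param subgroup_fields Patient fields for the subgroup table.
#' @param seed Seed covering every random element of the run.
#' @param out_dir Output directory for the CSV bundle and run log;
#'   `NULL` to skip writing.
#' @return A validated `run_config` list.
#' @export
run_config <- function(input_paths = NULL, synthetic = NULL,
                       unit_costs_path = NULL,
                       scenarios = sensitivity_scenarios(),
                       ci_method = c("normal", "bootstrap"),
                       subgroup_fields = c("sex", "age_group",
                                           "tx_vl_status"),
                       seed = 1, out_dir = NULL) {
  if (is.null(input_paths) == is.null(synthetic)) {
    abort("Supply exactly one of `input_paths` and `synthetic`.",
          class = "ambu_config_error")
  }
  if (!is.null(input_paths)) {
    need <- c("patients", "appointments", "tests", "dispensing")
    if (!all(need %in% names(input_paths))) {
      abort(sprintf("`input_paths` must name: %s.",
                    paste(need, collapse = ", ")),
            class = "ambu_config_error")
    }
  }
  if (!is.null(synthetic)) stopifnot(inherits(synthetic, "cohort_config"))
  bad <- setdiff(subgroup_fields, names(patient_levels()))
  if (length(bad)) {
    abort(sprintf("Unknown subgroup field(s): %s.", paste(bad, collapse = ", ")),
          class = "ambu_config_error")
  }
  structure(list(input_paths = input_paths, synthetic = synthetic,
                 unit_costs_path = unit_costs_path, scenarios = scenarios,
                 ci_method = match.arg(ci_method),
                 subgroup_fields = subgroup_fields, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

# Cohort profile: counts and shares of patients and of patient-months by
# each categorical patient field.
cohort_profile <- function(patients, follow_up) {
  joined <- inner_join(patients, follow_up, by = "patient_id")
  purrr::map(names(patient_levels()), function(field) {
    joined |>
      group_by(level = .data[[field]]) |>
      summarise(n_patients = n(),
                patient_months = sum(.data$patient_months),
                .groups = "drop") |>
      mutate(characteristic = field,
             pct_patients = 100 * .data$n_patients / sum(.data$n_patients),
             pct_months = 100 * .data$patient_months /
               sum(.data$patient_months)) |>
      select("characteristic", "level", "n_patients", "pct_patients",
             "patient_months", "pct_months")
  }) |> bind_rows()
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(sprintf("Pipeline stage '%s' failed: %s", name,
                  conditionMessage(e)),
          class = "ambu_pipeline_error", parent = e)
  })
}

#' Run the full costing pipeline
#'
#' From a [run_config()] to the report bundle: loads or generates the
#' event tables, builds the cost ledger, and produces the cohort
#' profile, priced resource-use table, base-case and sensitivity ppm
#' grid, subgroup cost tables, cost-regression results (Park-test family
#' selection, power-link scan, cost GLM on HAART patient-months, and a
#' PI-vs-NNRTI logistic model when both classes occur), and a
#' provenance log. Deterministic for a fixed seed. If `out_dir` is set,
#' each table is written as CSV alongside a plain-text run log.
#'
#' @param config A [run_config()].
#' @return Invisibly when writing, else visibly: a named list of report
#'   tibbles plus `run_log`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  unit_costs <- stage("unit_costs", {
    if (is.null(config$unit_costs_path)) ambu_unit_costs()
    else read_unit_costs(config$unit_costs_path)
  })
  bundle <- stage("inputs", {
    if (!is.null(config$synthetic)) generate_cohort(config$synthetic)
    else read_event_tables(config$input_paths[["patients"]],
                           config$input_paths[["appointments"]],
                           config$input_paths[["tests"]],
                           config$input_paths[["dispensing"]])
  })
  ledger <- stage("costing", build_ledger(bundle, unit_costs))
  profile <- stage("cohort_profile",
                   cohort_profile(bundle$patients, ledger$follow_up))
  usage <- stage("unit_cost_usage", {
    ledger$cost_lines |>
      group_by(.data$component, .data$source) |>
      summarise(quantity = sum(.data$quantity),
                unit_cost_eur = .data$unit_cost_eur[1],
                amount_eur = sum(.data$amount_eur), .groups = "drop")
  })
  sens <- stage("base_and_sensitivity",
                sensitivity_analysis(ledger, config$scenarios,
                                     ci_method = config$ci_method))
  subgroups <- stage("subgroup_costs", {
    purrr::map(config$subgroup_fields, function(f) {
      stratified_summary(ledger, bundle$patients, f,
                         ci_method = config$ci_method) |>
        mutate(characteristic = f, .before = 1)
    }) |> bind_rows()
  })
  glm_results <- stage("glm_results",
                       pipeline_regressions(ledger, bundle, config$seed))
  log <- c(sprintf("seed: %s", config$seed),
           sprintf("config hash: %s",
                   rlang::hash(config[setdiff(names(config), "out_dir")])),
           sprintf("R version: %s", getRversion()),
           sprintf("ambucost version: %s",
                   as.character(utils::packageVersion("ambucost"))),
           sprintf("patients costed: %d", nrow(ledger$follow_up)),
           sprintf("total patient-months: %.2f",
                   sum(ledger$follow_up$patient_months)),
           sprintf("ledger total: %.2f EUR", ledger_total(ledger)))
  out <- list(cohort_profile = profile, unit_cost_usage = usage,
              base_and_sensitivity = sens, subgroup_costs = subgroups,
              glm_results = glm_results, ledger = ledger, run_log = log)
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in c("cohort_profile", "unit_cost_usage", "base_and_sensitivity",
                 "subgroup_costs", "glm_results")) {
      readr::write_csv(out[[nm]], file.path(config$out_dir,
                                            paste0(nm, ".csv")))
    }
    write_ledger(ledger, config$out_dir)
    writeLines(log, file.path(config$out_dir, "run_log.txt"))
    return(invisible(out))
  }
  out
}

# Cost regressions on the costed cohort: total cost ppm of patients with
# any HAART months, modelled on the demographic covariates; family via
# the modified Park test, link via the power-link scan over a coarse
# grid (0, 0.2, ..., 1) to keep routine runs quick.
pipeline_regressions <- function(ledger, bundle, seed) {
  pc <- patient_component_costs(ledger) |>
    inner_join(bundle$patients, by = "patient_id") |>
    mutate(ppm = .data$total / .data$patient_months)
  on_haart <- filter(pc, .data$drug > 0, .data$ppm > 0)
  if (nrow(on_haart) < 50 ||
      dplyr::n_distinct(on_haart$sex) < 2 ||
      dplyr::n_distinct(on_haart$age_group) < 2) {
    return(tibble(model = character(), term = character(),
                  estimate = numeric(), std_error = numeric(),
                  p_value = numeric(), family = character(),
                  link_power = numeric()))
  }
  form <- ppm ~ sex + age_group + patient_type
  park <- modified_park_test(on_haart, form)
  # all-categorical designs have few distinct predictions, so the
  # Hosmer-Lemeshow grouping is coarsened; if no candidate link can be
  # fit at all, fall back to the log link
  scan <- tryCatch(
    select_power_link(on_haart, form, park$chosen_family,
                      grid = seq(0, 1, by = 0.2), groups = 5),
    error = function(e) list(chosen_power = 0))
  fit <- fit_cost_glm(on_haart, form, park$chosen_family,
                      scan$chosen_power)
  out <- tidy(fit) |>
    mutate(model = "total_ppm_on_haart", family = park$chosen_family,
           link_power = scan$chosen_power, .before = 1)
  select(out, "model", "term", "estimate", "std_error", "p_value",
         "family", "link_power")
}
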