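ledger_from_costs <- function(costs, months) {
  # minimal ledger: one staff line per patient with the given total cost
  ids <- sprintf("Q%02d", seq_along(costs))
  structure(list(
    cost_lines = tibble::tibble(
      patient_id = ids, component = "staff", source = "HIV_offHAART",
      date = as.Date("2012-06-01"), quantity = 1, unit_cost_eur = costs,
      amount_eur = costs),
    follow_up = tibble::tibble(
      patient_id = ids, start = as.Date("2012-01-01"),
      end = as.Date("2012-01-01") + months * 30.4375 - 1,
      patient_months = months),
    linkage = tibble::tibble(test_row = integer(), patient_id = character(),
                             date = as.Date(character()),
                             modality = character(),
                             appointment_row = integer())
  ), study_window = as.Date(c("2012-01-01", "2012-12-31")),
  class = "cost_ledger")
}

test_that("pooled ppm is the month-weighted mean of patient ppm", {
  led <- ledger_from_costs(c(100, 50), c(2, 2))
  s <- cost_ppm_summary(led, components = "total")
  expect_equal(s$mean_ppm_eur, 37.5)
  expect_equal(s$patient_months, 4)
  # unequal months weigh accordingly: (100 + 50) / (3 + 1) = 37.5 vs
  # patient ppm 33.3 and 50
  led2 <- ledger_from_costs(c(100, 50), c(3, 1))
  expect_equal(cost_ppm_summary(led2, components = "total")$mean_ppm_eur,
               150 / 4)
  expect_true(s$ci95_low_eur <= s$mean_ppm_eur &
                s$mean_ppm_eur <= s$ci95_high_eur)
})

test_that("a single-patient stratum gets a degenerate CI, not a failure", {
  led <- ledger_from_costs(100, 4)
  s <- cost_ppm_summary(led, components = "total")
  expect_equal(s$mean_ppm_eur, 25)
  expect_true(is.na(s$ci95_low_eur))
})

test_that("bootstrap and normal CIs agree roughly on well-behaved data", {
  set.seed(20)
  led <- ledger_from_costs(rgamma(80, 4, 0.01), runif(80, 6, 12))
  a <- cost_ppm_summary(led, components = "total")
  b <- cost_ppm_summary(led, components = "total", ci_method = "bootstrap",
                        boot_reps = 1500, boot_seed = 2)
  expect_equal(a$mean_ppm_eur, b$mean_ppm_eur)
  expect_lt(abs(a$ci95_low_eur - b$ci95_low_eur) / a$mean_ppm_eur, 0.15)
})

test_that("stratified summaries satisfy the decomposition identity", {
  b <- suppressMessages(suppressWarnings(
    generate_cohort(cohort_config(n_patients = 80, seed = 29))))
  led <- suppressMessages(build_ledger(b))
  overall <- cost_ppm_summary(led)
  for (field in c("sex", "risk_factor", "tx_vl_status")) {
    strat <- suppressWarnings(
      stratified_summary(led, b$patients, field,
                         components = c("staff", "diagnostic", "drug",
                                        "non_drug", "total")))
    for (comp in unique(strat$component)) {
      rows <- strat[strat$component == comp, ]
      expect_equal(sum(rows$total_cost_eur),
                   overall$total_cost_eur[overall$component == comp],
                   tolerance = 1e-9, label = paste(field, comp))
      # month-weighted mean of stratum ppm equals overall ppm
      expect_equal(
        sum(rows$mean_ppm_eur * rows$patient_months) /
          sum(rows$patient_months),
        overall$mean_ppm_eur[overall$component == comp],
        tolerance = 1e-9)
    }
  }
})

test_that("a single-level grouping reproduces the overall summary", {
  b <- tiny_bundle()
  led <- suppressMessages(build_ledger(b))
  strat <- suppressWarnings(
    stratified_summary(led, b$patients, "age_group", components = "total"))
  overall <- cost_ppm_summary(led, components = "total")
  expect_equal(nrow(strat), 1L)
  expect_equal(strat$mean_ppm_eur, overall$mean_ppm_eur)
  expect_error(stratified_summary(led, b$patients, "shoe_size"),
               class = "ambu_config_error")
})

test_that("sensitivity analysis scales only the targeted components", {
  led <- suppressMessages(build_ledger(tiny_bundle()))
  sa <- sensitivity_analysis(led)
  base <- sa[sa$scenario == "base", ]
  plain <- cost_ppm_summary(led)
  expect_equal(base$mean_ppm_eur, plain$mean_ppm_eur)
  # drug ppm invariant across scenarios
  drug <- sa[sa$component == "drug", ]
  expect_equal(length(unique(round(drug$mean_ppm_eur, 9))), 1L)
  # staff scales exactly with its multiplier
  staff <- sa[sa$component == "staff", ]
  expect_equal(staff$mean_ppm_eur[staff$scenario == "low"],
               0.8 * staff$mean_ppm_eur[staff$scenario == "base"])
  # total non-decreasing in the multipliers
  total <- sa[sa$component == "total", ]
  expect_true(total$mean_ppm_eur[total$scenario == "low"] <=
                total$mean_ppm_eur[total$scenario == "base"])
  expect_true(total$mean_ppm_eur[total$scenario == "base"] <=
                total$mean_ppm_eur[total$scenario == "high"])
  expect_error(sensitivity_analysis(led, tibble::tibble(
    scenario = "bad", staff_multiplier = 0, diagnostic_multiplier = 1)),
    class = "ambu_validation_error")
})

test_that("aggregate-count ppm matches an independent spreadsheet oracle", {
  # hand-coded 2012 frequencies and prices, summed independently
  appt_cost <- sum(c(12.68, 21.25, 174.89, 194.88, 174.26, 194.25,
                     244.46, 264.45) * c(32, 127, 89, 997, 2, 42, 14, 12))
  test_cost <- sum(c(47.29, 92.94, 6.79, 18.63, 28.39) *
                     c(1013, 995, 1036, 1042, 1262))
  expect_equal(appt_cost, 228067.94)
  s <- ppm_from_aggregate_counts(ambu_unit_costs(), ambu_resource_use(),
                                 3659)
  expect_equal(s$total_cost_eur[s$component == "staff"], appt_cost,
               tolerance = 1e-9)
  expect_equal(s$total_cost_eur[s$component == "diagnostic"], test_cost,
               tolerance = 1e-9)
  expect_equal(s$mean_ppm_eur[s$component == "staff"], appt_cost / 3659)
  # all-zero counts give zero everywhere
  zero <- ambu_resource_use()
  zero$quantity <- 0
  s0 <- ppm_from_aggregate_counts(ambu_unit_costs(), zero, 3659)
  expect_equal(s0$mean_ppm_eur, rep(0, 5))
  # unpriced resources are an error
  bad <- ambu_resource_use()
  bad$code[1] <- "NOT_A_CODE"
  expect_error(ppm_from_aggregate_counts(ambu_unit_costs(), bad, 3659),
               class = "ambu_pricing_error")
  expect_error(ppm_from_aggregate_counts(ambu_unit_costs(),
                                         ambu_resource_use(), 0),
               class = "ambu_denominator_error")
})

test_that("the flat-price benchmark is price times visits over months", {
  expect_equal(benchmark_ppm(130.56, 1315, 3659), 130.56 * 1315 / 3659)
  expect_equal(round(benchmark_ppm(130.56, 1315, 3659)), 47)
  expect_equal(benchmark_ppm(1, 50, 50), 1)
  expect_equal(benchmark_ppm(130.56, 1, 1), 130.56)
  expect_error(benchmark_ppm(130.56, 1315, 0),
               class = "ambu_denominator_error")
})
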