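test_that("HAART status follows the half-open coverage convention", {
  d <- disp_row("P1", coverage_start = "2012-02-01",
                coverage_stop = "2012-12-31")
  expect_equal(haart_status_at(d, "2012-06-15"), "on")
  expect_equal(haart_status_at(d, "2012-01-31"), "off")
  # the start date itself is on treatment
  expect_equal(haart_status_at(d, "2012-02-01"), "on")
  expect_equal(haart_status_at(empty_disp(), "2012-06-15"), "off")
  # stop before the study end is exclusive; a study-end stop means
  # treatment is ongoing through the last day
  d2 <- disp_row("P1", coverage_start = "2012-02-01",
                 coverage_stop = "2012-06-01")
  expect_equal(haart_status_at(d2, c("2012-05-31", "2012-06-01")),
               c("on", "off"))
  expect_equal(haart_status_at(d, "2012-12-31"), "on")
  # absent endpoints default to the study window
  d3 <- disp_row("P1")
  expect_equal(haart_status_at(d3, "2012-01-01"), "on")
})

test_that("status agrees with brute-force day enumeration on random coverage", {
  set.seed(41)
  sw <- as.Date(c("2012-01-01", "2012-12-31"))
  for (rep in 1:25) {
    n_int <- sample(0:3, 1)
    rows <- purrr::map(seq_len(n_int), function(k) {
      s <- sw[1] + sample(0:330, 1)
      disp_row("PX", coverage_start = s,
               coverage_stop = min(s + sample(10:300, 1), sw[2]))
    }) |> dplyr::bind_rows()
    if (n_int == 0) rows <- empty_disp()
    dates <- sw[1] + sample(0:365, 10)
    got <- haart_status_at(rows, dates)
    want <- vapply(dates, function(d) oracle_haart_status(rows, d),
                   character(1))
    expect_identical(got, want)
  }
})

test_that("appointments classify into exactly one of the eight types", {
  b <- tiny_bundle()
  cls <- classify_appointments(b$appointments, b$patients, b$dispensing)
  expect_true(all(cls$appointment_type %in% appointment_types()))
  expect_equal(nrow(cls), nrow(b$appointments))
  # P1 on HAART all year at the HIV clinic
  expect_equal(cls$appointment_type[cls$patient_id == "P1"],
               c("HIV_onHAART", "HIV_onHAART"))
  # P2's first visit is a baseline, off HAART
  expect_equal(cls$appointment_type[cls$patient_id == "P2"],
               c("BASE_offHAART", "HIV_offHAART"))
  # P3's missed appointment is a DNA
  expect_equal(cls$appointment_type[cls$patient_id == "P3"],
               c("HIV_offHAART", "DNA_offHAART"))
})

test_that("a baseline flagged at the antenatal clinic is a conflict", {
  p <- patient_row("P9", patient_type = "new_transfer", sex = "female")
  a <- appt_row("P9", "2012-03-01", clinic = "antenatal_hiv",
                is_baseline = TRUE)
  expect_error(classify_appointments(a, p, empty_disp()),
               class = "ambu_classification_error")
})

test_that("classification agrees with per-day status on a generated cohort", {
  b <- suppressMessages(suppressWarnings(
    generate_cohort(cohort_config(n_patients = 50, seed = 13))))
  cls <- classify_appointments(b$appointments, b$patients, b$dispensing)
  for (i in seq_len(nrow(cls))) {
    rows <- b$dispensing[b$dispensing$patient_id == cls$patient_id[i], ]
    want <- oracle_haart_status(rows, cls$date[i])
    got <- if (endsWith(cls$appointment_type[i], "onHAART")) "on" else "off"
    expect_identical(got, want)
  }
})

test_that("tests link per the stated same-day / nearest-previous rules", {
  app <- dplyr::bind_rows(
    appt_row("P1", "2012-03-01"),
    appt_row("P1", "2012-04-01"),
    appt_row("P1", "2012-05-01", attended = FALSE)
  )
  tst <- dplyr::bind_rows(
    test_row("P1", "2012-03-01"),                       # same-day lab
    test_row("P1", "2012-03-02"),                       # lab, no same-day visit
    test_row("P1", "2012-03-10", "OTHER_TEST", "radiology"),
    test_row("P1", "2012-05-01", "OTHER_TEST", "cardiology")
  )
  lk <- link_tests(tst, app)
  expect_equal(lk$appointment_row, c(1L, NA, 1L, 2L))
  # never linked forward in time, never to a missed appointment
  linked <- lk[!is.na(lk$appointment_row), ]
  expect_true(all(app$date[linked$appointment_row] <= linked$date))
  expect_true(all(app$attended[linked$appointment_row]))
})

test_that("linkage agrees with exhaustive search on a generated cohort", {
  b <- suppressMessages(suppressWarnings(
    generate_cohort(cohort_config(n_patients = 40, seed = 17))))
  got <- link_tests(b$tests, b$appointments)$appointment_row
  want <- oracle_link(b$tests, b$appointments)
  expect_identical(got, want)
})

test_that("follow-up applies the start, activity and censoring rules", {
  fu <- suppressMessages(compute_follow_up(tiny_bundle()))
  fu <- fu[order(fu$patient_id), ]
  # existing patient active in August: the full leap year
  expect_equal(fu$patient_months[1], 366 / 30.4375, tolerance = 1e-10)
  expect_equal(round(fu$patient_months[1], 2), 12.02)
  # new patient starting 1 July: 184 days inclusive
  expect_equal(fu$start[2], as.Date("2012-07-01"))
  expect_equal(fu$patient_months[2], 184 / 30.4375, tolerance = 1e-10)
  expect_equal(round(fu$patient_months[2], 2), 6.05)
  # no activity after June: censored at the last scheduled appointment
  expect_equal(fu$end[3], as.Date("2012-03-15"))
  expect_equal(fu$patient_months[3], 75 / 30.4375, tolerance = 1e-10)
  expect_equal(round(fu$patient_months[3], 2), 2.46)
})

test_that("patients with no attended appointment are excluded, not costed", {
  patients <- dplyr::bind_rows(patient_row("P1"), patient_row("P2"))
  appointments <- dplyr::bind_rows(
    appt_row("P1", "2012-08-01"),
    appt_row("P2", "2012-08-01", attended = FALSE))
  b <- suppressWarnings(cohort_bundle(patients, appointments, empty_tests(),
                                      empty_disp()))
  fu <- suppressMessages(compute_follow_up(b))
  expect_equal(fu$patient_id, "P1")
  expect_equal(attr(fu, "excluded"), "P2")
  led <- suppressMessages(build_ledger(b))
  expect_false("P2" %in% led$cost_lines$patient_id)
})

test_that("the ledger prices every line and conserves totals", {
  led <- suppressMessages(build_ledger(tiny_bundle()))
  lines <- led$cost_lines
  expect_equal(lines$amount_eur, lines$quantity * lines$unit_cost_eur)
  expect_equal(ledger_total(led),
               ledger_total(led, "staff") + ledger_total(led, "diagnostic") +
                 ledger_total(led, "drug"))
  # P1: two HIV_onHAART visits, CD4 + VL + other test, 12 months of the
  # NNRTI regimen
  p1 <- sum(lines$amount_eur[lines$patient_id == "P1"])
  expect_equal(p1, 2 * 194.88 + 47.29 + 92.94 + 28.39 + 12 * 816.61)
  # single attended HIV visit, nothing else
  solo <- suppressWarnings(
    cohort_bundle(patient_row("S1"), appt_row("S1", "2012-08-01"),
                  empty_tests(), empty_disp()))
  expect_equal(ledger_total(suppressMessages(build_ledger(solo))), 174.89)
})

test_that("an empty bundle yields an empty ledger with zero total", {
  b <- suppressWarnings(cohort_bundle(
    patient_row(character(0))[0, ],
    appt_row(character(0), as.Date(character(0)))[0, ],
    empty_tests(), empty_disp()))
  led <- suppressMessages(build_ledger(b))
  expect_equal(nrow(led$cost_lines), 0L)
  expect_equal(ledger_total(led), 0)
})

test_that("classification is total over a generated cohort", {
  b <- suppressMessages(suppressWarnings(
    generate_cohort(cohort_config(n_patients = 60, seed = 23))))
  cls <- classify_appointments(b$appointments, b$patients, b$dispensing)
  counts <- table(factor(cls$appointment_type, levels = appointment_types()))
  expect_equal(sum(counts), nrow(b$appointments))
})
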