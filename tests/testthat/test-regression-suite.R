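test_that("the modified Park test recovers the variance power by family", {
  # gamma: variance proportional to mu^2
  d <- generate_glm_dataset(glm_sim_config(
    n = 2000, seed = 7, family = "gamma", link_power = 0,
    coefficients = c(`(Intercept)` = 1, x = 0.5), dispersion = 0.5))
  pt <- modified_park_test(d, y ~ x)
  expect_gt(pt$lambda_hat, 1.5)
  expect_lt(pt$lambda_hat, 2.5)
  expect_equal(pt$chosen_family, "gamma")
  expect_equal(names(which.min(pt$distances)), pt$chosen_family)
  # homoskedastic gaussian: constant variance, lambda near 0
  d2 <- generate_glm_dataset(glm_sim_config(
    n = 2000, seed = 8, family = "gaussian", link_power = 0,
    coefficients = c(`(Intercept)` = 2, x = 0.3), dispersion = 1))
  pt2 <- modified_park_test(d2, y ~ x,
                            working_family = gaussian("log"))
  expect_lt(abs(pt2$lambda_hat), 0.5)
  expect_equal(pt2$chosen_family, "gaussian")
  # inverse gaussian under a square-root link: variance prop. to mu^3
  d3 <- generate_glm_dataset(glm_sim_config(
    n = 2000, seed = 9, family = "inverse_gaussian", link_power = 0.5,
    coefficients = c(`(Intercept)` = 2, x = 0.3), dispersion = 0.05))
  pt3 <- modified_park_test(d3, y ~ x)
  expect_gt(pt3$lambda_hat, 2.5)
  expect_lt(pt3$lambda_hat, 3.5)
  # the OLS-on-logs variant points to the same family here
  expect_equal(modified_park_test(d, y ~ x, method = "ols")$chosen_family,
               "gamma")
})

test_that("the Park test rejects degenerate inputs", {
  d <- generate_glm_dataset(glm_sim_config(n = 40, seed = 1))
  expect_error(modified_park_test(d, y ~ x),
               class = "ambu_validation_error")
  exact <- tibble::tibble(x = rep(1:2, each = 30))
  exact$y <- exact$x * 2
  expect_error(modified_park_test(exact, y ~ factor(x)),
               class = "ambu_singular_error")
})

test_that("link diagnostics pass a correct link and reject a wrong one", {
  d <- generate_glm_dataset(glm_sim_config(
    n = 1500, seed = 31, family = "gamma", link_power = 0,
    coefficients = c(`(Intercept)` = 1, x = 0.8), dispersion = 0.1))
  right <- link_diagnostics(d, y ~ x, "gamma", 0)
  expect_true(right$converged)
  expect_true(all(c(right$pearson_corr_p, right$pregibon_p,
                    right$hosmer_lemeshow_p) >= 0 &
                  c(right$pearson_corr_p, right$pregibon_p,
                    right$hosmer_lemeshow_p) <= 1))
  expect_true(right$passed)
  # a steep log truth tested at the identity link: the Pregibon term
  # detects the curvature in most replicates
  hits <- 0
  for (r in 1:10) {
    dm <- generate_glm_dataset(glm_sim_config(
      n = 1500, seed = 600 + r, family = "gaussian", link_power = 0,
      coefficients = c(`(Intercept)` = 1, x = 0.8), dispersion = 0.25))
    wrong <- link_diagnostics(dm, y ~ x, "gaussian", 1)
    if (isTRUE(wrong$pregibon_p < 0.05)) hits <- hits + 1
  }
  expect_gte(hits, 8)
})

test_that("residuals orthogonal to predictions give a null Pearson test", {
  # symmetric design: residuals constructed exactly orthogonal to fitted
  d <- tibble::tibble(x = rep(c(-1, 1), each = 50),
                      y = rep(c(1, 2), each = 50) + rep(c(-0.5, 0.5), 50))
  dg <- link_diagnostics(d, y ~ x, "gaussian", 1, groups = 2)
  expect_gt(dg$pearson_corr_p, 0.95)
})

test_that("the power-link scan recovers the generating link", {
  d <- generate_glm_dataset(glm_sim_config(
    n = 2000, seed = 10, family = "gamma", link_power = 0.5,
    coefficients = c(`(Intercept)` = 3, x = 0.6), dispersion = 0.1))
  sc <- select_power_link(d, y ~ x, "gamma")
  expect_equal(nrow(sc$diagnostics), 11L)
  expect_true(abs(sc$chosen_power - 0.5) <= 0.1 + 1e-9)
  expect_false(sc$no_link_passed)
  # singleton grid returns that link with its diagnostics
  one <- select_power_link(d, y ~ x, "gamma", grid = 0.5)
  expect_equal(one$chosen_power, 0.5)
  expect_equal(nrow(one$diagnostics), 1L)
  expect_error(select_power_link(d, y ~ x, grid = numeric(0)),
               class = "ambu_validation_error")
})

test_that("cost GLMs recover planted coefficients and flag collinearity", {
  cfg <- glm_sim_config(
    n = 2000, seed = 12, family = "gaussian", link_power = 0.2,
    coefficients = c(`(Intercept)` = 4.026, female = 0.139),
    dispersion = 200^2,
    covariate_gen = list(female = function(n) rbinom(n, 1, 0.41)))
  d <- generate_glm_dataset(cfg)
  fit <- fit_cost_glm(d, y ~ female, "gaussian", 0.2)
  td <- tidy(fit)
  fem <- td[td$term == "female", ]
  expect_lt(abs(fem$estimate - 0.139), 3 * fem$std_error)
  expect_equal(glance(fit)$link_power, 0.2)
  # intercept-only: inverse link of the intercept is the fitted mean
  fit0 <- fit_cost_glm(d, y ~ 1, "gamma", 0)
  expect_equal(exp(coef(fit0$fit)[[1]]), mean(d$y), tolerance = 1e-6)
  # duplicated covariate column
  d$female2 <- d$female
  expect_error(fit_cost_glm(d, y ~ female + female2, "gaussian", 0.2),
               class = "ambu_collinearity_error")
})

test_that("logistic odds ratios equal the 2x2 cross-product ratio", {
  # planted cross-product ratio 6.6: (33 * 100) / (10 * 50)
  d <- tibble::tibble(
    y = rep(c(1, 0, 1, 0), c(33, 10, 50, 100)),
    x = rep(c(1, 1, 0, 0), c(33, 10, 50, 100)))
  fl <- fit_logistic(d, y ~ x)
  td <- tidy(fl)
  or <- td$odds_ratio[td$term == "x"]
  expect_equal(or, (33 * 100) / (10 * 50), tolerance = 1e-6)
  expect_true(td$ci_low[td$term == "x"] < or &
                or < td$ci_high[td$term == "x"])
  expect_error(fit_logistic(tibble::tibble(y = rep(1, 20), x = rnorm(20)),
                            y ~ x),
               class = "ambu_validation_error")
  expect_error(fit_logistic(tibble::tibble(y = rep(2, 20), x = rnorm(20)),
                            y ~ x),
               class = "ambu_validation_error")
})

test_that("separation is flagged rather than silently reported", {
  d <- tibble::tibble(y = rep(c(0, 1), each = 20),
                      x = rep(c(0, 1), each = 20))
  expect_warning(fl <- fit_logistic(d, y ~ x), "separation")
  expect_true(any(tidy(fl)$separation))
})

test_that("the chi-squared homogeneity test matches the Pearson formula", {
  perfect <- matrix(c(10, 10, 10, 10), 2, 2)
  r <- chi_squared_homogeneity(perfect)
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  # hand-computed: all expected cells 12.5, sum of (obs-exp)^2/exp = 18
  r2 <- chi_squared_homogeneity(matrix(c(20, 5, 5, 20), 2, 2))
  expect_equal(r2$statistic, 18)
  expect_equal(r2$df, 1L)
  # planted trend in a 3x2 table is detected at n = 300
  set.seed(77)
  g <- rep(c("a", "b", "c"), each = 100)
  p <- c(a = 0.3, b = 0.5, c = 0.7)[g]
  d <- tibble::tibble(group = g, hit = rbinom(300, 1, p))
  expect_lt(chi_squared_homogeneity(d)$p_value, 0.05)
  expect_error(chi_squared_homogeneity(matrix(c(0, 0, 5, 5), 2, 2)),
               class = "ambu_degenerate_error")
})
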