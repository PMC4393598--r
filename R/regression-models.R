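# Cost GLMs, logistic models for treatment/regimen choice, and the
# chi-squared homogeneity test.

#' Fit a cost GLM with a power link
#'
#' Maximum-likelihood GLM of a (skewed, positive) cost outcome on
#' patient covariates, with the family chosen by [modified_park_test()]
#' and the link by [select_power_link()] (or set directly). Coefficients
#' are reported on the linear-predictor scale. Exact collinearity is an
#' error naming the offending term; non-convergence is an error.
#'
#' @param data Data frame with the response and covariates.
#' @param formula Model formula; factor covariates use their first level
#'   as reference.
#' @param family Family name (see [glm_family()]).
#' @param link_power Power link in `[0, 1]` (0 = log).
#' @return A `cost_glm` object wrapping the `glm` fit with its family
#'   name and link power.
#' @export
fit_cost_glm <- function(data, formula, family = "gaussian",
                         link_power = 0.2) {
  fam <- glm_family(family, link_power)
  mf <- stats::model.frame(formula, data)
  mm <- model.matrix(formula, mf)
  ls_coef <- stats::lm.fit(mm, stats::model.response(mf))$coefficients
  if (anyNA(ls_coef)) {
    abort(sprintf("Collinear covariate column(s): %s.",
                  paste(names(ls_coef)[is.na(ls_coef)], collapse = ", ")),
          class = "ambu_collinearity_error")
  }
  fit <- fit_glm_safely(formula, data, fam)
  if (!inherits(fit, "glm")) {
    abort(sprintf("GLM failed: %s.", conditionMessage(fit)),
          class = "ambu_fit_error")
  }
  if (!fit$converged) {
    abort("GLM did not converge.", class = "ambu_fit_error")
  }
  structure(list(fit = fit,
                 family = if (is.character(family)) family else fam$family,
                 link_power = link_power, formula = formula,
                 n = nrow(stats::model.frame(fit))),
            class = "cost_glm")
}

#' @export
print.cost_glm <- function(x, ...) {
  cat(sprintf("Cost GLM: %s family, link power %.1f, n = %d\n",
              x$family, x$link_power, x$n))
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cost_glm <- function(x, ...) {
  est <- summary(x$fit)$coefficients
  tibble(term = rownames(est), estimate = est[, 1], std_error = est[, 2],
         statistic = est[, 3], p_value = est[, 4])
}

#' @exportS3Method generics::glance
glance.cost_glm <- function(x, ...) {
  s <- summary(x$fit)
  tibble(family = x$family, link_power = x$link_power, n = x$n,
         deviance = s$deviance, dispersion = s$dispersion,
         aic = s$aic, converged = x$fit$converged)
}

#' @exportS3Method ggplot2::autoplot
autoplot.cost_glm <- function(object, conf_level = 0.95, ...) {
  td <- tidy(object)
  td <- td[td$term != "(Intercept)", ]
  z <- qnorm(1 - (1 - conf_level) / 2)
  td$low <- td$estimate - z * td$std_error
  td$high <- td$estimate + z * td$std_error
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate,
                                   y = stats::reorder(.data$term,
                                                      .data$estimate))) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$low,
                                          xmax = .data$high)) +
    ggplot2::labs(x = "coefficient (linear-predictor scale)", y = NULL,
                  title = sprintf("Cost GLM (%s, link power %.1f)",
                                  object$family, object$link_power)) +
    ggplot2::theme_minimal()
}

#' Logistic regression reported as odds ratios
#'
#' Binary-outcome logistic model with exponentiated coefficients and
#' Wald confidence intervals, as used for treatment receipt (HAART
#' yes/no) and regimen-class choice (PI vs NNRTI on the single-class
#' subset). A single-class outcome is a validation error; likely
#' separation (an extreme coefficient or standard error) is flagged per
#' term rather than hidden.
#'
#' @param data Data frame.
#' @param formula Formula with a binary outcome (logical, 0/1 or
#'   two-level factor).
#' @param conf_level Confidence level for the Wald intervals.
#' @return An `ambu_logistic` object; `tidy()` gives one row per term
#'   with `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `separation`.
#' @export
fit_logistic <- function(data, formula, conf_level = 0.95) {
  y <- stats::model.response(stats::model.frame(formula, data))
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) {
    abort("The outcome must be binary.", class = "ambu_validation_error")
  }
  if (length(unique(y)) < 2) {
    abort("The outcome has a single class; a logistic model cannot be fit.",
          class = "ambu_validation_error")
  }
  fit <- suppressWarnings(glm(formula, data = data, family = binomial()))
  est <- summary(fit)$coefficients
  z <- qnorm(1 - (1 - conf_level) / 2)
  beta <- unname(est[, 1])
  se <- unname(est[, 2])
  res <- tibble(
    term = rownames(est), estimate = beta, std_error = se,
    odds_ratio = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    p_value = unname(est[, 4]),
    separation = abs(beta) > 10 | se > 10
  )
  if (any(res$separation)) {
    warn(sprintf("Possible separation for term(s): %s.",
                 paste(res$term[res$separation], collapse = ", ")))
  }
  structure(list(fit = fit, results = res, formula = formula,
                 n = length(y), conf_level = conf_level),
            class = "ambu_logistic")
}

#' @export
print.ambu_logistic <- function(x, ...) {
  cat(sprintf("Logistic model (n = %d), odds ratios with %d%% Wald CIs:\n",
              x$n, round(100 * x$conf_level)))
  print(select(x$results, "term", "odds_ratio", "ci_low", "ci_high",
               "p_value"))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ambu_logistic <- function(x, ...) x$results

#' @exportS3Method generics::glance
glance.ambu_logistic <- function(x, ...) {
  tibble(n = x$n, deviance = x$fit$deviance,
         null_deviance = x$fit$null.deviance, aic = x$fit$aic,
         converged = x$fit$converged,
         any_separation = any(x$results$separation))
}

#' Pearson chi-squared homogeneity test
#'
#' Pearson chi-squared test of equal proportions across groups, without
#' continuity correction (so the 2x2 statistic is the classical
#' `N(ad - bc)^2 / (row and column marginals)` form).
#'
#' @param x A contingency table/matrix of counts, or a data frame whose
#'   first two columns are cross-tabulated.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
chi_squared_homogeneity <- function(x) {
  tab <- if (is.data.frame(x)) table(x[[1]], x[[2]]) else as.table(as.matrix(x))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Degenerate table: a row or column marginal is zero.",
          class = "ambu_degenerate_error")
  }
  res <- suppressWarnings(chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = unname(res$p.value))
}
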