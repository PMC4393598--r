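# Power-link diagnostics and selection: Pearson correlation, Pregibon
# link test and a modified (continuous-response) Hosmer-Lemeshow test,
# evaluated over a grid of candidate power links.

#' Link diagnostics for one candidate power link
#'
#' Fits the GLM at `(family, link_power)` and runs three specification
#' tests of the link:
#' * Pearson correlation test — p-value for zero correlation between raw
#'   residuals and predictions (by default; the linear predictor can be
#'   used instead);
#' * Pregibon link test — the response is refit on the fitted linear
#'   predictor and its square; the p-value is for the squared term;
#' * modified Hosmer-Lemeshow — raw residuals are grouped into deciles
#'   of the prediction and an F-test checks that all decile means are
#'   zero.
#' The link "passes" when all three p-values exceed `alpha`.
#'
#' @param data Data frame with response and covariates.
#' @param formula Model formula.
#' @param family Family name (see [glm_family()]).
#' @param link_power Power link to test, in `[0, 1]` (0 = log).
#' @param alpha Significance level for the pass flag.
#' @param groups Number of prediction groups for the Hosmer-Lemeshow
#'   test.
#' @param pearson_on `"predictions"` (default) or `"linear_predictor"`.
#' @return A `link_diagnostics` one-row tibble: `link_power`,
#'   `pearson_corr_p`, `pregibon_p`, `hosmer_lemeshow_p`, `min_p`,
#'   `passed`, `converged`, `failure`.
#' @export
link_diagnostics <- function(data, formula, family = "gamma", link_power = 0,
                             alpha = 0.05, groups = 10,
                             pearson_on = c("predictions",
                                            "linear_predictor")) {
  pearson_on <- match.arg(pearson_on)
  fail <- function(reason) {
    tibble(link_power = link_power, pearson_corr_p = NA_real_,
           pregibon_p = NA_real_, hosmer_lemeshow_p = NA_real_,
           min_p = NA_real_, passed = FALSE, converged = FALSE,
           failure = reason)
  }
  fam <- glm_family(family, link_power)
  fit <- fit_glm_safely(formula, data, fam)
  if (!inherits(fit, "glm") || !fit$converged) {
    return(structure(fail("fit did not converge"),
                     class = c("link_diagnostics", class(tibble()))))
  }
  y <- stats::model.response(stats::model.frame(formula, data))
  mu <- fitted(fit)
  eta <- fam$linkfun(mu)
  res <- y - mu

  ref <- if (pearson_on == "predictions") mu else eta
  pearson_p <- tryCatch(cor.test(res, ref)$p.value, error = function(e) NA)
  if (!is.na(pearson_p) && stats::sd(res) < .Machine$double.eps) pearson_p <- 1

  # Pregibon: refit on the linear predictor and its square; a
  # significant quadratic term signals a mis-specified link.
  preg_df <- tibble(y = y, z = eta, z2 = eta^2)
  preg <- fit_glm_safely(y ~ z + z2, preg_df, fam)
  pregibon_p <- if (inherits(preg, "glm") && preg$converged &&
                    !is.na(coef(preg)["z2"])) {
    summary(preg)$coefficients["z2", 4]
  } else NA_real_

  if (length(unique(mu)) < groups) {
    return(structure(fail(sprintf("fewer than %d distinct predictions", groups)),
                     class = c("link_diagnostics", class(tibble()))))
  }
  decile <- cut(rank(mu, ties.method = "first"),
                breaks = seq(0, length(mu), length.out = groups + 1),
                labels = FALSE)
  hl_fit <- lm(res ~ 0 + factor(decile))
  fstat <- summary(hl_fit)$fstatistic
  hl_p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)

  ps <- c(pearson_p, pregibon_p, hl_p)
  out <- tibble(link_power = link_power, pearson_corr_p = pearson_p,
                pregibon_p = pregibon_p, hosmer_lemeshow_p = unname(hl_p),
                min_p = if (anyNA(ps)) NA_real_ else min(ps),
                passed = !anyNA(ps) && all(ps > alpha), converged = TRUE,
                failure = NA_character_)
  structure(out, class = c("link_diagnostics", class(tibble())))
}

#' Select a power link over a grid
#'
#' Runs [link_diagnostics()] at every grid point and picks, among links
#' passing all three tests, the one with the largest minimum p-value
#' (the least evidence of link mis-specification). If no link passes,
#' the largest-minimum-p link is returned with `no_link_passed = TRUE`.
#'
#' @inheritParams link_diagnostics
#' @param grid Candidate powers (default 0, 0.1, ..., 1).
#' @return A `link_scan` list: `chosen_power`, `no_link_passed`, and
#'   `diagnostics` (one row per grid point).
#' @export
select_power_link <- function(data, formula, family = "gamma",
                              grid = seq(0, 1, by = 0.1), alpha = 0.05,
                              groups = 10,
                              pearson_on = c("predictions",
                                             "linear_predictor")) {
  if (!length(grid)) {
    abort("The link grid must be non-empty.", class = "ambu_validation_error")
  }
  pearson_on <- match.arg(pearson_on)
  diag <- purrr::map(grid, function(p) {
    link_diagnostics(data, formula, family, p, alpha, groups, pearson_on)
  }) |> bind_rows()
  if (all(!diag$converged)) {
    abort("No candidate link produced a converged fit.",
          class = "ambu_selection_error")
  }
  pool <- if (any(diag$passed)) diag[diag$passed, ] else
    diag[!is.na(diag$min_p), ]
  if (nrow(pool) == 0) pool <- diag[diag$converged, ]
  chosen <- pool$link_power[which.max(pool$min_p)]
  structure(list(chosen_power = chosen, no_link_passed = !any(diag$passed),
                 diagnostics = diag, family = family, alpha = alpha),
            class = "link_scan")
}

#' @export
print.link_scan <- function(x, ...) {
  cat(sprintf("Power-link scan (%s family): chosen power %.1f%s\n",
              x$family, x$chosen_power,
              if (x$no_link_passed) " [no link passed all tests]" else ""))
  print(as_tibble(x$diagnostics))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.link_scan <- function(x, ...) as_tibble(x$diagnostics)

#' @exportS3Method generics::glance
glance.link_scan <- function(x, ...) {
  tibble(chosen_power = x$chosen_power, no_link_passed = x$no_link_passed,
         family = x$family, alpha = x$alpha,
         n_grid = nrow(x$diagnostics))
}

#' @exportS3Method ggplot2::autoplot
autoplot.link_scan <- function(object, ...) {
  d <- tidyr::pivot_longer(object$diagnostics,
                           c("pearson_corr_p", "pregibon_p",
                             "hosmer_lemeshow_p"),
                           names_to = "test", values_to = "p_value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$link_power, y = .data$p_value,
                                  colour = .data$test)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$alpha, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = object$chosen_power,
                        linetype = "dotted") +
    ggplot2::labs(x = "link power (0 = log)", y = "p-value",
                  title = sprintf("Power-link diagnostics (%s family)",
                                  object$family)) +
    ggplot2::theme_minimal()
}
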