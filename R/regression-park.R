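# Modified Park test: GLM family selection for skewed cost data via the
# estimated power in the variance-mean relationship Var(y|x) ∝ E(y|x)^λ.

#' Build a GLM family with a power link
#'
#' Convenience wrapper mapping the family names used throughout this
#' package to [stats::family] objects with a power link; link power 0 is
#' the logarithmic link (the power-family limit).
#'
#' @param family `"gaussian"`, `"poisson"`, `"gamma"` or
#'   `"inverse_gaussian"`.
#' @param link_power Power in `[0, 1]`; 0 means log.
#' @return A `family` object.
#' @export
glm_family <- function(family = GLM_FAMILIES, link_power = 0) {
  family <- match.arg(family)
  link <- if (link_power == 0) "log" else stats::power(link_power)
  switch(family,
         gaussian = gaussian(link),
         poisson = poisson(link),
         gamma = Gamma(link),
         inverse_gaussian = inverse.gaussian(link))
}

fit_glm_safely <- function(formula, data, family) {
  y <- stats::model.response(stats::model.frame(formula, data))
  try1 <- tryCatch(glm(formula, data = data, family = family),
                   error = function(e) e, warning = function(w) w)
  if (inherits(try1, "glm") && try1$converged) return(try1)
  # Power links can fail to find valid starting values; restart from the
  # observed response (floored away from zero). glm() evaluates `mustart`
  # inside `data`, so it is passed as a column.
  data2 <- as.data.frame(data)
  data2$.mustart <- pmax(y, max(min(y[y > 0], na.rm = TRUE), 1e-3))
  tryCatch(suppressWarnings(
    glm(formula, data = data2, family = family, mustart = .mustart)),
    error = function(e) if (inherits(try1, "glm")) try1 else e)
}

#' Modified Park test for GLM family selection
#'
#' Fits a working GLM (by default gamma with log link), then regresses
#' the squared raw residuals on the log of the fitted means in a
#' log-link quasi-Poisson GLM. The slope `lambda_hat` estimates the
#' power in Var(y|x) ∝ mu^lambda; the family is chosen by the nearest
#' of 0 (Gaussian), 1 (Poisson), 2 (gamma), 3 (inverse Gaussian). An
#' ordinary least-squares regression of log squared residuals is
#' available as an alternative estimator.
#'
#' @param data Data frame containing the response and covariates.
#' @param formula Model formula for the working fit.
#' @param working_family Family of the working fit supplying the
#'   predictions (default gamma, log link).
#' @param method `"glm"` (log-link quasi-Poisson of squared residuals,
#'   the default) or `"ols"` (least squares on log squared residuals,
#'   dropping zero residuals).
#' @return A `park_test` object: `lambda_hat`, `se_lambda`,
#'   `chosen_family`, and the per-family distances `|lambda_hat - k|`.
#' @export
modified_park_test <- function(data, formula,
                               working_family = glm_family("gamma", 0),
                               method = c("glm", "ols")) {
  method <- match.arg(method)
  if (nrow(data) < 50) {
    abort("The modified Park test needs at least 50 observations.",
          class = "ambu_validation_error")
  }
  working <- fit_glm_safely(formula, data, working_family)
  if (!inherits(working, "glm")) {
    abort(sprintf("Working fit failed: %s.", conditionMessage(working)),
          class = "ambu_fit_error")
  }
  mu <- fitted(working)
  if (any(mu <= 0)) {
    abort("Working fit produced nonpositive predictions.",
          class = "ambu_domain_error")
  }
  y <- stats::model.response(stats::model.frame(formula, data))
  r2 <- (y - mu)^2
  if (all(r2 < .Machine$double.eps)) {
    abort("All residuals are zero; the Park regression is singular.",
          class = "ambu_singular_error")
  }
  park_df <- tibble(r2 = r2, lmu = log(mu))
  if (method == "glm") {
    fit <- glm(r2 ~ lmu, data = park_df, family = quasipoisson(link = "log"))
  } else {
    fit <- lm(log(r2) ~ lmu, data = park_df[park_df$r2 > 0, ])
  }
  est <- summary(fit)$coefficients
  lambda_hat <- est["lmu", 1]
  k <- c(gaussian = 0, poisson = 1, gamma = 2, inverse_gaussian = 3)
  dist <- abs(lambda_hat - k)
  structure(list(lambda_hat = lambda_hat, se_lambda = est["lmu", 2],
                 chosen_family = names(which.min(dist)), distances = dist,
                 method = method, n = nrow(data)),
            class = "park_test")
}

#' @export
print.park_test <- function(x, ...) {
  cat(sprintf("Modified Park test (%s): lambda = %.3f (SE %.3f) -> %s family\n",
              x$method, x$lambda_hat, x$se_lambda, x$chosen_family))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.park_test <- function(x, ...) {
  tibble(family = names(x$distances), variance_power = unname(c(0, 1, 2, 3)),
         distance = unname(x$distances),
         chosen = names(x$distances) == x$chosen_family)
}

#' @exportS3Method generics::glance
glance.park_test <- function(x, ...) {
  tibble(lambda_hat = x$lambda_hat, se_lambda = x$se_lambda,
         chosen_family = x$chosen_family, method = x$method, n = x$n)
}
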