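# Simulation of GLM datasets with planted truth, used for parameter- and
# link-recovery tests of the regression suite.

GLM_FAMILIES <- c("gaussian", "poisson", "gamma", "inverse_gaussian")

# Mean from the linear predictor under a power link mu = eta^(1/p);
# p = 0 denotes the logarithmic link (the power-family limit).
power_link_inv <- function(eta, link_power) {
  if (link_power == 0) exp(eta) else eta^(1 / link_power)
}

# Inverse-Gaussian deviates via the Michael-Schucany-Haas transform;
# mean `mu`, shape `lambda`, variance mu^3 / lambda.
rinvgauss <- function(n, mu, lambda) {
  y <- rnorm(n)^2
  x <- mu + mu^2 * y / (2 * lambda) -
    mu / (2 * lambda) * sqrt(4 * mu * lambda * y + mu^2 * y^2)
  u <- runif(n)
  ifelse(u <= mu / (mu + x), x, mu^2 / x)
}

#' Configuration for a simulated GLM dataset
#'
#' @param n Sample size.
#' @param seed Seed for the draw.
#' @param family One of `"gaussian"`, `"poisson"`, `"gamma"`,
#'   `"inverse_gaussian"`.
#' @param link_power Power of the link function, in `[0, 1]`; `0` is the
#'   logarithmic link.
#' @param coefficients Named numeric vector of linear-predictor
#'   coefficients; the element named `"(Intercept)"` is the intercept,
#'   every other name becomes a covariate column.
#' @param dispersion Dispersion parameter: the Gaussian variance, the
#'   Gamma squared coefficient of variation, the inverse-Gaussian
#'   `1/lambda` scale; ignored for Poisson.
#' @param covariate_gen Optional named list of functions `f(n)` drawing
#'   each covariate; default standard normal.
#' @return A validated `glm_sim_config` list.
#' @export
glm_sim_config <- function(n, seed = 1, family = "gamma", link_power = 0,
                           coefficients = c(`(Intercept)` = 1, x = 0.5),
                           dispersion = 1, covariate_gen = NULL) {
  family <- match.arg(family, GLM_FAMILIES)
  if (!is.numeric(link_power) || length(link_power) != 1 ||
      link_power < 0 || link_power > 1) {
    abort("`link_power` must be a single number in [0, 1].",
          class = "ambu_validation_error")
  }
  if (dispersion <= 0) {
    abort("`dispersion` must be positive.", class = "ambu_validation_error")
  }
  if (!"(Intercept)" %in% names(coefficients)) {
    abort("`coefficients` must include an \"(Intercept)\" element.",
          class = "ambu_validation_error")
  }
  structure(list(n = as.integer(n), seed = seed, family = family,
                 link_power = link_power, coefficients = coefficients,
                 dispersion = dispersion, covariate_gen = covariate_gen),
            class = "glm_sim_config")
}

#' Draw a GLM dataset with recorded truth
#'
#' Simulates covariates and a response whose conditional mean is the
#' inverse power link of the linear predictor, with the stated family's
#' mean-variance relationship. The generating truth (family, link power,
#' coefficients, dispersion) is attached as the `"truth"` attribute for
#' recovery tests.
#'
#' @param config A [glm_sim_config()].
#' @return Tibble with one column per covariate and a response column
#'   `y`; attribute `truth` holds the generating parameters.
#' @export
generate_glm_dataset <- function(config) {
  stopifnot(inherits(config, "glm_sim_config"))
  set.seed(config$seed)
  beta <- config$coefficients
  covs <- setdiff(names(beta), "(Intercept)")
  X <- purrr::map(covs, function(v) {
    gen <- config$covariate_gen[[v]] %||% rnorm
    gen(config$n)
  })
  names(X) <- covs
  X <- if (length(covs)) as_tibble(X) else tibble(.rows = config$n)
  eta <- if (length(covs)) {
    drop(as.matrix(X) %*% beta[covs]) + beta[["(Intercept)"]]
  } else {
    rep(beta[["(Intercept)"]], config$n)
  }
  if (config$link_power > 0 && any(eta <= 0)) {
    abort(paste("Linear predictor is nonpositive under a positive power",
                "link; rescale the coefficients."),
          class = "ambu_generation_error")
  }
  mu <- power_link_inv(eta, config$link_power)
  if (config$family != "gaussian" && any(mu <= 0)) {
    abort("Nonpositive means are invalid for this family; rescale the coefficients.",
          class = "ambu_generation_error")
  }
  phi <- config$dispersion
  y <- switch(config$family,
    gaussian = rnorm(config$n, mu, sqrt(phi)),
    poisson = rpois(config$n, mu),
    gamma = rgamma(config$n, shape = 1 / phi, rate = 1 / (phi * mu)),
    inverse_gaussian = rinvgauss(config$n, mu, 1 / phi)
  )
  out <- bind_cols(X, tibble(y = y))
  attr(out, "truth") <- config[c("family", "link_power", "coefficients",
                                 "dispersion")]
  out
}
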