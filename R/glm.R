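#' Fit the outcome GLMs of the depletion experiments
#'
#' Four model families over an outcome table:
#' \itemize{
#'   \item `morans`: Moran's I ~ cell + landscape + function (gamma, log link);
#'   \item `territory`: female territory size ~ cell + landscape + function
#'     (gamma, log link);
#'   \item `population`: population size ~ cell + landscape + function
#'     (negative binomial, log link);
#'   \item `territory_vs_morans`, `population_vs_morans`: outcome ~ Moran's I
#'     + landscape level.
#' }
#' Control replicates are the reference category for every factor. Because
#' the control level ties the three factors together, two dummy columns are
#' linearly dependent; factor levels are ordered so that the landscape-5%
#' and random-function columns are the ones dropped (reported as `dropped`).
#' Rows with a missing response (e.g. Moran's I of the zero-variance uniform
#' control, or territory size of extinct replicates) are excluded from the
#' affected model; populations of extinct replicates are retained as 0.
#' Wald confidence intervals (default 90%) are computed on the link scale.
#'
#' @param outcomes an outcome table from [run_experiment_suite()] (columns
#'   `fun`, `landscape_fraction`, `cell_fraction`, `population`,
#'   `territory_km2`, `starvation_rate`, `morans_i`).
#' @param ci_level confidence level for the Wald intervals.
#' @return list of class `outcome_models`: one tidy coefficient data.frame
#'   (`term`, `estimate`, `se`, `ci_lo`, `ci_hi`, `dropped`) per model, plus
#'   `control_means`.
#' @export
fit_outcome_models <- function(outcomes, ci_level = 0.9) {
  d <- as.data.frame(outcomes)
  d$cell_f <- depletion_factor(d$cell_fraction, d$fun,
                               alias_last = FALSE, prefix = "cell")
  d$landscape_f <- depletion_factor(d$landscape_fraction, d$fun,
                                    alias_last = TRUE, prefix = "landscape")
  d$fun_f <- function_factor(d$fun)
  z <- qnorm(1 - (1 - ci_level) / 2)

  fit_gamma <- function(formula, data) {
    data <- droplevels(data[stats::complete.cases(data[all.vars(formula)]), ])
    tidy_glm(glm(formula, data = data, family = Gamma(link = "log")), z)
  }
  fit_nb <- function(formula, data) {
    data <- droplevels(data[stats::complete.cases(data[all.vars(formula)]), ])
    tidy_glm(MASS::glm.nb(formula, data = data), z)
  }

  ctrl <- d[d$fun == "control", ]
  models <- list(
    morans = fit_gamma(morans_i ~ cell_f + landscape_f + fun_f, d),
    territory = fit_gamma(territory_km2 ~ cell_f + landscape_f + fun_f, d),
    population = fit_nb(population ~ cell_f + landscape_f + fun_f, d),
    territory_vs_morans = fit_gamma(territory_km2 ~ morans_i + landscape_f, d),
    population_vs_morans = fit_nb(population ~ morans_i + landscape_f, d),
    control_means = data.frame(
      population = mean(ctrl$population, na.rm = TRUE),
      territory_km2 = mean(ctrl$territory_km2, na.rm = TRUE),
      starvation_rate = mean(ctrl$starvation_rate, na.rm = TRUE)))
  class(models) <- "outcome_models"
  models
}

# factor with the control level first (reference); for the landscape factor
# the 5% level is ordered last so QR pivoting drops it (alias with control)
depletion_factor <- function(fraction, fun, alias_last, prefix) {
  lab <- ifelse(fun == "control", "control",
                sprintf("%s_%g", prefix, 100 * fraction))
  lev <- unique(lab[order(fun != "control", fraction)])
  if (alias_last && length(lev) > 2) lev <- c(lev[1], lev[-(1:2)], lev[2])
  factor(lab, levels = lev)
}

function_factor <- function(fun) {
  ord <- c("control", "exponential", "logarithm", "linear",
           "inverse_distance_weighted", "one_minus_exponential", "random")
  factor(fun, levels = ord[ord %in% unique(fun)])
}

tidy_glm <- function(fit, z) {
  cf <- coef(fit)
  sm <- summary(fit)$coefficients
  se <- rep(NA_real_, length(cf))
  names(se) <- names(cf)
  se[rownames(sm)] <- sm[, "Std. Error"]
  data.frame(term = clean_term(names(cf)), estimate = unname(cf),
             se = unname(se),
             ci_lo = unname(cf - z * se), ci_hi = unname(cf + z * se),
             dropped = is.na(unname(cf)), row.names = NULL)
}

clean_term <- function(x) {
  x <- sub("^cell_f", "", x)
  x <- sub("^landscape_f", "", x)
  x <- sub("^fun_f", "", x)
  x
}

#' @export
print.outcome_models <- function(x, ...) {
  for (nm in setdiff(names(x), "control_means")) {
    cat("==", nm, "==\n")
    print(x[[nm]], digits = 3)
  }
  cat("== control means ==\n")
  print(x$control_means, digits = 4)
  invisible(x)
}

#' Exponentiated effect of a log-link coefficient
#'
#' On the response scale a coefficient `b` multiplies the baseline by
#' `exp(b)`: a coefficient of 0.04 on a baseline of 20.51 km^2 predicts
#' about 21.35 km^2.
#'
#' @param baseline baseline (reference-category) mean.
#' @param coefficient log-link coefficient.
#' @export
exp_effect <- function(baseline, coefficient) baseline * exp(coefficient)

#' Look up a coefficient in a tidy model table
#'
#' @param model one tidy data.frame from [fit_outcome_models()].
#' @param term coefficient name, e.g. `"landscape_25"`.
#' @export
model_coef <- function(model, term) {
  i <- match(term, model$term)
  if (is.na(i)) stop(sprintf("no term '%s' in model", term))
  model$estimate[i]
}
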