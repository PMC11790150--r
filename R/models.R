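# Parameter containers for the pollination -> fertilization -> growth pipeline.
# All validation lives in the constructors so downstream code can assume
# well-formed models.

stop_domain <- function(msg, class = "strawsim_domain_error") {
  stop(errorCondition(msg, class = c(class, "strawsim_error", "error", "condition")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         integer = FALSE, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_domain(sprintf("'%s' must be a single finite number", name))
  }
  if (strict_lower && x <= lower) {
    stop_domain(sprintf("'%s' must be > %s (got %s)", name, lower, x))
  }
  if (!strict_lower && x < lower) {
    stop_domain(sprintf("'%s' must be >= %s (got %s)", name, lower, x))
  }
  if (x > upper) {
    stop_domain(sprintf("'%s' must be <= %s (got %s)", name, upper, x))
  }
  if (integer && x != round(x)) {
    stop_domain(sprintf("'%s' must be an integer (got %s)", name, x))
  }
  x
}

#' Bee visitation model
#'
#' Parameters of the daily bee-visit process for a single flower. Visits on
#' each day of bloom are independent Poisson counts with mean
#' `lambda_visits`; each visit deposits a fixed number of viable pollen
#' grains on the stigma.
#'
#' @param lambda_visits Mean bee visits per flower per day (default 4.5).
#' @param grains_per_visit Viable pollen grains deposited per visit
#'   (default 25).
#' @param bloom_days Flower lifespan in days (default 5).
#' @return An object of class `visit_model`.
#' @examples
#' visit_model()
#' visit_model(lambda_visits = 6)
#' @export
visit_model <- function(lambda_visits = 4.5, grains_per_visit = 25,
                        bloom_days = 5) {
  check_number(lambda_visits, "lambda_visits", lower = 0, strict_lower = TRUE)
  check_number(grains_per_visit, "grains_per_visit", lower = 1, integer = TRUE)
  check_number(bloom_days, "bloom_days", lower = 1, integer = TRUE)
  structure(
    list(lambda_visits = lambda_visits,
         grains_per_visit = as.integer(grains_per_visit),
         bloom_days = as.integer(bloom_days)),
    class = "visit_model"
  )
}

#' Fertilization model
#'
#' Age-dependent fertilization of deposited pollen. Stigma receptivity on
#' bloom day `n` decays as `exp(-decay_coeff * n^decay_power)`; a receptive
#' grain fertilizes with probability `compatibility` (self-pollen
#' compatibility of the cultivar, 0.8 for Beni hoppe).
#'
#' @param compatibility Self-pollen compatibility probability in \[0, 1\]
#'   (default 0.8).
#' @param decay_coeff Receptivity decay coefficient (default 0.01).
#' @param decay_power Receptivity decay exponent (default 3.6).
#' @return An object of class `fertilization_model`.
#' @export
fertilization_model <- function(compatibility = 0.8, decay_coeff = 0.01,
                                decay_power = 3.6) {
  check_number(compatibility, "compatibility", lower = 0, upper = 1)
  check_number(decay_coeff, "decay_coeff", lower = 0, strict_lower = TRUE)
  check_number(decay_power, "decay_power", lower = 0, strict_lower = TRUE)
  structure(
    list(compatibility = compatibility, decay_coeff = decay_coeff,
         decay_power = decay_power),
    class = "fertilization_model"
  )
}

#' Fruit growth model
#'
#' Linear map from achene count to fruit weight in grams,
#' `W = slope * Z_sum + intercept + Bias` with `Bias ~ N(0, bias_sd^2)`,
#' plus the commercial marketability threshold.
#'
#' The default `bias_sd = 3.09` g is calibrated so that the cohort weight
#' standard deviation `sqrt(slope^2 * Var(Z_sum) + bias_sd^2)` equals 4.42 g
#' under the default pollination and fertilization parameters
#' (`Var(Z_sum) ~ 3998`); see the methods vignette for the derivation.
#'
#' @param slope Grams of fruit weight per achene (default 0.05).
#' @param intercept Baseline weight in grams (default 2.0).
#' @param bias_sd Residual standard deviation in grams (default 3.09).
#' @param marketable_threshold Weight in grams a fruit must exceed
#'   (strictly) to be marketable (default 10).
#' @return An object of class `growth_model`.
#' @export
growth_model <- function(slope = 0.05, intercept = 2.0, bias_sd = 3.09,
                         marketable_threshold = 10) {
  check_number(slope, "slope", lower = 0, strict_lower = TRUE)
  check_number(intercept, "intercept")
  check_number(bias_sd, "bias_sd", lower = 0)
  check_number(marketable_threshold, "marketable_threshold",
               lower = 0, strict_lower = TRUE)
  structure(
    list(slope = slope, intercept = intercept, bias_sd = bias_sd,
         marketable_threshold = marketable_threshold),
    class = "growth_model"
  )
}

#' Full simulation configuration
#'
#' Bundles the three sub-models with the cohort size and RNG seed. Identical
#' configuration and seed always reproduce the identical cohort.
#'
#' @param visit A [visit_model()].
#' @param fert A [fertilization_model()].
#' @param growth A [growth_model()].
#' @param n_flowers Number of flowers simulated per cohort (default 10000).
#' @param seed Integer RNG seed, or `NULL` to use the current RNG state.
#' @return An object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(seed = 1, n_flowers = 500)
#' @export
simulation_config <- function(visit = visit_model(),
                              fert = fertilization_model(),
                              growth = growth_model(),
                              n_flowers = 10000, seed = NULL) {
  stopifnot(inherits(visit, "visit_model"),
            inherits(fert, "fertilization_model"),
            inherits(growth, "growth_model"))
  check_number(n_flowers, "n_flowers", lower = 1, integer = TRUE)
  if (!is.null(seed)) check_number(seed, "seed", integer = TRUE)
  structure(
    list(visit = visit, fert = fert, growth = growth,
         n_flowers = as.integer(n_flowers),
         seed = if (is.null(seed)) NULL else as.integer(seed)),
    class = "simulation_config"
  )
}

#' @export
print.simulation_config <- function(x, ...) {
  cat("Strawberry cohort simulation configuration\n")
  cat(sprintf("  visits:  Poisson(lambda = %g), %d grains/visit, %d bloom days\n",
              x$visit$lambda_visits, x$visit$grains_per_visit,
              x$visit$bloom_days))
  cat(sprintf("  fertilization: compatibility %g, receptivity exp(-%g * n^%g)\n",
              x$fert$compatibility, x$fert$decay_coeff, x$fert$decay_power))
  cat(sprintf("  growth:  W = %g * Z_sum + %g + N(0, %g^2); marketable > %g g\n",
              x$growth$slope, x$growth$intercept, x$growth$bias_sd,
              x$growth$marketable_threshold))
  cat(sprintf("  cohort:  %d flowers, seed %s\n", x$n_flowers,
              if (is.null(x$seed)) "<none>" else x$seed))
  invisible(x)
}
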