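# Configuration files and structured outputs. Config format is YAML; the
# flat key set mirrors the model parameters. Unknown keys are errors, not
# warnings — a silently misread simulator config is worse than friction.

CONFIG_KEYS <- c("lambda_visits", "grains_per_visit", "bloom_days",
                 "compatibility", "decay_coeff", "decay_power",
                 "slope", "intercept", "bias_sd", "marketable_threshold",
                 "n_flowers", "seed")

#' Load a simulation configuration from a YAML file
#'
#' Flat YAML with any subset of the keys `lambda_visits`,
#' `grains_per_visit`, `bloom_days`, `compatibility`, `decay_coeff`,
#' `decay_power`, `slope`, `intercept`, `bias_sd`, `marketable_threshold`,
#' `n_flowers`, `seed`; missing keys take the model defaults, an empty
#' file yields the full default configuration, and unknown keys or
#' out-of-range values raise a validation error naming the field.
#'
#' @param path Path to a YAML file.
#' @return A validated [simulation_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop_domain(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop_domain(sprintf("config file is not a key-value mapping: %s", path))
  unknown <- setdiff(names(raw), CONFIG_KEYS)
  if (length(unknown) > 0) {
    stop_domain(sprintf("unknown config key(s): %s",
                        paste(unknown, collapse = ", ")),
                class = "strawsim_config_error")
  }
  get <- function(key, default) if (is.null(raw[[key]])) default else raw[[key]]
  config_from_values(
    lambda_visits = get("lambda_visits", 4.5),
    grains_per_visit = get("grains_per_visit", 25),
    bloom_days = get("bloom_days", 5),
    compatibility = get("compatibility", 0.8),
    decay_coeff = get("decay_coeff", 0.01),
    decay_power = get("decay_power", 3.6),
    slope = get("slope", 0.05),
    intercept = get("intercept", 2.0),
    bias_sd = get("bias_sd", 3.09),
    marketable_threshold = get("marketable_threshold", 10),
    n_flowers = get("n_flowers", 10000),
    seed = get("seed", NULL)
  )
}

config_from_values <- function(lambda_visits, grains_per_visit, bloom_days,
                               compatibility, decay_coeff, decay_power,
                               slope, intercept, bias_sd,
                               marketable_threshold, n_flowers, seed) {
  simulation_config(
    visit = visit_model(lambda_visits, grains_per_visit, bloom_days),
    fert = fertilization_model(compatibility, decay_coeff, decay_power),
    growth = growth_model(slope, intercept, bias_sd, marketable_threshold),
    n_flowers = n_flowers, seed = seed
  )
}

#' Write the per-flower cohort table as CSV
#'
#' One row per flower with columns `flower_id`, daily visits `x1..`,
#' daily pollen `y1..`, daily fertilized grains `z1..`, `z_sum`, `weight`
#' (grams, 6 decimals — sub-milligram, so the rounding is biologically
#' lossless and the file is byte-reproducible), and `marketable`.
#'
#' @param result A `cohort_result` from [run_cohort()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort_csv <- function(result, path) {
  stopifnot(inherits(result, "cohort_result"))
  df <- result$records
  df$weight <- round(df$weight, 6)
  tryCatch(
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE),
    error = function(e) {
      stop_domain(sprintf("cannot write cohort CSV to '%s': %s", path,
                          conditionMessage(e)), class = "strawsim_io_error")
    }
  )
  invisible(path)
}

#' Write the cohort summary as JSON
#'
#' Serialises the summary block (per-variable mean/sd/skewness/SE/z,
#' marketable fraction, nonpositive-weight count, config echo and seed),
#' optionally with normal and 3-parameter lognormal fit blocks for the
#' weight column.
#'
#' @param result A `cohort_result` from [run_cohort()].
#' @param path Output file path.
#' @param fits Include `fit_normal`/`fit_lognormal3` blocks? (default TRUE)
#' @return `path`, invisibly.
#' @export
write_summary_json <- function(result, path, fits = TRUE) {
  stopifnot(inherits(result, "cohort_result"))
  out <- result$summary
  if (isTRUE(fits)) {
    out$fits <- list(
      normal = unclass(fit_normal(result$records$weight)),
      lognormal3 = unclass(fit_lognormal3(result$records$weight))
    )
  }
  tryCatch(
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = 10,
                         null = "null"),
    error = function(e) {
      stop_domain(sprintf("cannot write summary JSON to '%s': %s", path,
                          conditionMessage(e)), class = "strawsim_io_error")
    }
  )
  invisible(path)
}

#' Generate a pseudo-empirical weight sample
#'
#' Draws `n` fruit weights from the default generative model under an
#' independent seed and writes them as a one-column CSV (`weight`, grams,
#' 6 decimals). This is a synthetic stand-in for observed greenhouse
#' weights, intended for exercising [ks_two_sample()]; it shares the
#' simulator's idealisations and is not field data.
#'
#' @param n Number of weights, >= 1.
#' @param seed Integer seed.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
generate_pseudo_empirical <- function(n, seed, path) {
  check_number(n, "n", lower = 1, integer = TRUE)
  check_number(seed, "seed", integer = TRUE)
  res <- run_cohort(simulation_config(n_flowers = n, seed = seed))
  df <- data.frame(weight = round(res$records$weight, 6))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
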