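# Cohort runner: the full per-flower pipeline for N flowers, the per-flower
# table, summary statistics, and the closed-form moment oracle.

#' Simulate a cohort of flowers
#'
#' Runs the full pipeline for every flower in the configured cohort: daily
#' Poisson bee visits over the bloom, fixed pollen deposition per visit,
#' day-by-day binomial fertilization under decaying stigma receptivity,
#' accumulation into the achene total, and one Gaussian-residual weight
#' draw. Flowers are independent; a single RNG stream seeded from
#' `config$seed` makes the whole cohort reproducible (same config + seed,
#' identical table).
#'
#' @param config A [simulation_config()].
#' @return A list of class `cohort_result` with:
#'   \describe{
#'     \item{records}{data.frame, one row per flower: `flower_id`,
#'       `x1..x<d>` daily visits, `y1..y<d>` daily pollen, `z1..z<d>` daily
#'       fertilized grains, `z_sum` achene total, `weight` grams,
#'       `marketable`.}
#'     \item{summary}{per-variable mean/sd/skewness/SE/z for `z_sum` and
#'       `weight`, the marketable fraction, the count of nonpositive
#'       weights, and the config echo.}
#'   }
#' @examples
#' res <- run_cohort(simulation_config(seed = 1, n_flowers = 200))
#' res$summary$weight$mean
#' @export
run_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n_flowers
  d <- config$visit$bloom_days

  visits <- sample_visits(config$visit, n = n)
  pollen <- deposit_pollen(visits, config$visit$grains_per_visit)
  probs <- fertilization_prob(seq_len(d), config$fert)
  fert <- matrix(0L, nrow = n, ncol = d)
  for (j in seq_len(d)) {
    fert[, j] <- sample_fertilized(pollen[, j], probs[j])
  }
  z_sum <- rowSums(fert)
  weight <- fruit_weight(z_sum, config$growth)
  marketable <- is_marketable(weight, config$growth$marketable_threshold)

  records <- data.frame(
    flower_id = seq_len(n),
    visits, pollen, fert,
    z_sum = z_sum, weight = weight, marketable = marketable
  )
  names(records) <- c("flower_id", paste0("x", seq_len(d)),
                      paste0("y", seq_len(d)), paste0("z", seq_len(d)),
                      "z_sum", "weight", "marketable")

  summarise_var <- function(v) {
    # constant variables (e.g. z_sum when compatibility = 0) have no skewness
    sk <- if (stats::var(v) > 0) {
      skewness_report(v)
    } else {
      list(skewness = NA_real_,
           se_skewness = sqrt(6 * n * (n - 1) / ((n - 2) * (n + 1) * (n + 3))),
           z_score = NA_real_)
    }
    list(mean = mean(v), sd = stats::sd(v), skewness = sk$skewness,
         se_skewness = sk$se_skewness, skewness_z = sk$z_score)
  }
  summary <- list(
    n_flowers = n,
    z_sum = summarise_var(z_sum),
    weight = summarise_var(weight),
    marketable_fraction = mean(marketable),
    n_nonpositive_weight = sum(weight <= 0),
    seed = config$seed,
    config = list(
      lambda_visits = config$visit$lambda_visits,
      grains_per_visit = config$visit$grains_per_visit,
      bloom_days = config$visit$bloom_days,
      compatibility = config$fert$compatibility,
      decay_coeff = config$fert$decay_coeff,
      decay_power = config$fert$decay_power,
      slope = config$growth$slope,
      intercept = config$growth$intercept,
      bias_sd = config$growth$bias_sd,
      marketable_threshold = config$growth$marketable_threshold
    )
  )
  structure(list(records = records, summary = summary),
            class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Cohort of %d flowers (seed %s)\n", s$n_flowers,
              if (is.null(s$seed)) "<none>" else s$seed))
  cat(sprintf("  achene total: mean %.2f, sd %.2f, skewness %.3f (z %.1f)\n",
              s$z_sum$mean, s$z_sum$sd, s$z_sum$skewness, s$z_sum$skewness_z))
  cat(sprintf("  weight:       mean %.2f g, sd %.2f g, skewness %.3f (z %.1f)\n",
              s$weight$mean, s$weight$sd, s$weight$skewness,
              s$weight$skewness_z))
  cat(sprintf("  marketable fraction (> %g g): %.3f\n",
              s$config$marketable_threshold, s$marketable_fraction))
  if (s$n_nonpositive_weight > 0) {
    cat(sprintf("  note: %d nonpositive weight(s) (unbounded residual)\n",
                s$n_nonpositive_weight))
  }
  invisible(x)
}

#' Closed-form moments of the simulated variables
#'
#' Analytic means and variances under the configured model, used as an
#' independent oracle for Monte Carlo runs. Per day `n` with fertilization
#' probability `p_n`: `E[Y_n] = g*lambda`, `Var(Y_n) = g^2*lambda`,
#' `E[Z_n] = g*lambda*p_n`, and by the law of total variance
#' `Var(Z_n) = E[Y_n] p_n (1 - p_n) + p_n^2 Var(Y_n)`. Days are
#' independent, so the achene-total moments are sums; the weight moments
#' follow from the affine map plus the independent residual.
#'
#' @param config A [simulation_config()].
#' @return A list with per-day vectors `mean_pollen`, `var_pollen`,
#'   `mean_fertilized`, `var_fertilized` and scalars `mean_zsum`,
#'   `var_zsum`, `mean_weight`, `var_weight`.
#' @examples
#' expected_summaries(simulation_config())$mean_zsum   # ~246.3
#' @export
expected_summaries <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  g <- config$visit$grains_per_visit
  lam <- config$visit$lambda_visits
  p <- fertilization_prob(seq_len(config$visit$bloom_days), config$fert)
  mean_y <- rep(g * lam, length(p))
  var_y <- rep(g^2 * lam, length(p))
  mean_z <- mean_y * p
  var_z <- mean_y * p * (1 - p) + p^2 * var_y
  mean_zsum <- sum(mean_z)
  var_zsum <- sum(var_z)
  list(
    mean_pollen = mean_y, var_pollen = var_y,
    mean_fertilized = mean_z, var_fertilized = var_z,
    mean_zsum = mean_zsum, var_zsum = var_zsum,
    mean_weight = config$growth$slope * mean_zsum + config$growth$intercept,
    var_weight = config$growth$slope^2 * var_zsum + config$growth$bias_sd^2
  )
}
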