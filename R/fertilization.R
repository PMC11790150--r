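# Age-dependent fertilization: receptivity decay, compatibility, binomial
# thinning of deposited pollen, accumulation over the bloom, and an exact
# convolution pmf of the achene total used as an independent oracle.

#' Stigma receptivity on a given bloom day
#'
#' Receptivity decays with flower age `n` (days, 1-based) as
#' `exp(-decay_coeff * n^decay_power)`: near 1 on the first day, nearly 0 by
#' day 5 under defaults.
#'
#' @param day Flower age in days, integer >= 1 (vectorised).
#' @param model A [fertilization_model()].
#' @return Receptivity probability in (0, 1].
#' @examples
#' stigma_receptivity(1:5, fertilization_model())
#' @export
stigma_receptivity <- function(day, model = fertilization_model()) {
  stopifnot(inherits(model, "fertilization_model"))
  if (!is.numeric(day) || any(!is.finite(day)) || any(day < 1) ||
      any(day != round(day))) {
    stop_domain("'day' must be integer(s) >= 1 (flower age in days)")
  }
  exp(-model$decay_coeff * day^model$decay_power)
}

#' Per-grain fertilization probability on a given bloom day
#'
#' The product of self-pollen compatibility and stigma receptivity: a
#' deposited grain fertilizes an ovule with probability
#' `compatibility * exp(-decay_coeff * day^decay_power)`.
#'
#' @inheritParams stigma_receptivity
#' @return Fertilization probability, at most the receptivity.
#' @examples
#' fertilization_prob(1:5, fertilization_model())
#' @export
fertilization_prob <- function(day, model = fertilization_model()) {
  model$compatibility * stigma_receptivity(day, model)
}

#' Sample the number of fertilized grains for one flower-day
#'
#' Binomial thinning of the day's deposited pollen: each grain independently
#' fertilizes with the day's fertilization probability.
#'
#' @param pollen Non-negative grain count(s) deposited that day.
#' @param prob Per-grain fertilization probability in \[0, 1\] (scalar or
#'   one per element of `pollen`).
#' @return Fertilized grain count(s), never exceeding `pollen`.
#' @export
sample_fertilized <- function(pollen, prob) {
  if (!is.numeric(pollen) || any(!is.finite(pollen)) || any(pollen < 0) ||
      any(pollen != round(pollen))) {
    stop_domain("'pollen' must be non-negative integer(s)")
  }
  if (!is.numeric(prob) || any(!is.finite(prob)) || any(prob < 0) ||
      any(prob > 1)) {
    stop_domain("'prob' must be probabilit(ies) in [0, 1]")
  }
  stats::rbinom(length(pollen), size = pollen, prob = prob)
}

#' Total achenes from daily fertilized counts
#'
#' Sums the fertilized grains over the bloom; each fertilized ovule matures
#' into one achene, so the sum is the flower's achene count.
#'
#' @param daily_fertilized Non-negative counts, one per bloom day.
#' @return The achene total.
#' @examples
#' accumulate_achenes(c(60, 55, 40, 15, 1))
#' @export
accumulate_achenes <- function(daily_fertilized) {
  if (length(daily_fertilized) == 0L) {
    stop_domain("'daily_fertilized' must be non-empty")
  }
  if (!is.numeric(daily_fertilized) || any(!is.finite(daily_fertilized)) ||
      any(daily_fertilized < 0)) {
    stop_domain("'daily_fertilized' must be non-negative")
  }
  sum(daily_fertilized)
}

#' Exact distribution of the achene total (convolution oracle)
#'
#' Computes the exact pmf of the bloom-long fertilized total without any
#' sampling, for small parameter settings: the daily pollen pmf is the
#' Poisson visit pmf placed on multiples of `grains_per_visit`, each daily
#' pmf is binomially thinned by that day's fertilization probability, and
#' the daily pmfs are convolved across the bloom. Intended as an
#' independent check on the Monte Carlo pipeline; the support grows as
#' `bloom_days * grains_per_visit * qpois(1 - eps, lambda)` and the
#' function refuses settings where it would exceed `max_support`.
#'
#' @param visit A [visit_model()] with small `lambda_visits` and
#'   `grains_per_visit` (e.g. lambda <= 2, grains <= 5).
#' @param fert A [fertilization_model()].
#' @param max_support Largest admissible support size (default 5000).
#' @return Numeric vector `p` with `p[k + 1] = P(Z_sum = k)`, summing to
#'   1 within 1e-8.
#' @examples
#' pmf <- exact_zsum_pmf(visit_model(lambda_visits = 0.5, grains_per_visit = 2))
#' sum(pmf * (seq_along(pmf) - 1))  # exact mean achene count
#' @export
exact_zsum_pmf <- function(visit, fert = fertilization_model(),
                           max_support = 5000L) {
  stopifnot(inherits(visit, "visit_model"),
            inherits(fert, "fertilization_model"))
  g <- visit$grains_per_visit
  kmax <- stats::qpois(1 - 1e-14, visit$lambda_visits)
  day_max <- kmax * g
  if ((day_max + 1) * visit$bloom_days > max_support) {
    stop_domain(paste0(
      "support too large (", (day_max + 1) * visit$bloom_days,
      " states); use smaller lambda_visits/grains_per_visit or raise",
      " max_support"))
  }
  # pmf of daily pollen Y on 0..day_max (mass only on multiples of g)
  y_pmf <- numeric(day_max + 1)
  y_pmf[seq(0, kmax) * g + 1] <- stats::dpois(seq(0, kmax),
                                              visit$lambda_visits)
  probs <- fertilization_prob(seq_len(visit$bloom_days), fert)
  total <- 1
  for (p in probs) {
    # binomial thinning of the daily pollen pmf
    z_pmf <- numeric(day_max + 1)
    for (y in which(y_pmf > 0) - 1) {
      z_pmf[0:y + 1] <- z_pmf[0:y + 1] +
        y_pmf[y + 1] * stats::dbinom(0:y, size = y, prob = p)
    }
    # convolve into the running total
    new_total <- numeric(length(total) + length(z_pmf) - 1)
    for (z in which(z_pmf > 0) - 1) {
      idx <- seq_along(total) + z
      new_total[idx] <- new_total[idx] + total * z_pmf[z + 1]
    }
    total <- new_total
  }
  if (abs(sum(total) - 1) > 1e-8) {
    stop_domain("convolution pmf lost mass; parameters too large")
  }
  total
}
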