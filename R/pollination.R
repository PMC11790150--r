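# Daily bee visitation and pollen deposition for one flower.

#' Probability mass of k bee visits in one day
#'
#' Daily visits to a flower follow a Poisson distribution with mean
#' `lambda_visits`, so `P(X = k) = lambda^k e^(-lambda) / k!`.
#'
#' @param k Non-negative integer visit count (vectorised).
#' @param lambda_visits Mean visits per flower per day; must be positive.
#' @return Probability of exactly `k` visits.
#' @examples
#' visit_pmf(4, 4.5)   # the modal daily visit count under defaults
#' @export
visit_pmf <- function(k, lambda_visits) {
  if (!is.numeric(lambda_visits) || length(lambda_visits) != 1L ||
      !is.finite(lambda_visits) || lambda_visits <= 0) {
    stop_domain("'lambda_visits' must be a single positive number")
  }
  if (!is.numeric(k) || any(!is.finite(k)) || any(k < 0) ||
      any(k != round(k))) {
    stop_domain("'k' must be non-negative integer(s)")
  }
  stats::dpois(k, lambda_visits)
}

#' Sample daily visit counts over a flower's bloom
#'
#' Draws one Poisson visit count per bloom day; each day shares the same
#' marginal distribution and days are independent.
#'
#' @param model A [visit_model()].
#' @param n Number of flowers to draw (default 1).
#' @return An `n` x `bloom_days` integer matrix of visit counts.
#' @export
sample_visits <- function(model, n = 1L) {
  stopifnot(inherits(model, "visit_model"))
  check_number(n, "n", lower = 1, integer = TRUE)
  matrix(stats::rpois(n * model$bloom_days, model$lambda_visits),
         nrow = n, ncol = model$bloom_days)
}

#' Pollen grains deposited by a day's visits
#'
#' Each visit deposits a fixed number of viable grains, so daily pollen is
#' `grains_per_visit * visits`.
#'
#' @param visits Non-negative visit count(s).
#' @param grains_per_visit Grains deposited per visit.
#' @return Pollen grain count(s), divisible by `grains_per_visit`.
#' @examples
#' deposit_pollen(4, 25)  # 100
#' @export
deposit_pollen <- function(visits, grains_per_visit) {
  if (!is.numeric(visits) || any(!is.finite(visits)) || any(visits < 0)) {
    stop_domain("'visits' must be non-negative")
  }
  check_number(grains_per_visit, "grains_per_visit", lower = 1,
               integer = TRUE)
  grains_per_visit * visits
}
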