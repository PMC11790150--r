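# Achene count -> fruit weight, marketability, and the closed-form
# marketable fraction under a normal weight approximation.

#' Fruit weight from achene count
#'
#' `W = slope * achenes + intercept + Bias` with `Bias ~ N(0, bias_sd^2)`.
#' The residual is unbounded, so slightly negative weights are possible
#' (probability ~0.06% under defaults) and are deliberately not clamped;
#' cohort summaries report how many occurred.
#'
#' @param achenes Non-negative achene count(s).
#' @param model A [growth_model()].
#' @return Fruit weight(s) in grams; deterministic affine when
#'   `bias_sd = 0`.
#' @examples
#' fruit_weight(160, growth_model(bias_sd = 0))  # exactly 10 g
#' @export
fruit_weight <- function(achenes, model = growth_model()) {
  stopifnot(inherits(model, "growth_model"))
  if (!is.numeric(achenes) || any(!is.finite(achenes)) || any(achenes < 0)) {
    stop_domain("'achenes' must be non-negative")
  }
  bias <- if (model$bias_sd > 0) {
    stats::rnorm(length(achenes), 0, model$bias_sd)
  } else {
    0
  }
  model$slope * achenes + model$intercept + bias
}

#' Is a fruit marketable?
#'
#' Marketable fruits must weigh strictly more than the threshold ("over
#' 10 g"); a fruit at exactly the threshold is not marketable.
#'
#' @param weight Weight(s) in grams.
#' @param threshold Threshold in grams (default 10).
#' @return Logical.
#' @examples
#' is_marketable(c(10, 10.01), 10)
#' @export
is_marketable <- function(weight, threshold = 10) {
  weight > threshold
}

#' Marketable fraction under a normal weight approximation
#'
#' For fruit weight approximated by `N(mean, sd^2)`, the marketable
#' fraction is `1 - pnorm((threshold - mean) / sd)`. With
#' `round_z = TRUE` the standardized score is rounded to two decimals
#' before evaluating the normal CDF, matching the hand arithmetic commonly
#' used with printed summary tables (e.g. `1 - pnorm(-0.97) = 0.834` for
#' mean 14.3, sd 4.42, threshold 10).
#'
#' @param mean Mean weight in grams.
#' @param sd Weight standard deviation in grams; must be positive.
#' @param threshold Marketability threshold in grams (default 10).
#' @param round_z Round the z score to two decimals first? (default FALSE)
#' @return Probability that a fruit exceeds the threshold.
#' @examples
#' marketable_fraction_normal(14.3, 4.42, 10, round_z = TRUE)   # 0.834
#' marketable_fraction_normal(14.3, 4.42, 10)                   # 0.8347
#' @export
marketable_fraction_normal <- function(mean, sd, threshold = 10,
                                       round_z = FALSE) {
  check_number(mean, "mean")
  check_number(threshold, "threshold")
  if (!is.numeric(sd) || length(sd) != 1L || !is.finite(sd) || sd <= 0) {
    stop_domain("'sd' must be a single positive number")
  }
  z <- (threshold - mean) / sd
  if (isTRUE(round_z)) z <- round(z, 2)
  1 - stats::pnorm(z)
}
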