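#' Monte Carlo simulation of damage variability
#'
#' Draws `n` normally distributed damage values about a mean and standard
#' deviation and estimates the probability of failure as the fraction of
#' draws at or above the failure threshold (`D = 1` is total failure).
#' Draws below zero are kept by default: the model is a plain normal, and
#' truncation is opt-in.
#'
#' @param mean Mean damage of the distribution.
#' @param sd Standard deviation (>= 0).
#' @param n Number of draws (default 200).
#' @param seed Integer RNG seed; required for reproducibility.
#' @param threshold Failure threshold on the damage scale (default 1).
#' @param truncate_at_zero If `TRUE`, negative draws are replaced by 0.
#' @return An object of class `damage_sample`: a list with `values`,
#'   `mean`, `sd`, `variance`, `p_failure`, `n`, `seed`, `threshold`.
#'   Summary statistics use the sample (n - 1) convention.
#' @examples
#' mc <- monte_carlo_damage(0.333299, 0.393134, n = 200, seed = 42)
#' mc$p_failure
#' @export
monte_carlo_damage <- function(mean, sd, n = 200, seed = 1, threshold = 1,
                               truncate_at_zero = FALSE) {
  if (sd < 0) abort("`sd` must be nonnegative.")
  if (n < 1) abort("`n` must be at least 1.")
  values <- withr::with_seed(seed, rnorm(n, mean, sd))
  if (truncate_at_zero) values <- pmax(values, 0)
  s <- summarize_damage(values_or_na(values))
  structure(
    list(
      values = values,
      mean = s$mean, sd = s$sd, variance = s$variance,
      p_failure = mean(values >= threshold),
      n = n, seed = seed, threshold = threshold
    ),
    class = "damage_sample"
  )
}

values_or_na <- function(v) if (length(v) >= 2) v else c(v, v)

#' Sample summary statistics of damage draws
#'
#' Sample mean, standard deviation and variance (`variance = sd^2`,
#' n - 1 convention) of a set of damage values.
#'
#' @param values Numeric vector with at least 2 elements.
#' @return One-row tibble: `mean`, `sd`, `variance`, `n`.
#' @examples
#' summarize_damage(c(0, 2))
#' @export
summarize_damage <- function(values) {
  if (!is.numeric(values) || length(values) < 2) {
    abort("`values` must be numeric with at least 2 elements.")
  }
  s <- sd(values)
  tibble::tibble(mean = mean(values), sd = s, variance = s^2,
                 n = length(values))
}

#' Closed-form normal probability of failure
#'
#' Tail probability `P(D >= threshold)` under the fitted normal model,
#' `1 - pnorm((threshold - mean) / sd)`. Useful as an analytic check on
#' the Monte Carlo estimate.
#'
#' @inheritParams monte_carlo_damage
#' @return Scalar probability.
#' @export
normal_failure_probability <- function(mean, sd, threshold = 1) {
  if (sd < 0) abort("`sd` must be nonnegative.")
  if (sd == 0) return(as.numeric(mean >= threshold))
  1 - pnorm((threshold - mean) / sd)
}
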