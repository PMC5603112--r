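#' Tidiers and plots for fitted fatigue objects
#'
#' Broom-style methods: `tidy()` returns per-term estimates, `glance()` a
#' one-row model summary, and `autoplot()` a ggplot of the object.
#'
#' @param x,object A fitted object (`sn_fit`, `damage_curve`,
#'   `damage_sample`, `force_trace`, `cycle_spectrum`).
#' @param ... Unused.
#' @return `tidy()` and `glance()` return tibbles; `autoplot()` returns a
#'   ggplot object.
#' @name tidiers
NULL

#' @rdname tidiers
#' @method tidy sn_fit
#' @export
tidy.sn_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = c("intercept", "log(n_f)"),
    estimate = s[, 1],
    std.error = s[, 2],
    statistic = s[, 3],
    p.value = s[, 4]
  )
}

#' @rdname tidiers
#' @method glance sn_fit
#' @export
glance.sn_fit <- function(x, ...) {
  tibble::tibble(
    r.squared = x$r_squared,
    slope = x$slope,
    intercept = x$intercept,
    nobs = x$n
  )
}

#' @rdname tidiers
#' @method tidy damage_curve
#' @export
tidy.damage_curve <- function(x, ...) {
  tibble::tibble(
    term = paste0("b^", seq_along(x$coefficients) - 1),
    estimate = x$coefficients
  )
}

#' @rdname tidiers
#' @method glance damage_curve
#' @export
glance.damage_curve <- function(x, ...) {
  tibble::tibble(
    zone = x$zone,
    degree = x$degree,
    r.squared = x$r_squared
  )
}

#' @rdname tidiers
#' @method tidy damage_sample
#' @export
tidy.damage_sample <- function(x, ...) {
  tibble::tibble(draw = seq_along(x$values), value = x$values)
}

#' @rdname tidiers
#' @method glance damage_sample
#' @export
glance.damage_sample <- function(x, ...) {
  tibble::tibble(
    mean = x$mean, sd = x$sd, variance = x$variance,
    p_failure = x$p_failure, n = x$n, seed = x$seed,
    threshold = x$threshold
  )
}

#' @rdname tidiers
#' @method print sn_fit
#' @export
print.sn_fit <- function(x, ...) {
  cat("Log-linear S-N fit: sigma_max =",
      sprintf("%.3f ln(N_f) + %.3f", x$slope, x$intercept),
      sprintf("(R^2 = %.3f, n = %d)\n", x$r_squared, x$n))
  invisible(x)
}

#' @rdname tidiers
#' @method print damage_curve
#' @export
print.damage_curve <- function(x, ...) {
  terms <- sprintf("%.4g B^%d", x$coefficients, seq_along(x$coefficients) - 1)
  cat("Damage-growth curve (", x$zone, "): A = ",
      paste(terms, collapse = " + "),
      sprintf(" (R^2 = %.3f)\n", x$r_squared), sep = "")
  invisible(x)
}

#' @rdname tidiers
#' @method print damage_sample
#' @export
print.damage_sample <- function(x, ...) {
  cat(sprintf(
    "Monte Carlo damage sample: n = %d, mean = %.4f, sd = %.4f, P(D >= %.2f) = %.4f\n",
    x$n, x$mean, x$sd, x$threshold, x$p_failure
  ))
  invisible(x)
}

#' @rdname tidiers
#' @method autoplot force_trace
#' @export
autoplot.force_trace <- function(object, ...) {
  long <- tidyr::pivot_longer(object, c("fx", "fy", "fz"),
                              names_to = "component", values_to = "force")
  ggplot2::ggplot(long, ggplot2::aes(.data$time, .data$force,
                                     colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "force (N)",
                  title = "Hip-contact force history")
}

#' @rdname tidiers
#' @method autoplot cycle_spectrum
#' @export
autoplot.cycle_spectrum <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$mean, .data$range,
                                       size = .data$count)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "cycle mean", y = "cycle range",
                  title = "Rainflow cycle spectrum")
}

#' @rdname tidiers
#' @method autoplot sn_fit
#' @export
autoplot.sn_fit <- function(object, ...) {
  d <- object$fit$model
  names(d) <- c("sigma_max", "log_nf")
  ggplot2::ggplot(d, ggplot2::aes(exp(.data$log_nf), .data$sigma_max)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(ggplot2::aes(y = predict(object$fit)), colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cycles to failure", y = "maximum stress",
                  title = "S-N curve")
}

#' @rdname tidiers
#' @method autoplot damage_curve
#' @export
autoplot.damage_curve <- function(object, ...) {
  b <- seq(0, 1, length.out = 201)
  d <- tibble::tibble(b = b, a = eval_damage_curve(object, b))
  ggplot2::ggplot(d, ggplot2::aes(.data$b, .data$a)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "cycle fraction n/Nf", y = "damage",
                  title = paste("Damage-growth curve:", object$zone))
}

#' Plot damage-curve samples with fitted stage boundaries
#'
#' @param data Data frame of `(b, a)` damage-curve samples.
#' @param stages A one-row tibble from [classify_stages()].
#' @param b,a Column names.
#' @return A ggplot object.
#' @export
plot_stages <- function(data, stages, b = "b", a = "a") {
  check_columns(data, c(b, a))
  ggplot2::ggplot(data, ggplot2::aes(.data[[b]], .data[[a]])) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(stages$lower, stages$upper),
                        linetype = "dashed", colour = "red") +
    ggplot2::labs(x = "cycle fraction n/Nf", y = "damage",
                  title = "Three-stage damage growth")
}
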