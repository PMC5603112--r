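#' Strain-life fatigue properties
#'
#' Parameters of the Coffin-Manson strain-life law. The defaults are the
#' literature values used for bone tissue: fatigue strength coefficient
#' `sigma_f_prime = 6` (same stress unit as the stiffness tensor, GPa by
#' convention), fatigue ductility coefficient `eps_f_prime = 0.352`, and
#' the universal-slopes exponents `b = -0.12`, `c = -0.6` which stand in
#' for material-specific exponents when no fatigue test data exist.
#'
#' @param sigma_f_prime Fatigue strength coefficient (> 0).
#' @param eps_f_prime Fatigue ductility coefficient (> 0).
#' @param b Fatigue strength exponent (< 0).
#' @param c Fatigue ductility exponent (< 0).
#' @return A one-row tibble of class `fatigue_properties`.
#' @export
fatigue_properties <- function(sigma_f_prime = 6, eps_f_prime = 0.352,
                               b = -0.12, c = -0.6) {
  if (sigma_f_prime <= 0 || eps_f_prime <= 0) {
    abort("`sigma_f_prime` and `eps_f_prime` must be positive.")
  }
  if (b >= 0 || c >= 0) abort("`b` and `c` must be negative.")
  out <- tibble::tibble(
    sigma_f_prime = sigma_f_prime, eps_f_prime = eps_f_prime, b = b, c = c
  )
  class(out) <- c("fatigue_properties", class(out))
  out
}

#' Mean stress and stress amplitude of a load cycle
#'
#' `sigma_m = (sigma_max + sigma_min) / 2`,
#' `sigma_a = (sigma_max - sigma_min) / 2`.
#'
#' @param sigma_max,sigma_min Cycle extremes; `sigma_max >= sigma_min`
#'   elementwise.
#' @return Tibble with columns `sigma_m` and `sigma_a`.
#' @examples
#' mean_and_amplitude(100, -100)  # fully reversed cycle
#' @export
mean_and_amplitude <- function(sigma_max, sigma_min) {
  if (any(sigma_max < sigma_min)) {
    abort("`sigma_max` must be >= `sigma_min`.")
  }
  tibble::tibble(
    sigma_m = (sigma_max + sigma_min) / 2,
    sigma_a = (sigma_max - sigma_min) / 2
  )
}

#' Mean-stress-corrected strain-life relation
#'
#' Total strain amplitude at a given life: the elastic term
#' `(sigma_f' - sigma_m) / E * (2 Nf)^b` plus the plastic term
#' `eps_f' * ((sigma_f' - sigma_m) / sigma_f')^(c/b) * (2 Nf)^c`.
#' With the universal slopes `b = -0.12`, `c = -0.6` the mean-stress
#' knockdown exponent `c/b` equals exactly 5. At `sigma_m = 0` the
#' expression reduces to the plain Coffin-Manson law. For user-supplied
#' exponents the knockdown keeps the general `c/b` form.
#'
#' @param n_f Cycles to failure (vectorised, >= 1).
#' @param props A [fatigue_properties()] row.
#' @param sigma_m Mean stress, same unit as `sigma_f_prime`; must be
#'   below `sigma_f_prime`.
#' @param elastic_modulus Elastic modulus in the same stress unit.
#' @return Numeric vector of total strain amplitudes (dimensionless).
#' @export
strain_life <- function(n_f, props = fatigue_properties(), sigma_m = 0,
                        elastic_modulus) {
  stopifnot(inherits(props, "fatigue_properties"))
  if (any(n_f < 1)) abort("`n_f` must be >= 1.")
  if (any(sigma_m >= props$sigma_f_prime)) {
    abort("`sigma_m` must be below `sigma_f_prime` (negative effective strength).")
  }
  if (elastic_modulus <= 0) abort("`elastic_modulus` must be positive.")
  eff <- props$sigma_f_prime - sigma_m
  eff / elastic_modulus * (2 * n_f)^props$b +
    props$eps_f_prime * (eff / props$sigma_f_prime)^(props$c / props$b) *
      (2 * n_f)^props$c
}

#' Invert the strain-life relation for cycles to failure
#'
#' Finds the unique `Nf` with `strain_life(Nf) = strain_amplitude`. The
#' strain-life curve is strictly decreasing in `Nf` for negative `b` and
#' `c`, so a bracketing root search on `log(Nf)` over `[1, 1e12]` suffices
#' (relative tolerance 1e-9).
#'
#' @inheritParams strain_life
#' @param strain_amplitude Target total strain amplitude (> 0);
#'   vectorised.
#' @return Numeric vector of cycles to failure.
#' @export
solve_life <- function(strain_amplitude, props = fatigue_properties(),
                       sigma_m = 0, elastic_modulus) {
  if (any(strain_amplitude <= 0)) abort("`strain_amplitude` must be positive.")
  lo <- 1; hi <- 1e12
  eps_hi <- strain_life(1, props, sigma_m, elastic_modulus)
  eps_lo <- strain_life(hi, props, sigma_m, elastic_modulus)
  vapply(strain_amplitude, function(target) {
    if (target > eps_hi || target < eps_lo) {
      abort(sprintf(
        "Strain amplitude %.4g is outside the invertible range [%.4g, %.4g].",
        target, eps_lo, eps_hi
      ))
    }
    f <- function(logn) {
      strain_life(exp(logn), props, sigma_m, elastic_modulus) - target
    }
    exp(uniroot(f, c(log(lo), log(hi)), tol = 1e-9 * log(hi))$root)
  }, numeric(1))
}

#' Miner's-rule damage accumulation over a cycle spectrum
#'
#' Linear damage summation `D = sum_i n_i / N_fi` over the blocks of a
#' scaled cycle spectrum. The raw sum is reported alongside a value
#' clamped at 1 and a `failed` flag (`D >= 1` means total failure).
#'
#' @param spectrum A scaled `cycle_spectrum` with an `n` column (see
#'   [scale_spectrum()]).
#' @param life Either the name of a column holding cycles to failure per
#'   block, or a function taking the spectrum tibble and returning a
#'   numeric vector of `N_f` values.
#' @return One-row tibble: `damage_raw`, `damage` (clamped at 1),
#'   `failed`, `n_blocks`.
#' @export
miner_damage <- function(spectrum, life = "n_f") {
  check_columns(spectrum, "n")
  n_f <- if (is.function(life)) life(spectrum) else {
    check_columns(spectrum, life)
    spectrum[[life]]
  }
  if (length(n_f) != nrow(spectrum)) {
    abort("`life` must yield one N_f per spectrum block.")
  }
  if (any(!is.finite(n_f)) || any(n_f <= 0)) {
    abort("All cycles-to-failure must be positive and finite.")
  }
  d <- sum(spectrum$n / n_f)
  tibble::tibble(
    damage_raw = d,
    damage = min(d, 1),
    failed = d >= 1,
    n_blocks = nrow(spectrum)
  )
}

#' Scalar damage from the stress-strain state
#'
#' Continuum-damage identity `D = (C eps - sigma) / (C eps)`, evaluated on
#' one Voigt component of the elastic stress prediction `C eps`. By
#' default the work-conjugate pair of the largest-magnitude strain
#' component is used; a component index (1-6, Voigt order) can be forced.
#'
#' @param stiffness A `stiffness_matrix`.
#' @param strain Length-6 Voigt strain vector.
#' @param stress Length-6 Voigt stress vector (observed, degraded).
#' @param component Optional Voigt component index to evaluate on.
#' @return One-row tibble: `component`, `damage_raw`, `damage` (clipped to
#'   `[0, 1]`), `in_range`.
#' @export
damage_from_state <- function(stiffness, strain, stress, component = NULL) {
  stopifnot(inherits(stiffness, "stiffness_matrix"),
            length(strain) == 6, length(stress) == 6)
  elastic <- as.numeric(unclass(stiffness) %*% strain)
  k <- component %||% which.max(abs(strain))
  if (elastic[k] == 0) {
    abort("Damage is undefined: the elastic stress prediction is zero.")
  }
  d <- (elastic[k] - stress[k]) / elastic[k]
  tibble::tibble(
    component = k,
    damage_raw = d,
    damage = min(max(d, 0), 1),
    in_range = d >= 0 && d <= 1
  )
}

#' Stress carried by a damaged material
#'
#' Damage-degraded constitutive law `sigma = (1 - D) C eps`.
#'
#' @param d Scalar damage in `[0, 1]`.
#' @param stiffness A `stiffness_matrix`.
#' @param strain Length-6 Voigt strain vector.
#' @return Tibble with columns `component` and `stress`.
#' @export
degraded_stress <- function(d, stiffness, strain) {
  stopifnot(inherits(stiffness, "stiffness_matrix"), length(strain) == 6)
  if (d < 0 || d > 1) abort("`d` must lie in [0, 1].")
  tibble::tibble(
    component = c("11", "22", "33", "12", "13", "23"),
    stress = (1 - d) * as.numeric(unclass(stiffness) %*% strain)
  )
}

# ---- damage-growth curves -------------------------------------------------

#' Damage-growth polynomial curves
#'
#' A damage-growth curve expresses accumulated damage `A` as a polynomial
#' in the cycle fraction `B = n / N_f`. `damage_curve()` wraps a
#' coefficient vector; `reference_damage_curves()` returns the three
#' published bone models (cortical quintic, composite cubic, trabecular
#' quartic) fitted to whole-femur finite element damage data;
#' `eval_damage_curve()` evaluates a curve.
#'
#' @param coefficients Numeric polynomial coefficients, ascending in `B`
#'   (constant term first).
#' @param zone Label: `"cortical"`, `"trabecular"` or `"composite"`.
#' @param r_squared Optional goodness of fit.
#' @return `damage_curve()`: an object of class `damage_curve`.
#'   `reference_damage_curves()`: a named list of three `damage_curve`
#'   objects.
#' @export
damage_curve <- function(coefficients, zone = "composite", r_squared = NA_real_) {
  if (!is.numeric(coefficients) || length(coefficients) < 1) {
    abort("`coefficients` must be a nonempty numeric vector.")
  }
  structure(
    list(
      coefficients = unname(coefficients),
      degree = length(coefficients) - 1L,
      zone = zone,
      r_squared = r_squared
    ),
    class = "damage_curve"
  )
}

#' @rdname damage_curve
#' @export
reference_damage_curves <- function() {
  list(
    cortical = damage_curve(
      c(0, 5.485, -13.38, 7.315, 14.60, -20.13),
      zone = "cortical", r_squared = 0.973
    ),
    composite = damage_curve(
      c(0.009, 2.402, -5.202, 3.706),
      zone = "composite", r_squared = 0.982
    ),
    trabecular = damage_curve(
      c(0, 2.573, -13.66, 31.52, -31.84),
      zone = "trabecular", r_squared = 0.992
    )
  )
}

#' @rdname damage_curve
#' @param curve A `damage_curve`.
#' @param b Cycle fractions at which to evaluate.
#' @export
eval_damage_curve <- function(curve, b) {
  stopifnot(inherits(curve, "damage_curve"))
  co <- curve$coefficients
  Reduce(`+`, lapply(seq_along(co), function(i) co[i] * b^(i - 1)))
}

#' Least-squares polynomial fit of a damage-growth curve
#'
#' Ordinary least squares of damage `A` on powers of the cycle fraction
#' `B` up to the requested degree. The coefficient of determination is
#' `1 - SS_res / SS_tot` (1 when the data carry no variance).
#'
#' @param data Data frame of curve samples.
#' @param b,a Column names of the cycle fraction and damage values.
#' @param degree Polynomial degree (>= 0). Needs at least `degree + 2`
#'   points.
#' @return A `damage_curve` with the fitted coefficients (ascending) and
#'   `r_squared`.
#' @export
fit_damage_curve <- function(data, b = "b", a = "a", degree = 3) {
  check_columns(data, c(b, a))
  x <- data[[b]]; y <- data[[a]]
  if (length(x) < degree + 2) {
    abort("Underdetermined fit: need at least `degree + 2` points.")
  }
  if (any(x < 0 | x > 1)) abort("Cycle fractions must lie in [0, 1].")
  X <- outer(x, 0:degree, `^`)
  fit <- stats::lm.fit(X, y)
  res <- y - X %*% fit$coefficients
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  r2 <- if (ss_tot == 0) 1 else 1 - ss_res / ss_tot
  damage_curve(as.numeric(fit$coefficients), zone = "fitted", r_squared = r2)
}

#' Three-stage segmentation of a damage-growth curve
#'
#' Damage accumulation in bone follows a three-stage pattern: a primary
#' (decelerating) phase, a secondary phase of linear growth, and a
#' tertiary phase of rapid change leading to fracture. This routine
#' segments sampled `(B, A)` data by exhaustive two-breakpoint
#' least-squares: quadratic fits on the outer segments, a linear fit on
#' the middle segment, with breakpoints searched on a grid of resolution
#' `grid_res`. If the piecewise model does not improve materially on a
#' single global line the data are classified as all secondary stage and
#' the degenerate boundaries `(0, 1)` are returned.
#'
#' @param data Data frame of at least 10 curve samples spanning `[0, 1]`.
#' @param b,a Column names of cycle fraction and damage.
#' @param grid_res Breakpoint grid resolution (default 0.01).
#' @param min_points Minimum samples per segment (default 3).
#' @return One-row tibble: `lower`, `upper` (the stage I/II and II/III
#'   boundaries), `sse`, `sse_linear`, `degenerate`.
#' @export
classify_stages <- function(data, b = "b", a = "a", grid_res = 0.01,
                            min_points = 3) {
  check_columns(data, c(b, a))
  x <- data[[b]]; y <- data[[a]]
  if (length(x) < 10) abort("Stage segmentation needs at least 10 samples.")
  o <- order(x); x <- x[o]; y <- y[o]

  seg_sse <- function(xs, ys, degree) {
    X <- outer(xs, 0:degree, `^`)
    # guard against rank deficiency on tiny segments
    f <- stats::lm.fit(X, ys)
    sum((ys - X %*% ifelse(is.na(f$coefficients), 0, f$coefficients))^2)
  }

  sse_linear <- seg_sse(x, y, 1)
  ss_tot <- sum((y - mean(y))^2)

  grid <- seq(grid_res, 1 - grid_res, by = grid_res)
  best <- list(sse = Inf, lower = 0, upper = 1)
  for (b1 in grid) {
    i1 <- x <= b1
    if (sum(i1) < min_points) next
    s1 <- seg_sse(x[i1], y[i1], 2)
    for (b2 in grid[grid > b1]) {
      i2 <- x > b1 & x <= b2
      i3 <- x > b2
      if (sum(i2) < min_points || sum(i3) < min_points) next
      s <- s1 + seg_sse(x[i2], y[i2], 1) + seg_sse(x[i3], y[i3], 2)
      if (s < best$sse) best <- list(sse = s, lower = b1, upper = b2)
    }
  }

  # a single line explaining the data as well as the piecewise model
  # (relative to total variance) means there is no stage structure
  degenerate <- !is.finite(best$sse) ||
    (sse_linear - best$sse) <= 1e-6 * max(ss_tot, .Machine$double.eps)
  tibble::tibble(
    lower = if (degenerate) 0 else best$lower,
    upper = if (degenerate) 1 else best$upper,
    sse = if (degenerate) sse_linear else best$sse,
    sse_linear = sse_linear,
    degenerate = degenerate
  )
}

#' Fit a log-linear S-N curve
#'
#' Ordinary least squares of the maximum stress on the natural log of
#' cycles to failure, `sigma_max = slope * ln(N_f) + intercept`. A
#' negative slope reflects physical fatigue behaviour (stress endurance
#' falls with life).
#'
#' @param data Data frame of fatigue test results.
#' @param sigma_max,n_f Column names of maximum stress and cycles to
#'   failure. `n_f` must be positive; at least 3 pairs are required.
#' @return An object of class `sn_fit` with elements `slope`, `intercept`,
#'   `r_squared` and the underlying `lm` fit.
#' @export
fit_sn_curve <- function(data, sigma_max = "sigma_max", n_f = "n_f") {
  check_columns(data, c(sigma_max, n_f))
  y <- data[[sigma_max]]; nf <- data[[n_f]]
  if (length(y) < 3) abort("An S-N fit needs at least 3 pairs.")
  if (any(nf <= 0)) abort("Cycles to failure must be positive.")
  lx <- log(nf)
  if (var(lx) == 0) abort("Degenerate fit: no variance in log(N_f).")
  fit <- lm(y ~ lx)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((y - mean(y))^2)
  structure(
    list(
      slope = unname(coef(fit)[2]),
      intercept = unname(coef(fit)[1]),
      r_squared = r2,
      n = length(y),
      fit = fit
    ),
    class = "sn_fit"
  )
}

#' Serialize a fitted model to YAML
#'
#' Writes the coefficients, degree and goodness of fit of a
#' [damage_curve()] or [fit_sn_curve()] object to a YAML file.
#'
#' @param object A `damage_curve` or `sn_fit`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_model_yaml <- function(object, path) {
  payload <- if (inherits(object, "damage_curve")) {
    list(
      model = "damage_curve", zone = object$zone,
      degree = object$degree, coefficients = object$coefficients,
      r_squared = object$r_squared
    )
  } else if (inherits(object, "sn_fit")) {
    list(
      model = "sn_fit", slope = object$slope,
      intercept = object$intercept, r_squared = object$r_squared,
      n = object$n
    )
  } else {
    abort("`object` must be a `damage_curve` or `sn_fit`.")
  }
  yaml::write_yaml(payload, path)
  invisible(path)
}
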