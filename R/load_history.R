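#' Validate and construct a tri-axial force trace
#'
#' A force trace holds a gait loading history sampled in time: the vertical
#' hip-contact force `fz` and the smaller anterior-posterior (`fy`) and
#' medial-lateral (`fx`) components.
#'
#' @param data Data frame with columns `time`, `fx`, `fy`, `fz`. `time`
#'   must be strictly increasing with at least 2 samples.
#' @return The input as a validated tibble of class `force_trace`.
#' @export
force_trace <- function(data) {
  check_columns(data, c("time", "fx", "fy", "fz"))
  if (nrow(data) < 2) abort("A force trace needs at least 2 samples.")
  if (any(diff(data$time) <= 0)) abort("`time` must be strictly increasing.")
  if (any(!is.finite(as.matrix(data[c("time", "fx", "fy", "fz")])))) {
    abort("Force trace values must be finite.")
  }
  out <- tibble::as_tibble(data)
  class(out) <- c("force_trace", class(out))
  out
}

#' Reduce a tri-axial trace to an equivalent uniaxial load history
#'
#' Collapses the three force components to a single scalar history: the
#' per-sample Euclidean resultant `sqrt(fx^2 + fy^2 + fz^2)` carrying the
#' sign of the vertical component `fz`, so the compressive or tensile
#' character of the dominant axis is retained for mean-stress bookkeeping.
#'
#' @param trace A [force_trace()] (or data frame with the same columns).
#' @return The trace with an added `load` column.
#' @export
equivalent_uniaxial <- function(trace) {
  trace <- force_trace(trace)
  dplyr::mutate(
    trace,
    load = sqrt(.data$fx^2 + .data$fy^2 + .data$fz^2) *
      ifelse(.data$fz < 0, -1, 1)
  )
}

# Peak-valley reduction: collapse plateaus, keep strict turning points.
# Endpoints are always retained.
turning_points <- function(x) {
  stopifnot(is.numeric(x))
  x <- x[c(TRUE, diff(x) != 0)]             # collapse plateaus
  if (length(x) < 3) return(x)
  d <- diff(x)
  keep <- c(TRUE, d[-1] * d[-length(d)] < 0, TRUE)
  x[keep]
}

#' Rainflow cycle counting (ASTM E1049-85)
#'
#' Decomposes an irregular scalar load history into closed cycles using
#' the ASTM E1049-85 rainflow rules: the history is reduced to its turning
#' points, ranges are paired by the three-point rule, ranges containing
#' the starting point and the final residue are counted as half cycles.
#' Every turning-point interval is consumed, so half-cycle counts sum to
#' `(number of turning points - 1) / 2`.
#'
#' @param data Data frame holding the load history, or a numeric vector.
#' @param load Name of the load column when `data` is a data frame.
#' @return A `cycle_spectrum` tibble with one row per counted cycle:
#'   `sigma_max`, `sigma_min`, `range`, `mean`, `amplitude`, `count`
#'   (0.5 for half cycles, 1 for full cycles). A constant history yields a
#'   zero-row spectrum.
#' @examples
#' rainflow_count(c(-2, 1, -3, 5, -1, 3, -4, 4, -2))
#' @export
rainflow_count <- function(data, load = "load") {
  x <- if (is.data.frame(data)) {
    check_columns(data, load)
    data[[load]]
  } else {
    data
  }
  if (!is.numeric(x) || any(!is.finite(x))) {
    abort("The load history must be finite numeric.")
  }
  tp <- turning_points(x)
  rec_max <- numeric(0); rec_min <- numeric(0); rec_count <- numeric(0)
  record <- function(a, b, count) {
    rec_max <<- c(rec_max, max(a, b))
    rec_min <<- c(rec_min, min(a, b))
    rec_count <<- c(rec_count, count)
  }
  if (length(tp) >= 2) {
    # three-point rule on a growing stack; start-point ranges count as halves
    stack <- numeric(0)
    for (p in tp) {
      stack <- c(stack, p)
      repeat {
        n <- length(stack)
        if (n < 3) break
        X <- abs(stack[n] - stack[n - 1])
        Y <- abs(stack[n - 1] - stack[n - 2])
        if (X < Y) break
        if (n == 3) {
          record(stack[1], stack[2], 0.5)   # Y contains the starting point
          stack <- stack[-1]
        } else {
          record(stack[n - 2], stack[n - 1], 1)
          stack <- stack[-c(n - 2, n - 1)]
        }
      }
    }
    if (length(stack) >= 2) {               # residue: halves
      for (i in seq_len(length(stack) - 1)) record(stack[i], stack[i + 1], 0.5)
    }
  }
  out <- tibble::tibble(
    sigma_max = rec_max,
    sigma_min = rec_min,
    range = rec_max - rec_min,
    mean = (rec_max + rec_min) / 2,
    amplitude = (rec_max - rec_min) / 2,
    count = rec_count
  )
  class(out) <- c("cycle_spectrum", class(out))
  out
}

#' Scale a cycle spectrum to a target number of applied cycles
#'
#' Rescales the per-block counts proportionally so that the applied
#' repetitions sum to `cycles_per_year * years`, preserving the relative
#' frequency of each counted block. One year of normal walking is taken as
#' 10^6 gait cycles.
#'
#' @param spectrum A `cycle_spectrum` from [rainflow_count()].
#' @param cycles_per_year Walking cycles per year (default 1e6).
#' @param years Exposure duration in years; must be positive.
#' @return The spectrum with an added (or rescaled) `n` column summing to
#'   the target.
#' @export
scale_spectrum <- function(spectrum, cycles_per_year = 1e6, years = 1) {
  check_columns(spectrum, c("range", "mean", "count"))
  if (nrow(spectrum) == 0) abort("Cannot scale an empty spectrum.")
  if (!is.numeric(years) || years <= 0) abort("`years` must be positive.")
  if (cycles_per_year <= 0) abort("`cycles_per_year` must be positive.")
  total <- cycles_per_year * years
  dplyr::mutate(spectrum, n = .data$count / sum(.data$count) * total)
}

#' Read or write a force trace as CSV
#'
#' CSV layout: columns `time`, `fx`, `fy`, `fz` with a header row.
#'
#' @param path File path.
#' @param trace A [force_trace()].
#' @return `read_force_trace()` returns a validated `force_trace`;
#'   `write_force_trace()` returns the path invisibly.
#' @export
read_force_trace <- function(path) {
  force_trace(tibble::as_tibble(read.csv(path)))
}

#' @rdname read_force_trace
#' @export
write_force_trace <- function(trace, path) {
  trace <- force_trace(trace)
  write.csv(trace[c("time", "fx", "fy", "fz")], path, row.names = FALSE)
  invisible(path)
}
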