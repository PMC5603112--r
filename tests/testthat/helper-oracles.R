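# Independent oracles, coded separately from the package implementations.

# Rainflow counting by repeated leftmost-triple scanning (ASTM E1049-85
# three-point rules). Independent of the package's single-pass stack
# implementation.
oracle_rainflow <- function(x) {
  # peak-valley reduction
  x <- x[c(TRUE, diff(x) != 0)]
  if (length(x) >= 3) {
    d <- diff(x)
    x <- x[c(TRUE, d[-1] * d[-length(d)] < 0, TRUE)]
  }
  out <- data.frame(sigma_max = numeric(0), sigma_min = numeric(0),
                    count = numeric(0))
  add <- function(a, b, count) {
    rbind(out, data.frame(sigma_max = max(a, b), sigma_min = min(a, b),
                          count = count))
  }
  repeat {
    if (length(x) < 3) break
    found <- FALSE
    for (i in seq_len(length(x) - 2)) {
      Y <- abs(x[i + 1] - x[i])
      X <- abs(x[i + 2] - x[i + 1])
      if (X >= Y) {
        if (i == 1) {
          out <- add(x[1], x[2], 0.5)
          x <- x[-1]
        } else {
          out <- add(x[i], x[i + 1], 1)
          x <- x[-c(i, i + 1)]
        }
        found <- TRUE
        break
      }
    }
    if (!found) break
  }
  if (length(x) >= 2) {
    for (i in seq_len(length(x) - 1)) out <- add(x[i], x[i + 1], 0.5)
  }
  out
}

# Canonical multiset representation of a cycle set for comparison:
# rounded (max, min, count) triples, sorted.
cycle_multiset <- function(df) {
  m <- data.frame(
    sigma_max = round(df$sigma_max, 9),
    sigma_min = round(df$sigma_min, 9),
    count = df$count
  )
  m <- stats::aggregate(count ~ sigma_max + sigma_min, data = m, FUN = sum)
  m[order(m$sigma_max, m$sigma_min), ]
}

# Direct polynomial evaluation, ascending coefficients.
oracle_polyval <- function(coefs, x) {
  s <- 0
  for (i in seq_along(coefs)) s <- s + coefs[i] * x^(i - 1)
  s
}

# Step-by-step strain-life evaluation (two power terms written out).
oracle_strain_life <- function(n_f, sigma_f, eps_f, b, c, sigma_m, E) {
  elastic <- (sigma_f - sigma_m) / E * (2 * n_f)^b
  plastic <- eps_f * ((sigma_f - sigma_m) / sigma_f)^(c / b) * (2 * n_f)^c
  elastic + plastic
}
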