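test_that("mean stress and amplitude cover the three fluctuating-load types", {
  expect_equal(mean_and_amplitude(100, -100), tibble::tibble(sigma_m = 0, sigma_a = 100))
  expect_equal(mean_and_amplitude(100, 0), tibble::tibble(sigma_m = 50, sigma_a = 50))
  expect_equal(mean_and_amplitude(80, 20), tibble::tibble(sigma_m = 50, sigma_a = 30))
  expect_error(mean_and_amplitude(0, 10), ">=")
})

test_that("strain-life matches a step-by-step evaluation and its limits", {
  p <- fatigue_properties()
  E <- 20.24

  # direct arithmetic oracle at the default bone constants
  for (nf in c(1e2, 1e4, 1e6)) {
    expect_equal(
      strain_life(nf, p, sigma_m = 0, elastic_modulus = E),
      oracle_strain_life(nf, 6, 0.352, -0.12, -0.6, 0, E),
      tolerance = 1e-14
    )
  }

  # zero mean stress reduces to plain Coffin-Manson on a 100-point grid
  nf <- 10^seq(0.1, 8, length.out = 100)
  plain <- 6 / E * (2 * nf)^-0.12 + 0.352 * (2 * nf)^-0.6
  expect_equal(strain_life(nf, p, 0, E), plain, tolerance = 1e-14)

  # universal slopes make the plastic-term knockdown exactly a 5th power
  sm <- 2
  with_mean <- strain_life(nf, p, sm, E)
  elastic <- (6 - sm) / E * (2 * nf)^-0.12
  plastic0 <- 0.352 * (2 * nf)^-0.6
  expect_equal(with_mean - elastic, plastic0 * ((6 - sm) / 6)^5, tolerance = 1e-12)

  # strictly decreasing in life and in mean stress
  expect_true(all(diff(strain_life(nf, p, 0, E)) < 0))
  sms <- seq(0, 5, by = 0.5)
  eps_by_sm <- vapply(sms, function(s) strain_life(1e4, p, s, E), numeric(1))
  expect_true(all(diff(eps_by_sm) < 0))

  expect_error(strain_life(1e3, p, sigma_m = 6, elastic_modulus = E), "below")
})

test_that("life inversion round-trips and matches a log-grid search", {
  p <- fatigue_properties()
  E <- 20.24
  for (N in c(1e2, 1e4, 1e6)) {
    eps <- strain_life(N, p, 0, E)
    expect_equal(solve_life(eps, p, 0, E), N, tolerance = 1e-4)
  }
  # larger strain target, smaller life
  lives <- solve_life(c(0.05, 0.03, 0.02), p, 0, E)
  expect_true(all(diff(lives) > 0))

  # brute-force log-grid oracle
  grid <- 10^seq(0, 12, length.out = 1e6)
  target <- 0.0305
  oracle <- grid[which.min(abs(strain_life(grid, p, 0, E) - target))]
  expect_equal(solve_life(target, p, 0, E), oracle,
               tolerance = 2 * 12 / 1e6 * log(10))

  expect_error(solve_life(10, p, 0, E), "outside")
})

test_that("Miner's rule sums cycle ratios with clamping and failure flag", {
  sp1 <- tibble::tibble(range = 1, mean = 0, count = 1, n = 5e3, n_f = 5e3)
  expect_equal(miner_damage(sp1)$damage, 1)
  expect_true(miner_damage(sp1)$failed)

  sp2 <- tibble::tibble(range = c(1, 2), mean = 0, count = 1,
                        n = c(250, 1000), n_f = c(500, 2000))
  expect_equal(miner_damage(sp2)$damage_raw, 1)

  set.seed(21)
  sp3 <- tibble::tibble(range = runif(5), mean = 0, count = 1,
                        n = runif(5, 10, 100), n_f = runif(5, 1e3, 1e5))
  expect_equal(miner_damage(sp3)$damage_raw, sum(sp3$n / sp3$n_f))

  # additive over concatenation, homogeneous in applied cycles
  expect_equal(
    miner_damage(dplyr::bind_rows(sp2, sp3))$damage_raw,
    miner_damage(sp2)$damage_raw + miner_damage(sp3)$damage_raw
  )
  sp3k <- dplyr::mutate(sp3, n = 3 * n)
  expect_equal(miner_damage(sp3k)$damage_raw, 3 * miner_damage(sp3)$damage_raw)

  expect_error(miner_damage(dplyr::mutate(sp1, n_f = 0)), "positive")
})

test_that("damage variable identities hold against the constitutive law", {
  C <- assemble_stiffness(material_groups_table()[80, ])
  eps <- c(1e-3, 2e-4, 3e-3, 0, 0, 0)
  elastic <- as.numeric(unclass(C) %*% eps)

  expect_equal(damage_from_state(C, eps, elastic)$damage, 0)
  expect_equal(damage_from_state(C, eps, rep(0, 6))$damage, 1)
  expect_equal(damage_from_state(C, eps, 0.5 * elastic)$damage, 0.5)

  # degraded stress scales the elastic prediction
  expect_equal(degraded_stress(0, C, eps)$stress, elastic)
  expect_equal(degraded_stress(1, C, eps)$stress, rep(0, 6))
  expect_equal(degraded_stress(0.25, C, eps)$stress, 0.75 * elastic)

  # damage_from_state after degraded_stress recovers D exactly
  for (d in seq(0, 1, by = 0.1)) {
    sigma <- degraded_stress(d, C, eps)$stress
    expect_equal(damage_from_state(C, eps, sigma)$damage, d, tolerance = 1e-12)
  }
  # dominant component selection: largest strain is component 3
  expect_equal(damage_from_state(C, eps, elastic)$component, 3)
  expect_error(degraded_stress(1.2, C, eps), "0, 1")
})

test_that("polynomial damage-curve fitting recovers generating truths", {
  comp <- reference_damage_curves()$composite
  b <- seq(0, 1, length.out = 50)
  samples <- tibble::tibble(b = b, a = eval_damage_curve(comp, b))
  fit <- fit_damage_curve(samples, degree = 3)
  expect_equal(fit$coefficients, c(0.009, 2.402, -5.202, 3.706), tolerance = 1e-6)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
  expect_equal(eval_damage_curve(fit, 0), 0.009, tolerance = 1e-9)

  # cross-check evaluation against the plain polynomial oracle
  expect_equal(eval_damage_curve(comp, b), oracle_polyval(comp$coefficients, b))

  const <- fit_damage_curve(tibble::tibble(b = b, a = 0.4), degree = 0)
  expect_equal(const$coefficients, 0.4)
  expect_equal(const$r_squared, 1)

  expect_error(fit_damage_curve(samples[1:3, ], degree = 3), "Underdetermined")
})

test_that("reference damage curves carry the published constant terms", {
  curves <- reference_damage_curves()
  expect_equal(eval_damage_curve(curves$cortical, 0), 0)
  expect_equal(eval_damage_curve(curves$trabecular, 0), 0)
  expect_equal(eval_damage_curve(curves$composite, 0), 0.009)
  expect_equal(curves$cortical$degree, 5)
  expect_equal(curves$composite$degree, 3)
  expect_equal(curves$trabecular$degree, 4)
})

test_that("stage segmentation finds breakpoints and degenerates on lines", {
  b <- seq(0, 1, length.out = 80)
  line <- classify_stages(tibble::tibble(b = b, a = 0.2 + 0.5 * b))
  expect_true(line$degenerate)
  expect_equal(c(line$lower, line$upper), c(0, 1))

  # three-piece synthetic curve with known breakpoints (0.2, 0.8)
  a0 <- ifelse(b <= 0.2, 0.25 * (2 * (b / 0.2) - (b / 0.2)^2),
        ifelse(b <= 0.8, 0.25 + (b - 0.2) * 0.5 / 0.6,
               0.75 + 6.25 * (b - 0.8)^2))
  set.seed(3)
  noisy <- tibble::tibble(b = b, a = a0 + rnorm(80, 0, 0.005))
  st <- classify_stages(noisy)
  expect_false(st$degenerate)
  expect_lt(abs(st$lower - 0.2), 0.05)
  expect_lt(abs(st$upper - 0.8), 0.05)

  # cortical quintic: tertiary acceleration sets in near 0.8
  quintic <- reference_damage_curves()$cortical
  bb <- seq(0, 1, length.out = 101)
  stq <- classify_stages(tibble::tibble(b = bb, a = eval_damage_curve(quintic, bb)))
  expect_gte(stq$upper, 0.7)
  expect_lte(stq$upper, 0.9)

  expect_error(classify_stages(noisy[1:5, ]), "at least 10")
})

test_that("S-N fitting recovers log-linear generating parameters", {
  nf <- 10^seq(2, 7, length.out = 30)
  exact <- tibble::tibble(sigma_max = -19.0 * log(nf) + 309.4, n_f = nf)
  fit <- fit_sn_curve(exact)
  expect_equal(fit$slope, -19.0, tolerance = 1e-9)
  expect_equal(fit$intercept, 309.4, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  # a two-point fit (plus midpoint) reproduces the line through the points
  two <- tibble::tibble(sigma_max = c(200, 100, 150), n_f = c(1e3, 1e6, 10^4.5))
  f2 <- fit_sn_curve(two)
  expect_equal(predict(f2$fit), two$sigma_max, ignore_attr = TRUE)

  noisy <- gen_sn_data(slope = -19.0, intercept = 309.4, n = 50,
                       noise_sd = 5, seed = 101)
  fn <- fit_sn_curve(noisy)
  expect_lt(abs(fn$slope - (-19.0)), 2)
  expect_lt(fn$slope, 0)

  expect_error(fit_sn_curve(exact[1:2, ]), "at least 3")
  expect_error(
    fit_sn_curve(tibble::tibble(sigma_max = c(1, 2, 3), n_f = rep(10, 3))),
    "Degenerate"
  )
})

test_that("fitted models serialize to YAML with their parameters", {
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(reference_damage_curves()$composite, path)
  back <- yaml::read_yaml(path)
  expect_equal(back$coefficients, c(0.009, 2.402, -5.202, 3.706))
  expect_equal(back$degree, 3)

  fit <- fit_sn_curve(gen_sn_data(n = 20, seed = 3))
  write_model_yaml(fit, path)
  back <- yaml::read_yaml(path)
  expect_equal(back$slope, fit$slope)
})
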