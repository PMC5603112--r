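#' Synthetic gait loading parameters
#'
#' Parameters of the synthetic hip-contact force generator. The vertical
#' force during stance shows the characteristic double peak of normal
#' walking (heel-strike and push-off), with near-zero load during swing.
#' Defaults describe a 750 N (about 76 kg) adult walking with a 1.1 s
#' gait cycle and a 60% stance fraction; the peak vertical hip-contact
#' force defaults to 2.4 body weights with a slightly lower second peak,
#' in the range reported by instrumented-prosthesis gait studies. Peak
#' magnitudes are configuration, not ground truth.
#'
#' @param body_weight Body weight in N (> 0).
#' @param peak_multipliers Two nonnegative factors for the two vertical
#'   force peaks, in units of body weight.
#' @param cadence Gait cycles per second.
#' @param duty Stance fraction of the gait cycle, in (0, 1).
#' @param n_steps Number of gait cycles to generate (>= 1).
#' @param samples_per_cycle Samples per gait cycle.
#' @param fx_scale,fy_scale Medial-lateral and anterior-posterior force
#'   components as fractions of the vertical component.
#' @param noise_sd Additive Gaussian noise, in N.
#' @param seed Integer RNG seed.
#' @return A list of class `gait_params`.
#' @export
gait_params <- function(body_weight = 750,
                        peak_multipliers = c(2.4, 2.1),
                        cadence = 0.9, duty = 0.6, n_steps = 10,
                        samples_per_cycle = 100,
                        fx_scale = 0.15, fy_scale = 0.3,
                        noise_sd = 0, seed = 1) {
  if (body_weight <= 0) abort("`body_weight` must be positive.")
  if (length(peak_multipliers) != 2 || any(peak_multipliers < 0)) {
    abort("`peak_multipliers` must be two nonnegative factors.")
  }
  if (duty <= 0 || duty >= 1) abort("`duty` must lie in (0, 1).")
  if (n_steps < 1) abort("`n_steps` must be at least 1.")
  structure(
    list(
      body_weight = body_weight, peak_multipliers = peak_multipliers,
      cadence = cadence, duty = duty, n_steps = n_steps,
      samples_per_cycle = samples_per_cycle,
      fx_scale = fx_scale, fy_scale = fy_scale,
      noise_sd = noise_sd, seed = seed
    ),
    class = "gait_params"
  )
}

#' Generate a synthetic tri-axial gait force trace
#'
#' Builds a periodic hip-contact force history from [gait_params()]: a
#' double-peak vertical component during stance, proportional smaller
#' medial-lateral and anterior-posterior components, and optional
#' additive Gaussian noise. The noiseless vertical peak equals exactly
#' `body_weight * max(peak_multipliers)`. Deterministic under the seed.
#'
#' @param params A [gait_params()] object.
#' @return A [force_trace()] tibble with columns `time`, `fx`, `fy`, `fz`.
#' @export
gen_gait <- function(params = gait_params()) {
  stopifnot(inherits(params, "gait_params"))
  p <- params
  n <- p$n_steps * p$samples_per_cycle
  time <- (seq_len(n) - 1) / (p$samples_per_cycle * p$cadence)
  phase <- ((seq_len(n) - 1) %% p$samples_per_cycle) / p$samples_per_cycle
  # two Gaussian lobes inside the stance window
  lobe <- function(centre, width) exp(-0.5 * ((phase - centre) / width)^2)
  shape <- p$peak_multipliers[1] * lobe(0.22 * p$duty, 0.16 * p$duty) +
    p$peak_multipliers[2] * lobe(0.75 * p$duty, 0.16 * p$duty)
  shape[phase > p$duty] <- 0
  peak <- max(shape)
  fz <- if (peak == 0) rep(0, n) else {
    p$body_weight * max(p$peak_multipliers) * shape / peak
  }
  fx <- p$fx_scale * fz
  fy <- p$fy_scale * fz
  if (p$noise_sd > 0) {
    noise <- withr::with_seed(p$seed, rnorm(3 * n, 0, p$noise_sd))
    fx <- fx + noise[seq_len(n)]
    fy <- fy + noise[n + seq_len(n)]
    fz <- fz + noise[2 * n + seq_len(n)]
  }
  force_trace(tibble::tibble(time = time, fx = fx, fy = fy, fz = fz))
}

#' Generate a synthetic two-zone Hounsfield-unit field
#'
#' Draws voxel densities uniformly within each zone's density band (the
#' zones split at the cortical/trabecular threshold) and converts them to
#' Hounsfield units by inverting the CT density calibration. Defaults
#' span the 0.997-1.071 g/cm^3 range of the published 80-group database.
#'
#' @param n_voxels Number of voxels (>= 1).
#' @param trabecular_fraction Proportion of trabecular voxels, in
#'   `[0, 1]`.
#' @param density_range Length-2 density range (g/cm^3), within
#'   (0.9, 1.2).
#' @param zone_split Trabecular/cortical density threshold.
#' @param seed Integer RNG seed.
#' @return Tibble with columns `hu`, `density`, `zone`.
#' @export
gen_hu_field <- function(n_voxels = 1000, trabecular_fraction = 0.55,
                         density_range = c(0.997, 1.071),
                         zone_split = 1.0375, seed = 1) {
  if (n_voxels < 1) abort("`n_voxels` must be at least 1.")
  if (trabecular_fraction < 0 || trabecular_fraction > 1) {
    abort("`trabecular_fraction` must lie in [0, 1].")
  }
  if (any(density_range <= 0.9) || any(density_range >= 1.2) ||
      density_range[1] > density_range[2]) {
    abort("`density_range` must be ordered and lie within (0.9, 1.2).")
  }
  n_trab <- round(n_voxels * trabecular_fraction)
  n_cort <- n_voxels - n_trab
  lo_t <- density_range[1]; hi_t <- min(zone_split, density_range[2])
  lo_c <- max(zone_split, density_range[1]); hi_c <- density_range[2]
  rho <- withr::with_seed(seed, c(
    runif(n_trab, lo_t, min(hi_t, hi_c)),
    runif(n_cort, max(lo_c, lo_t), hi_c)
  ))
  tibble::tibble(
    hu = density_to_hu(rho),
    density = rho,
    zone = rep(c("trabecular", "cortical"), c(n_trab, n_cort))
  )
}

#' Generate synthetic S-N fatigue data
#'
#' Samples cycles to failure log-uniformly over `n_f_range` (so fits are
#' well conditioned across decades) and evaluates the log-linear S-N law
#' `sigma_max = slope * ln(N_f) + intercept` with additive Gaussian
#' noise. The default generating truth is the multiaxial whole-femur fit
#' (slope -19.0, intercept 309.4 MPa); the uniaxial fit is
#' (-16.8, 265.5).
#'
#' @param slope Generating slope (< 0).
#' @param intercept Generating intercept (stress units, MPa).
#' @param n Number of pairs (>= 1).
#' @param noise_sd Gaussian noise standard deviation on the stress.
#' @param n_f_range Length-2 range of cycles to failure.
#' @param seed Integer RNG seed.
#' @return Tibble with columns `sigma_max`, `n_f`.
#' @export
gen_sn_data <- function(slope = -19.0, intercept = 309.4, n = 50,
                        noise_sd = 0, n_f_range = c(1e2, 1e7), seed = 1) {
  if (slope >= 0) abort("`slope` must be negative for physical fatigue data.")
  if (n < 1) abort("`n` must be at least 1.")
  draws <- withr::with_seed(seed, {
    nf <- exp(runif(n, log(n_f_range[1]), log(n_f_range[2])))
    eps <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    list(nf = nf, eps = eps)
  })
  tibble::tibble(
    sigma_max = slope * log(draws$nf) + intercept + draws$eps,
    n_f = draws$nf
  )
}

#' Generate synthetic damage-growth curve samples
#'
#' Samples cycle fractions on `[0, 1]` (both endpoints always included),
#' evaluates a [damage_curve()] and adds Gaussian noise; damage values
#' are clipped at zero.
#'
#' @param curve A [damage_curve()] used as generating truth.
#' @param n Number of samples; at least `degree + 2`.
#' @param noise_sd Gaussian noise standard deviation on the damage.
#' @param seed Integer RNG seed.
#' @return Tibble with columns `b` (cycle fraction) and `a` (damage).
#' @export
gen_damage_samples <- function(curve, n = 50, noise_sd = 0, seed = 1) {
  if (!inherits(curve, "damage_curve")) {
    abort("`curve` must be a `damage_curve`.")
  }
  if (n < curve$degree + 2) {
    abort("`n` must be at least `degree + 2` for a recoverable curve.")
  }
  draws <- withr::with_seed(seed, {
    b <- if (n <= 2) seq(0, 1, length.out = n) else c(0, sort(runif(n - 2)), 1)
    eps <- if (noise_sd > 0) rnorm(n, 0, noise_sd) else 0
    list(b = b, eps = eps)
  })
  tibble::tibble(
    b = draws$b,
    a = pmax(eval_damage_curve(curve, draws$b) + draws$eps, 0)
  )
}

#' Generate a complete synthetic study
#'
#' Bundles every input the damage pipeline consumes — a gait force trace,
#' a two-zone Hounsfield-unit field, S-N pairs and damage-curve samples —
#' together with a manifest of all generator parameters. The manifest
#' suffices to regenerate every table bit-for-bit:
#' `gen_study(manifest = m)` reproduces the study.
#'
#' @param seed Master integer seed; per-table seeds are derived from it.
#' @param gait,hu,sn,damage Named lists of overrides passed to the
#'   respective generators.
#' @param manifest Optional manifest from a previous study; when given,
#'   all other arguments are ignored.
#' @return A list of class `synthetic_study` with elements `trace`,
#'   `hu_field`, `sn_pairs`, `damage_samples`, `manifest`.
#' @export
gen_study <- function(seed = 1, gait = list(), hu = list(), sn = list(),
                      damage = list(), manifest = NULL) {
  if (is.null(manifest)) {
    base <- seed %% 2147480000L
    manifest <- list(
      seed = seed,
      gait = utils::modifyList(
        unclass(gait_params(seed = base + 1)), gait),
      hu = utils::modifyList(
        list(n_voxels = 1000, trabecular_fraction = 0.55,
             density_range = c(0.997, 1.071), zone_split = 1.0375,
             seed = base + 2), hu),
      sn = utils::modifyList(
        list(slope = -19.0, intercept = 309.4, n = 50, noise_sd = 0,
             n_f_range = c(1e2, 1e7), seed = base + 3), sn),
      damage = utils::modifyList(
        list(curve = "composite", n = 50, noise_sd = 0, seed = base + 4),
        damage)
    )
  }
  m <- manifest
  curve <- if (is.character(m$damage$curve)) {
    reference_damage_curves()[[m$damage$curve]]
  } else {
    m$damage$curve
  }
  structure(
    list(
      trace = gen_gait(do.call(gait_params, m$gait)),
      hu_field = do.call(gen_hu_field, m$hu),
      sn_pairs = do.call(gen_sn_data, m$sn),
      damage_samples = gen_damage_samples(
        curve, n = m$damage$n, noise_sd = m$damage$noise_sd,
        seed = m$damage$seed
      ),
      manifest = m
    ),
    class = "synthetic_study"
  )
}
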