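# osteofatigue

Fatigue damage accumulation modelling for whole-bone structures in R.

Predicting when a bone will fail under everyday cyclic loading is a core
problem in orthopaedic biomechanics: a femur sees on the order of a
million walking cycles per year, and fatigue microdamage accumulates long
before any single overload would fracture it. `osteofatigue` implements a
desk-scale version of a whole-femur macrodamage analysis as a tested,
reproducible pipeline:

1. **Material mapping.** CT Hounsfield units are converted to effective
   density, `rho = 0.0000464 HU + 1` (g/cm^3), and density-binned into
   cortical and trabecular material groups. Each group receives nine
   orthotropic engineering constants from zone-specific power laws
   (e.g. trabecular `E1 = E2 = 1157 rho^1.78`, `E3 = 1904 rho^1.64` MPa)
   and a 6x6 Voigt stiffness matrix is assembled from them. The published
   80-group material database ships with the package.
2. **Load spectrum.** A tri-axial hip-contact force history for walking
   (double-peak vertical component) is reduced to an equivalent uniaxial
   history and rainflow-counted (ASTM E1049-85) into cycles with ranges,
   means and counts, then scaled to 10^6 cycles/year.
3. **Fatigue life and damage.** Each counted cycle enters the
   mean-stress-corrected Coffin-Manson strain-life law under the
   universal slopes method,

   `eps_a = (sigma_f' - sigma_m)/E (2 Nf)^b + eps_f' ((sigma_f' - sigma_m)/sigma_f')^(c/b) (2 Nf)^c`

   with `b = -0.12`, `c = -0.6` (so `c/b = 5`), `sigma_f' = 6`,
   `eps_f' = 0.352`. Damage accumulates by Miner's rule
   `D = sum n_i / N_fi`, with the constitutive coupling
   `sigma = (1 - D) C eps`. Three-stage damage-growth polynomials
   (primary / secondary-linear / tertiary) and log-linear S-N curves
   `sigma_max = slope ln(Nf) + intercept` are fitted to data.
4. **Failure probability.** Monte Carlo simulation draws normally
   distributed damage values about a mean and SD and reports the mean,
   SD, variance and `P(D >= 1)`.

All inputs can be synthesized by the package (gait traces, two-zone HU
fields, S-N and damage-curve samples), so the entire analysis runs
without any external data.

## Worked example

```r
library(osteofatigue)

# 1. density -> orthotropic constants (GPa), trabecular zone
density_to_constants(c(0.997, 1.037), zone_calibration("trabecular"))
#>   density    E1    E3   G12   G23   G31
#> 1   0.997 1.151 1.895 0.053 0.066 0.061
#> 2   1.037 1.234 2.021 0.057 0.071 0.066

# 2. stiffness matrix of the densest cortical group (GPa)
g80 <- material_groups_table()[80, ]
stiffness_components(assemble_stiffness(g80))
#>      C11    C22    C33   C12   C13   C23  C44  C55  C66 gamma
#> 1 16.835 16.835 24.587 6.061 2.694 2.694 7.11 6.58 5.71 1.375

# 3. gait trace -> rainflow spectrum scaled to one year of walking
spectrum <- gen_gait(gait_params(n_steps = 5, noise_sd = 25, seed = 2)) |>
  equivalent_uniaxial() |>
  rainflow_count() |>
  scale_spectrum(cycles_per_year = 1e6, years = 1)
sum(spectrum$n)
#> [1] 1e+06

# 4. S-N curve recovery from noisy synthetic data
fit_sn_curve(gen_sn_data(slope = -19.0, intercept = 309.4,
                         n = 50, noise_sd = 5, seed = 7))
#> Log-linear S-N fit: sigma_max = -18.962 ln(N_f) + 309.453 (R^2 = 0.997, n = 50)

# 5. Monte Carlo probability of failure about a damage estimate
monte_carlo_damage(0.333299, 0.393134, n = 200, seed = 11)
#> Monte Carlo damage sample: n = 200, mean = 0.3331, sd = 0.3751, P(D >= 1.00) = 0.0400
normal_failure_probability(0.333299, 0.393134)   # analytic check
#> [1] 0.04495601
```

The stiffness components `C33 = 24.587`, `C22 = 16.835`, `C12 = 6.061`
and `C23 = 2.694` GPa reproduce the published 80-group stiffness
database; `C44/C55/C66` are the engineering shear moduli `G23/G31/G12`.
The 200-draw Monte Carlo estimate (4.0%) sits close to the closed-form
normal tail (4.5%).

The full chain — synthetic HU field, material binning, gait spectrum,
Miner damage, stage curves and Monte Carlo — is driven by

```r
res <- run_pipeline(pipeline_config(seed = 1, out_dir = "run"))
```

which writes `materials.csv`, `stiffness.csv`, `spectrum.csv`,
`damage_curves.csv`, `stages.csv`, `mc_summary.csv` and a
`manifest.yaml` carrying every parameter and a configuration hash.

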