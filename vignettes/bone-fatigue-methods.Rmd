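---
title: "Methods: fatigue damage accumulation in whole bone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fatigue damage accumulation in whole bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteofatigue)
```

## The model

Bone is a composite of a dense cortical shell (5–10 % porosity) and a
porous trabecular interior (50–95 % porosity). Under the million-or-so
walking cycles a femur sees per year, fatigue damage accumulates at
stresses far below the monotonic strength. `osteofatigue` chains the
four stages of a macroscale damage analysis; this vignette records the
model, its assumptions, the parameter choices, and what the package's
tests do and do not demonstrate.

### CT calibration and orthotropic elasticity

Voxel Hounsfield units map linearly to effective density,
$\rho = 4.64\times10^{-5}\,\mathrm{HU} + 1$ (g/cm³). Densities are
binned per zone into material groups (80 by default, mirroring the
published database: 44 trabecular groups up to 1.037 g/cm³, 36 cortical
from 1.038 g/cm³; the zone threshold is 1.0375 g/cm³, the midpoint
between the two adjacent printed densities). Each group gets nine
engineering constants from zone power laws (`zone_calibration()`):

* Young's moduli $E_i = a_i \rho^{p_i}$ (MPa), with $E_1 = E_2$
  (radial = circumferential) in both zones;
* constant Poisson ratios $\nu_{12}=0.4$, $\nu_{23}=\nu_{31}=0.25$;
* shear moduli $G_{ij} = s\, G_{ij,\max} (\rho/\rho_{\max})^2$ with
  $G_{12,\max}=5.71$, $G_{23,\max}=7.11$, $G_{31,\max}=6.58$.

Two conventions in the shear relation are deliberate and encoded in the
default calibrations, because the published 80-group table is only
reproduced this way: cortical shear values read the maxima in GPa with
the global maximum density $\rho_{\max}=1.071$ and scale $s=1$;
trabecular values need $s=1/100$ and the zone-local
$\rho_{\max}=1.037$. With these defaults, all 44 trabecular rows of the
shipped table are reproduced to ±0.001 GPa when the power laws are
evaluated on the unrounded uniform density grid
$\rho_g = 0.997 + (g-1)\,0.074/79$ the table was evidently built on
(several printed densities repeat, betraying 3-decimal rounding).

The cortical Young's-modulus columns of the published table are *not*
reproducible from the published cortical power laws (those give
~2.6 GPa at 1.071 g/cm³ against a printed 13.064). They instead track
the trabecular relation scaled by a factor 10 almost exactly
(fitting $\log E$ on $\log\rho$ over the 36 cortical rows gives
exponent 1.77, $R^2 = 0.999998$). We ship the printed table verbatim as
the authoritative database (`material_groups_table()`), and
`build_material_table()` flags regenerated cortical rows as
`matches_published = FALSE` rather than silently "correcting" either
source.

### Stiffness assembly

`assemble_stiffness()` builds the 6×6 Voigt matrix
$$C_{11} = E_1(1-\nu_{23}\nu_{32})\gamma,\quad
  C_{33} = E_3(1-\nu_{12}\nu_{21})\gamma,\quad
  C_{12} = E_1(\nu_{21}-\nu_{31}\nu_{23})\gamma, \dots$$
with $C_{44}=G_{23}$, $C_{55}=G_{31}$, $C_{66}=G_{12}$ and
$$\gamma = \frac{1}{1-\nu_{12}\nu_{21}-\nu_{23}\nu_{32}
  -2\nu_{21}\nu_{32}\nu_{13}}.$$

Two points deserve care:

* Only six Poisson ratios are tabulated; the other three are taken as
  the symmetric pairs $\nu_{21}=\nu_{12}$, $\nu_{32}=\nu_{23}$,
  $\nu_{13}=\nu_{31}$. This is the convention under which the published
  stiffness table's $C_{33}$, $C_{22}$, $C_{12}$ and $C_{23}$ columns
  are reproduced exactly at 3 decimals.
* This $\gamma$ omits the $\nu_{13}\nu_{31}$ pair term that the
  textbook orthotropic compliance inversion includes. We implement the
  model as defined — it is what the published stiffness database
  embodies — so in the isotropic limit the assembly reduces to
  $C_{11} = E(1-\nu^2)/(1-2\nu^2-2\nu^3)$, not the classical
  $E(1-\nu)/((1+\nu)(1-2\nu))$. The tests pin the former.
* Two published group-80 cells cannot be explained under any single
  convention: the printed $C_{11}=16.162$ (the symmetric convention
  yields $C_{11}=C_{22}=16.835$) and $C_{13}=3.367$ (the printed
  formula gives 2.694; 3.367 would require
  $E_1(\nu_{31}-\nu_{23}\nu_{32})\gamma$). Both are documented here and
  excluded from verification; the four consistent cells are pinned.

The composite behaviour assumes **iso-strain mixing**: cortical and
trabecular zones see the same strain and the composite stress is the
volume-fraction-weighted sum of phase stresses
(`composite_response()`). This is the stiff-bound rule of mixtures; it
overestimates the compliance-weighted response of real trabecular
architecture but matches the strain-based damage formulation used
throughout.

### Load history and rainflow counting

Walking loads are tri-axial hip-contact forces. `equivalent_uniaxial()`
collapses them to the per-sample Euclidean resultant signed by the
vertical component — the reduction is not prescribed by the source
model, and the signed resultant was chosen so that the
compressive/tensile character survives into the mean-stress correction.
`rainflow_count()` implements ASTM E1049-85 three-point counting (the
de-facto standard; no variant is prescribed): plateaus collapse, the
turning-point sequence is processed against a stack, ranges containing
the starting point and the final residue count as half cycles. The
implementation is pinned against the canonical nine-point worked
example of the standard and against an independently coded
repeated-scan implementation on random histories.
`scale_spectrum()` rescales block counts proportionally to the target
exposure, 10⁶ cycles/year by default.

The finite-element step that converts force to stress is out of scope;
the pipeline uses a linear `stress_per_force` factor (GPa/N). The
pipeline default, 5.8×10⁻⁵ GPa/N, places the peak walking stress near
0.11 GPa for the default 750 N subject — the whole-femur dynamic stress
magnitude reported for this loading; the low-level operations default
to a factor of 1 so unit choices stay explicit.

### Strain-life, Miner's rule, damage coupling

The strain-life law splits total strain amplitude into elastic and
plastic power-law terms in reversals $2N_f$, with a mean-stress
knockdown:
$$\varepsilon_a = \frac{\sigma_f'-\sigma_m}{E}(2N_f)^{b}
 + \varepsilon_f'\Big(\frac{\sigma_f'-\sigma_m}{\sigma_f'}\Big)^{c/b}
   (2N_f)^{c}.$$
The universal slopes method replaces material-specific exponents with
$b=-0.12$, $c=-0.6$, making the knockdown exponent $c/b$ exactly 5; for
user-supplied exponents we keep the general $c/b$ form. The bone
constants are $\sigma_f'=6$ and $\varepsilon_f'=0.352$. The source
gives $\sigma_f'$ without units; we interpret it on the same GPa scale
as the stiffness tensor so the knockdown ratio is dimensionless and the
elastic term is a strain — this is a configuration choice
(`fatigue_properties()`), not a derived fact.

`solve_life()` inverts the law by bracketed root finding on
$\log N_f$ over $[1, 10^{12}]$ (relative tolerance $10^{-9}$); the
curve is strictly decreasing so the root is unique. Spectrum blocks
whose strain amplitude falls below the curve at the $10^{12}$-cycle cap
are treated by the pipeline as non-damaging (assigned the cap). With
physiological stresses (~0.05 GPa amplitude against a ~20 GPa modulus)
*every* walking block is in this regime, so the default annual Miner
sum is of order $10^{-6}$: a healthy femur does not fatigue-fail in a
year of walking. Damage of order one requires the strain amplification
that only an FE stress field supplies, which is outside this package.

Miner's rule `miner_damage()` sums $n_i/N_{fi}$; raw sums above 1 are
reported raw and clamped, with a `failed` flag, and downstream
probability uses the raw value. The scalar damage variable couples to
elasticity by $\sigma=(1-D)C\varepsilon$ (`degraded_stress()`), and
`damage_from_state()` recovers $D=(C\varepsilon-\sigma)/(C\varepsilon)$
on the work-conjugate component of the largest-magnitude strain entry
(configurable), since the scalar identity must be evaluated on one
component of a tensorial state.

### Damage-growth curves and stages

Three published polynomials express damage $A$ against cycle fraction
$B=n/N_f$: a cortical quintic, a trabecular quartic (both with zero
constant term) and a composite cubic (constant 0.009);
`reference_damage_curves()` carries them. Both the quintic and the
quartic go negative inside $[0,1]$ (the quintic below zero beyond
$B\approx0.72$, the quartic beyond $\approx0.45$), so they should be
read as fits valid over the authors' data range, not as globally
monotone damage laws; the composite cubic is nonnegative on all of
$[0,1]$.

`classify_stages()` segments sampled curves into
primary/secondary/tertiary by exhaustive two-breakpoint least squares:
quadratic outer segments, a linear middle segment (the secondary stage
is linear by definition), breakpoints on a 0.01 grid with at least 3
points per segment. If the piecewise model does not improve on a single
global line by more than $10^{-6}$ of the total variance, the data are
declared all-secondary and $(0,1)$ is returned. On the raw cortical
quintic sampled at 101 points the tertiary boundary lands at 0.78,
consistent with the reported onset of rapid damage growth near a cycle
fraction of 0.8.

### Monte Carlo failure probability

`monte_carlo_damage()` draws $n$ (default 200, mirroring the source
study) normal damage values about a mean and SD, reports sample mean,
SD, variance ($=\mathrm{SD}^2$, $n-1$ convention) and
$P(D \ge \text{threshold})$ with threshold 1 (total failure). Negative
draws are kept unless truncation is requested, keeping the model a
plain normal. The failure criterion is our definition: the source
never states how its printed probabilities were computed, and they are
not consistent with a normal tail at the printed means/SDs, so only the
variance arithmetic is verified against the printed summary. A
closed-form check, `normal_failure_probability()`, accompanies the
sampler; for the printed mean 0.333299 and SD 0.393134 the tail is
4.5 %.

## Synthetic data

The generators make every stage testable without downloads:

* `gen_gait()` — periodic double-peak vertical force (two Gaussian
  lobes in the stance window, 60 % duty), proportional smaller
  horizontal components, optional Gaussian noise. Defaults: 750 N body
  weight, peaks 2.4/2.1 body weights, 0.9 Hz cadence, 100
  samples/cycle — magnitudes typical of instrumented-hip walking data,
  configurable and not asserted as ground truth. The noiseless peak
  equals exactly `body_weight * max(peak_multipliers)`.
* `gen_hu_field()` — zone-labelled densities uniform within each
  zone's band of the 0.997–1.071 g/cm³ range, converted to HU by the
  exact inverse calibration.
* `gen_sn_data()` — lives log-uniform over $[10^2, 10^7]$ (so fits are
  conditioned across decades), stress from the log-linear law plus
  noise; generating truths default to the published multiaxial fit
  (−19.0, 309.4), with (−16.8, 265.5) as the uniaxial alternative.
* `gen_damage_samples()` — cycle fractions uniform with both endpoints
  included, damage from a reference polynomial plus noise, clipped at
  zero (real damage measurements are nonnegative; note the clipping
  flattens the negative tails of the quintic/quartic, which is why
  stage tests on those curves sample the polynomial directly).

Every generator is a pure function of its parameters and seed;
`gen_study()` bundles them with a manifest that regenerates all tables
bit-for-bit. What the generators do *not* emulate: anatomical geometry,
spatially correlated density fields, measured hip-contact waveforms,
muscle co-contraction, or bone remodelling. Passing tests therefore
demonstrate correctness of the computational chain under the stated
statistical assumptions, not validity against in-vivo data.

## Numerical choices

* Table reproduction tolerance ±0.001 on 3-decimal cells (printed
  densities are rounded; one cell, the group-1 longitudinal modulus,
  evaluates to 1.895 vs a printed 1.894).
* Root finding: `uniroot` on $\log N_f$, tolerance $10^{-9}\log(10^{12})$.
* Polynomial fits use raw-power design matrices via `lm.fit`; $R^2 = 1 -
  SS_{res}/SS_{tot}$, defined as 1 when the data carry no variance.
* Volume fractions must sum to 1 within $10^{-9}$; damage inputs to
  `degraded_stress()` must be inside $[0,1]$ exactly.
* Stage-search grid 0.01 with ≥3 points per segment; degeneracy margin
  $10^{-6}$ of total variance.
* Seeds: every stochastic function takes an explicit seed and uses it
  locally (`withr::with_seed`), so calls do not disturb the global RNG
  stream; derived seeds stay below $2^{31}$.
* Problem sizes in the shipped tests and pipeline default: 1000 voxels,
  5–10 gait cycles at 100 samples/cycle, 50-point fitting samples,
  200-draw Monte Carlo — sizes at which every stage is exact or
  statistically stable, chosen to keep the full analysis interactive.

## Known limitations

* No bone remodelling or self-healing: damage only accumulates, so
  long-exposure extrapolations are conservative.
* The force→stress map is a single linear factor; real femoral stress
  fields are strongly position-dependent and require an FE solution
  (out of scope), as do von Mises fields, mesh-based stiffness
  estimates and whole-bone life maps.
* The published cortical elasticity columns and two group-80 stiffness
  cells are internally inconsistent with their own generating
  relations; we ship the printed data and document the discrepancies
  rather than resolve them.
* Printed failure probabilities of the source study are not
  reproducible under any normal-tail criterion and are not targets.
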