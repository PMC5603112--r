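Package: osteofatigue
Title: Fatigue Damage Accumulation Modelling for Whole-Bone Structures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for modelling macroscale fatigue damage accumulation in
    bone under cyclic physiological loading. Maps CT Hounsfield units to
    density-binned orthotropic elastic constants for cortical and trabecular
    bone, assembles 6x6 orthotropic stiffness matrices, reduces tri-axial
    hip-contact force histories to equivalent uniaxial load spectra by
    ASTM E1049-85 rainflow counting, predicts fatigue life with a
    mean-stress-corrected Coffin-Manson strain-life law under the universal
    slopes method, accumulates damage with Miner's rule, fits S-N curves and
    three-stage damage-growth polynomials, and estimates probability of
    failure by Monte Carlo simulation. All user-facing functions are data
    frame first and return tibbles; fitted objects have tidy(), glance()
    and autoplot() methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
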