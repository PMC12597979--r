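Package: thermonod
Title: Thermal and Phosphorus-Limitation Growth Traits for Phytoplankton Strains
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates strain-level thermal and resource-use traits from
    plate-reader fluorescence growth assays run across crossed temperature and
    phosphorus gradients. Growth rates are extracted per well by AICc selection
    among segmented exponential models (with optional lag and saturation
    phases), then summarised as thermal performance curves (Thomas 2012 form)
    with optimum temperature, area under the curve and Arrhenius activation
    energies, and as Monod curves with half-saturation constants and minimal
    phosphorus requirements (P*) under a fixed mortality rate. Trait responses
    along the opposing gradient are classified by penalized-spline effective
    degrees of freedom, lake monitoring records are summarised (with a seasonal
    regression model for sparsely sampled lakes), and temperature-dependent
    local adaptation is tested by inverse-variance weighted regression of
    trait-environment slopes on experimental temperature. A synthetic-data
    generator with known ground truth supports power analysis and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    mgcv,
    minpack.lm,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
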