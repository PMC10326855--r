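Package: crystkin
Title: Rapid Assessment of Crystallization Nucleation and Growth Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of crystallization kinetics from small-scale agitated
    vial experiments. Fits primary nucleation rates and growth-time offsets to
    censored ensembles of isothermal induction times, estimates secondary
    nucleation rates from calibrated particle-count traces and crystal growth
    rates from volume-weighted d90 trajectories of number-based particle size
    distributions, fits power-law supersaturation kinetics, synthesises the
    single-nucleus mechanism quantities (minimum secondary-nucleation size,
    detection delays), and applies steady-state MSMPR design relations for
    cubic crystals. Includes a Monte-Carlo simulator of instrument-level
    datasets so every estimator is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
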