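Package: sertpbpk
Title: Gestational Physiologically Based Pharmacokinetic Modeling of
    Sertraline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A minimal five-compartment physiologically based
    pharmacokinetic (PBPK) model of oral sertraline in nonpregnant and
    pregnant women. Hepatic clearance is built by in vitro-in vivo
    extrapolation over five cytochrome P450 enzymes, tissue partitioning by
    the tissue-composition method for lipophilic compounds, absorption by a
    time-dependent dissolution-limited rate with enterohepatic
    recirculation, and pregnancy by gestational-age-dependent scaling of
    body weight, plasma volume, cardiac output, plasma protein binding, and
    CYP3A4/CYP2D6 activity. Includes non-compartmental analysis, Monte
    Carlo population simulation with truncated distributions, normalized
    local sensitivity analysis, fold-error predictive-performance metrics,
    and a gestational dose-adjustment solver that restores nonpregnant
    steady-state exposure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deSolve,
    yaml,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    withr
Config/testthat/edition: 3
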