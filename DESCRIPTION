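Package: hvdbe
Title: Model-Based Design and Power Simulation for Bioequivalence Trials of
    Highly Variable Drugs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte-Carlo simulator for bioequivalence trials of highly
    variable drugs. Simulates subject-level concentration-time profiles from a
    two-compartment oral-absorption population pharmacokinetic model with
    lognormal between- and within-subject random effects, reduces them to Cmax
    and AUC by noncompartmental analysis, and evaluates bioequivalence under
    both the EMA scaled average bioequivalence procedure (expanded acceptance
    limits) and the FDA reference-scaled average bioequivalence procedure
    (mixed scaling with the Howe-type upper confidence bound). Compares 2x2,
    3x3 partial-replicate and 2x4 full-replicate crossover designs by
    statistical power versus the total number of observations, with dropout
    and residual-error sensitivity analyses and a post-hoc subsampling power
    analysis for observed replicate-design datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tools,
    MASS,
    nlme,
    yaml,
    jsonlite,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
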