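Package: previnc
Title: Illness-Death Modelling of Chronic-Disease Prevalence and Incidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the three-state illness-death model of chronic-disease
    epidemiology. Solves the direct problem linking age-specific incidence and
    mortality to age-specific prevalence, both through the two-compartment
    linear cohort system and through the scalar Riccati-type prevalence ODE in
    all six mortality-information variants (m and m0, m and m1, m0 and m1,
    m0 and R, m1 and R, m and R). Solves the inverse problem of estimating
    age-specific incidence from cross-sectional prevalence plus mortality
    information, including relative-risk scenario sweeps and the sandwich
    principle, and demonstrates the ill-posedness of that inversion under
    high-frequency perturbations. Includes an individual-level competing-risks
    microsimulator for validating the deterministic theory and a generator of
    synthetic noisy prevalence curves. Curves and estimates are tidy tibbles;
    ggplot2 autoplot() methods and a thin command-line interface are provided.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
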