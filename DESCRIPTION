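Package: virodyn
Title: Spatiotemporal Dynamics of Oncolytic Virotherapy and Radiovirotherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the reaction-diffusion dynamics of tumour cells treated
    with an oncolytic virus delivered continuously from a blood vessel, and the
    extension of that model with radiotherapy (radiovirotherapy). The tissue
    annulus around a single vessel is discretized with a conservative
    finite-volume form of the cylindrically symmetric radial Laplacian and the
    resulting system is integrated by the method of lines with a fixed-step
    classic fourth-order Runge-Kutta scheme. Provides time-dependent radiation
    dose-rate schedules (constant, decaying, periodic), the normalized viable
    tumour mass functional, trajectory summaries (minimum, final value, peak
    time, oscillation and eradication flags), parameter-sweep drivers, broom
    style tidiers, ggplot2 figures, and YAML/JSON run configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    utils
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
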