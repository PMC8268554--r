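Package: eitherm
Title: Electrical Impedance Tomography Monitoring of Hyperthermia Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and reconstruction toolkit for monitoring mild
    hyperthermia treatment with electrical impedance tomography (EIT).
    Generates a synthetic heterogeneous torso phantom on a tetrahedral mesh,
    solves the quasi-static conduction forward problem with a P1 finite
    element method and adjoint sensitivities, and reconstructs
    heating-induced conductivity changes by regularized iterative
    Gauss-Newton difference imaging with tissue-dependent penalties,
    adaptive prior regions, positivity constraints and thermal-length
    smoothing. Couples conductivity to temperature and perfusion through a
    Pennes bioheat simulation with temperature-dependent perfusion and a
    two-frequency conductivity-change model, including disentangling of the
    direct temperature and perfusion contributions from reconstructions at
    two frequencies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
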