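Package: coreshell
Title: Diffusion-Controlled Drug Release from Core-Shell Microspheres
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates Fickian, diffusion-controlled drug release from
    bi-layered (core-shell) spherical microspheres and supports the full
    model-based design workflow for long-acting intravitreal depots: a
    method-of-lines finite-difference solver for the two-layer spherical
    diffusion equation with a partitioning interface condition, cumulative
    release and daily release-rate metrics, local/Morris/Sobol sensitivity
    analysis, multi-start nonlinear least-squares parameter estimation with
    Latin hypercube initialisation, sandwich-covariance parameter
    uncertainty, and design-space sweeps over core radius and shell
    thickness against therapeutic release thresholds.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    minpack.lm,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
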