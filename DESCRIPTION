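Package: biocavity
Title: Gravitactic Bioconvection with Nanoparticles in a Heated Cavity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Finite-difference solver for gravitactic bioconvection of
    upward-swimming microorganisms (e.g. Paramecium caudatum) in a
    water-nanoparticle suspension inside a two-dimensional rectangular
    cavity with wall thermal sources. The coupled five-field model
    (stream function, vorticity, microorganism concentration,
    temperature, nanoparticle volume fraction) is advanced with an
    Alternating Direction Implicit scheme in stream-function-vorticity
    form, including Brownian and thermophoretic nanoparticle transport
    and thermally guided swimming. Diagnostics cover field extrema,
    convection-cell counting, nanoparticle Rayleigh-number sweeps with
    onset estimation, and mesh-independence studies, plus a small
    command-line front end for batch runs.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
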