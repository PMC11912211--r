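Package: auxgen
Title: Automatic Even-Tempered Auxiliary Basis Sets and Variational Density Fitting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic generation of even-tempered, shared-exponent primitive
    Hermite Gaussian auxiliary basis sets from an atomic orbital basis, and a
    self-contained variational density-fitting engine for the two-electron
    Coulomb repulsion and Fock exchange energies of closed-shell densities.
    Includes an analytic McMurchie-Davidson Gaussian integral engine (Boys
    function, overlap, two-, three- and four-center electron repulsion
    integrals), an independent numerical-quadrature oracle, direct, truncated
    eigendecomposition and MINRES solvers for the Coulomb fitting system, and
    a reproducible validation harness with toy molecular fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
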