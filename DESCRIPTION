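Package: dnalie
Title: Lie Symmetry Analysis of the Microwave-Driven DNA Strand-Displacement Equation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Symbolic and numeric toolkit for the nonlinear fourth-order wave
    equation governing longitudinal strand displacement in DNA under an
    external microwave field. Computes Lie point symmetries from first
    principles via an exact sparse Laurent-polynomial engine (fourth-order
    prolongation, determining equations, nullspace solve), builds the
    commutator and adjoint tables and the one-dimensional optimal system of
    subalgebras, performs similarity reductions to ordinary differential
    equations, integrates the quadrature-solvable reductions into closed-form
    invariant solutions, implements the Riccati-type auxiliary-equation
    travelling-wave method with its 17-branch solution catalogue, and verifies
    every candidate solution both symbolically and on numeric grids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
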