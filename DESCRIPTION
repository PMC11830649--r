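Package: rfekit
Title: Response-Function Reduction of Linear Reaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reduces linear (first-order) chemical reaction networks to renewal
    equations between compartments of states. Computes the matrix-valued and
    scalar response kernels of the compartment decomposition, solves the
    resulting Volterra systems, analyses kernels for normalization, complete
    monotonicity under detailed balance, Markovianity and long-time behaviour,
    approximates arbitrary waiting-time distributions by Erlang mixtures
    realized as explicit reaction chains, converts between renewal equations
    and age-structured population equations, and ships worked biochemical
    models (Hopfield kinetic proofreading, linear and nonlinear polymerization,
    adaptation, coherent feed-forward loop).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
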