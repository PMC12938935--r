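Package: mtexciton
Title: Collective Ultraviolet Excitation Dynamics in Microtubule Tryptophan Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models networks of tryptophan chromophores in tubulin and
    microtubule lattices as radiatively coupled two-level dipoles. Builds
    dipole-dipole coupling and collective radiative decay matrices from site
    geometry, diagonalizes the effective non-Hermitian Hamiltonian to obtain
    superradiant and subradiant eigenmodes and radiative lifetimes, propagates
    the trace-preserving Lindblad master equation with collective jump
    operators on the single-excitation manifold plus an explicit ground sink,
    and evaluates quantum-information measures (L1 coherence, correlated
    coherence, logarithmic negativity, mutual information, trace-distance
    backflow) over the resulting trajectories. Includes synthetic network
    generators, static and structural disorder models, and size-scaling scans
    of bright and dark mode lifetimes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
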