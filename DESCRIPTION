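Package: ddrabm
Title: Hybrid Agent-Based Simulation of Tumour Cell Populations Under ATR
    Inhibition
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: On-lattice hybrid multiscale agent-based simulation of monolayer
    cancer cell populations and two-dimensional tumour spheroid cross sections
    responding to an ATR-inhibiting drug. Agents progress through a
    probabilistic cell-cycle state machine with a replication-stress DNA-damage
    state; repair of damaged cells is inhibited through a sigmoid Emax
    dose-effect model. In spheroid mode, oxygen and drug are transported by
    explicit finite-difference reaction-diffusion on the lattice, hypoxia
    elongates the G1 phase, quiescence is space-limited, and dead agents are
    removed. Readouts include the gammaH2AX-positive fraction, state-resolved
    cell counts and the disc-to-spheroid extrapolated tumour volume, with
    root-mean-square-error comparison against experimental time courses, CSV
    and VTK export, and a YAML-configured command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
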