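Package: gapdyn
Title: Non-Autonomous Gap Gene Circuit Simulation and Phase Portrait Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates hybrid gene-circuit models of the Drosophila trunk gap
    gene network (hb, Kr, gt, kni) driven by time-variable maternal and
    terminal inputs (Bcd, Cad, Tll, Hkb), including the mitotic production
    shut-off and the nuclear division between cleavage cycles 13 and 14A.
    Provides frozen-gradient comparison runs, instantaneous phase portrait
    analysis of the diffusion-less per-nucleus system (Newton-Raphson steady
    state search, eigenvalue classification, steady-state tracking and
    saddle-node detection, basin assignment, classification of non-autonomous
    patterning mechanisms into transitions, pursuits, and geometrical or
    topological captures), half-maximum domain boundary extraction with shift
    rate and overshoot quantification, and a sign-constrained simulated
    annealing harness for reverse-engineering circuit parameters from
    expression data, together with a synthetic-data generator emulating the
    blastoderm inputs and gap gene pattern.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
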