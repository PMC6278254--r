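Package: dsdlogic
Title: Domain-Label DNA Strand-Displacement Logic Circuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Compiles digital logic circuits built from domain-label DNA
    strand-displacement gates (K-input mapping modules, catalytic
    amplification and fan-out gates, fluorophore reporter gates) into
    strand-level species, closes the species set into a finite chemical
    reaction network under toehold-mediated displacement semantics,
    integrates the network under deterministic mass-action kinetics, and
    threshold-decodes fluorophore trajectories back into bits.  Ships the
    three reference circuits of the architecture (1-bit full adder, 4x4
    binary multiplier, 8-bit ripple-carry adder/subtractor with
    two's-complement subtraction), a logic-level netlist twin used as a
    simulation oracle, and a minimal dual-rail seesaw baseline exhibiting
    the threshold-edge instability that concentration-encoded logic
    suffers and domain-label logic avoids.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    xml2,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
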