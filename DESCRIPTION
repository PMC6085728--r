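Package: prismlogic
Title: Domain-Level Simulation of a Reconfigurable DNA Triangular-Prism Logic Platform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Deterministic domain-level modelling of a reconfigurable
    three-dimensional DNA triangular prism that computes molecular logic.
    Provides a strand/domain algebra with a constraint-satisfying sequence
    fixture generator, assembly of the two triangular face motifs and the
    closed prism, a toehold-mediated strand-displacement reaction engine
    iterated to a fixed point (invasion, solution-phase sequestration,
    hairpin caging and erase-driven re-closure), a coarse-grained B-form
    geometry model with a Foerster-transfer fluorescence readout, and a
    gate library covering binary OR/AND/XOR/INHIBIT gates, three-input
    INHIBIT-OR combinatorial gates, a ternary INHIBIT gate and a
    binary-coded-decimal even/odd identifier. Results are returned as
    tibbles with broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
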