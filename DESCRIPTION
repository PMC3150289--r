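Package: signalogic
Title: Logical Modeling, IFF-SAT Analysis and Merging of Signaling Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Boolean (logical) models of receptor signaling networks.
    Implication formulas with early/late/permanent time horizons are compiled
    into if-and-only-if (IFF) clause systems whose satisfying assignments are
    the admissible states of the network. The package provides feasibility
    checking and state enumeration with a built-in DPLL solver, prediction of
    stimulus responses (including sequential two-receptor stimulation),
    computation of subset-minimal intervention sets that restore feasibility,
    extraction of minimal infeasible cores with negative-feedback-loop
    annotation, semi-automated merging of two parent networks into a child
    network with conflict classification and provenance tracking, and exact
    logical projection of small networks onto component subsets. Curated
    transcriptions of T-cell receptor and interleukin-2 receptor signaling
    models are bundled, together with a seeded random-network generator.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
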