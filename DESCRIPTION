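Package: edamcompose
Title: Automated Composition of Mass-Spectrometry Data-Analysis Pipelines
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bounded synthesis of linear bioinformatics tool pipelines from
    semantic tool annotations. Tools are annotated with EDAM-style operation,
    data and format concepts; a workflow specification gives an initial data
    state, a goal class and finite-trace temporal constraints expressed in
    five natural-language templates. The package loads EDAM-style taxonomies
    (OBO subset or flattened table), decides ontology subsumption, compiles
    constraints to deterministic finite-state monitors, enumerates every
    compatible tool pipeline up to a length bound by breadth-first search over
    the product of data states and monitor states, and renders merged
    automaton-like solution graphs. A bundled proteomics domain model
    (msconvert, Comet, X! Tandem, PeptideProphet, ProteinProphet and friends)
    with four use-case specifications reproduces published solution counts for
    typical shotgun-proteomics analysis tasks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, jsonlite, stats, utils, tools
Suggests: testthat (>= 3.0.0), optparse, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
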