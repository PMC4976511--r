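Package: elrepo
Title: An OWL-EL Ontology Repository with Saturation-Based Reasoning
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A self-contained ontology repository for the OWL 2 EL profile.
    Reads and writes ontologies in OWL 2 Functional-Style Syntax, filters
    axioms to the EL fragment, classifies ontologies with a completion-rule
    saturation reasoner, answers Manchester-syntax description-logic queries
    resolved through class and property labels, maintains a multi-ontology
    store with load-outcome accounting and aggregate statistics, runs a
    randomized parallel query benchmark with timing capture and correlation
    analysis, and materializes inferred subsumption axioms into an ontology
    so that the same queries are answered from told axioms alone. Includes a
    seeded generator of labeled biomedical-style synthetic ontologies and a
    brute-force entailment oracle for verification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
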