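Package: ontomdr
Title: Ontologically Founded Metadata Registry for Clinical and
    Epidemiological Research
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A typed, validating implementation of an ISO/IEC 11179-style
    metadata registry grounded in a top-level ontology with higher-order
    category typing. Provides a finite ontology graph with inductive order
    computation, lifted (universal-existential) categorial relations, the
    data element / data element concept / conceptual domain / value domain
    metamodel with permissible-value relators and measurement partitions,
    clinical-trial item extensions (defaults, ranges, data acquisition,
    complex-concept composition, item variants), phenotypic property-nexus
    classification, a canonical JSON registry dialect, a seeded fixture
    generator with violation injection for mutation testing, item queries,
    DOT export, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
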