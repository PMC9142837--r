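Package: boolsynth
Title: Synthesis of Boolean Gene Networks from Experimental Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Formal reasoning over Abstract Boolean Networks (ABNs): network
    templates with definite and optional signed interactions and a menu of
    monotone regulation conditions per component. Provides synchronous
    Boolean semantics, the 18 monotone regulation-condition templates,
    timed experimental-observation constraints with knockout and forced
    expression perturbations, a bounded synthesis engine that enumerates
    all concrete networks consistent with a set of experiments (with an
    independent brute-force oracle), null-hypothesis satisfiability tests,
    a packaged model of the C. elegans germline stem-cell fate decision
    circuit with its in-silico perturbation suite, a synthetic-fixture
    generator with planted hidden networks, JSON/TSV/CSV file formats,
    DOT/GraphML export and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    igraph,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
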