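Package: gapscope
Title: Topological Gap-Filling of Genome-Scale Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Completes draft genome-scale metabolic networks by topological
    (graph-based) gap-filling. Producibility of a metabolite is defined by
    forward-scope reachability from seed nutrients: a reaction fires only when
    all of its reactants are reachable, and the scope is the least fixed point
    of this relation. Given a draft network, seeds, targets and a reference
    reaction database, the solver enumerates exhaustively all
    cardinality-minimal completions restoring producibility of the targets,
    together with their union and intersection (brave and cautious
    consequences). Filled networks are validated with flux balance analysis and
    flux variability analysis, classifying reactions as essential, alternative
    or blocked with respect to a biomass reaction, and a degradation benchmark
    harness measures recovery of essential reactions at configurable scale.
    Networks are exchanged as SBML Level 2/3 or plain-text identifier lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    xml2
LinkingTo: Rcpp
Suggests:
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
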