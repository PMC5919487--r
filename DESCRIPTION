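Package: graphletdelta
Title: Incremental Graphlet and Orbit Counting in Evolving Networks
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Exact counting of 2-5 node graphlet and node-orbit occurrences
    in undirected networks, together with an incremental counter that
    computes the signed difference in counts under single edge additions
    or removals by exploring only the neighbourhood of the modified edge.
    Includes evolving-network generators (Barabasi-Albert, Erdos-Renyi,
    geometric), a graphlet-redundancy criterion for growing ranked
    gene-regulatory networks, ranked-edge-list evaluation (AUROC, AUPR,
    their harmonic mean), and a command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
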