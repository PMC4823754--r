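Package: centerfind
Title: Center-Based Community Detection in Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects communities in undirected networks by first electing
    community centers and then diffusing their labels. Every node receives a
    local density score (degree or triangle count) and a capped minimum
    shortest-path distance to a denser node; the product of the two, the
    community centrality, ranks nodes as center candidates. Centers seed a
    greedy majority-vote label propagation ordered by centrality. Ships with
    the evaluation metrics used to validate such partitions (Newman-Girvan
    modularity, normalized mutual information, rich-club connectivity), an
    LFR-style benchmark generator with planted communities, a planted-partition
    generator, classic fixtures, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
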