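Package: flowdec
Title: Exact Minimum Flow Decomposition on Graphs with Cycles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Exact solvers for minimum flow decomposition (MFD) on directed
    graphs that may contain cycles, via integer linear programming. Supports
    three decomposition variants: source-to-sink paths or cycles (a sequential
    node-ordering formulation with cycle-start variables), source-to-sink
    trails (both a constraint-generation procedure over strongly connected
    component cuts and a reachability/spanning-tree formulation), and
    source-to-sink walks (the reachability formulation with integer edge
    multiplicities and power-of-two product linearization). Includes linear
    and doubling minimum-k search drivers, greedy shortest/widest residual
    path baselines, an exhaustive brute-force oracle for tiny instances, a
    synthetic cyclic instance generator with planted decompositions, and
    readers/writers for the Catfish-style '.graph' benchmark format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    reticulate,
    rlang,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
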