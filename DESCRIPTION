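Package: cascadedist
Title: Final-Size Distributions of Contagion Cascades on Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the full probability distribution of the final size of
    contagion cascades (threshold contagion and the independent cascade /
    bond-percolation model) on networks. On trees the distribution is obtained
    exactly by subtree distribution propagation, a single bottom-up
    message-passing sweep that convolves per-subtree size distributions. On
    general, locally tree-like networks it is approximated by the tree
    distribution approximation: loopy belief propagation for directed-edge
    activation probabilities, a randomized minimum spanning tree, a
    ghost-neighbor update of each node's response function, and the exact tree
    sweep on the result. Monte Carlo simulation, exhaustive enumeration, and a
    bond-percolation sampler provide independent ground truth, and synthetic
    generators (stars, paths, uniform random trees, hub trees, power-law
    configuration models) supply study networks. Results are tidy tibbles with
    broom-style tidiers and ggplot2 autoplot methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
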