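Package: nectarnet
Title: Macrostructure, Null Models and Interaction Drivers for Weighted
    Bat-Flower Pollination Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of weighted bipartite pollen-transport
    networks between flower-visiting bats and plants. Implements weighted
    macrostructure metrics (Barber modularity maximised with the DIRTLPAwb+
    label-propagation algorithm, complementary specialisation H2', and the
    weighted nestedness metric WNODA with its within- and between-module
    decomposition for compound topologies), Monte Carlo significance under
    the connectance-preserving vaznull null model, construction of
    interaction-probability matrices from species abundances, morphological
    specialisation indices, phenological and spatial overlap, and their
    comparison against observed networks by multinomial likelihood and AIC.
    Includes Chao1 sampling-completeness estimation, module-wise trait
    comparisons, and a synthetic bat-flower community generator for
    end-to-end validation and driver-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
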