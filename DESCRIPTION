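Package: grnland
Title: Fitness Landscapes of Gene Regulatory Networks by Multicanonical Monte Carlo
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and rare-event sampling of small gene regulatory
    networks (GRNs) modelled as signed directed graphs with sigmoidal
    discrete-time expression dynamics. Provides a Wang-Landau /
    entropic-sampling Monte Carlo engine that samples networks nearly
    uniformly across fitness, estimating the relative number of networks
    per fitness bin (the "fitness landscape"), together with downstream
    analyses of bistability and hysteresis, robustness against input and
    internal noise, mutational robustness under edge deletion, edge
    addition and gene knockout, and a census of three-gene feedback and
    feedforward loop motifs. A brute-force enumeration oracle validates
    the sampler on small systems.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
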