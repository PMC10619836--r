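Package: allosim
Title: Evolutionary Agent-Based Simulation of Large-Theropod Foraging Ecology
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A seeded, configurable agent-based simulator of scavenging
    versus predation in a population of large endothermic theropods. Agents
    carry six heritable phenotypic traits (carcass detection range, fat
    storage, carcass-site dominance, bite force, hearing, binocular vision),
    forage on a toroidal landscape shared with huntable prey and massive,
    decaying sauropod carcasses, and run field-metabolic-rate energy budgets
    that couple body mass to daily meat requirements. A statistics layer
    computes lifetime-reproductive-success distributions, trait-stratified
    reproduction probabilities and fitness ratios, offspring-binned trait
    summaries, and yearly phenotype-composition time series.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
Roxygen: list(markdown = TRUE, load = "source")
RoxygenNote: 7.3.3
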