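Package: pheronet
Title: Qualitative Petri-Net Modelling of the Yeast Pheromone Response Pathway
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A discrete (qualitative) Petri-net engine and a curated model of
    the Saccharomyces cerevisiae pheromone response pathway, from receptor
    binding through the Ste5-scaffolded MAPK cascade to release of the
    transcription factor Ste12.  Reaction thresholds (kd values) are modelled
    as randomized integer arc weights; ensembles of weight configurations are
    swept over grids of initial protein concentrations and each network's
    mating response is classified.  Edge weights that determine a positive
    response are mined with gain-ratio (C4.5-style) decision trees under
    stratified cross-validation, with per-level attribute summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
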