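Package: netoverlap
Title: First-Degree Interactome Overlap Statistics for Gene-List
    Prioritisation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Links hits from a model-organism modifier screen to human
    disease-association (GWAS) candidates through a protein-protein
    interaction network. Builds +1 interactomes (a gene set plus all
    first-degree physical interactors), scores the overlap between a
    screen gene's +1 interactome and a fixed GWAS +1 interactome against
    size-matched random interactomes by Monte Carlo simulation, and
    corrects for the hub bias of screen hits via connectivity-rank
    binning and log-log slope comparison. Includes a BioGrid
    tab-delimited reader, orthologue selection with binomial enrichment
    testing, and a synthetic-data generator with planted signal so every
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    graphics,
    stats,
    utils,
    tools,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
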