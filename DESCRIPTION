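Package: phyllocom
Title: Structure and Assembly Analysis of Phyllosphere Microbial Communities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Community-ecology inference for amplicon sequence variant (ASV)
    tables from plant phyllosphere surveys, built around a wild-versus-cultivated
    rice study design. Provides core-microbiome identification by prevalence and
    abundance thresholds, alpha/beta diversity with ordination and PERMANOVA,
    differential-abundance enrichment classification, thresholded Spearman
    co-occurrence networks with topology, hub, and stability metrics, Sloan
    neutral community model fitting, the five-process null-model framework
    (beta nearest-taxon index and abundance-based Raup-Crick), and Levins'
    niche breadth. A synthetic-data module generates ASV tables, metadata, and
    phylogenies with known ground truth (neutral, selective, dispersal-limited,
    and planted-correlation regimes) so that every stage can be validated
    end-to-end against controllable inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    vegan,
    ape,
    igraph,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    picante,
    optparse
Config/testthat/edition: 3
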