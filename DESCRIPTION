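Package: gutmgwas
Title: Metagenome-Wide Association Analysis of the Hypertensive Gut Microbiome
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested re-implementation of a shotgun-metagenomics case/control
    analysis of gut microbiota in primary hypertension: length- and
    depth-normalised gene relative-abundance profiles, rarefied gene richness
    and Shannon diversity, Bray-Curtis distance and distance-based redundancy
    analysis, metagenome-wide association (Mann-Whitney with
    Benjamini-Hochberg FDR) to call marker genes, canopy clustering of
    co-abundant markers into metagenomic linkage groups (MLGs) with
    vote-based taxonomic assignment, Spearman co-occurrence networks,
    KEGG-ortholog and pathway functional contrasts (TMA-production and
    SCFA-production enzyme panels), blood-pressure severity staging, and
    random-forest classification of disease status from MLG profiles.
    Includes a synthetic marker-gene cohort generator with planted
    species-level co-abundance structure so every stage is testable without
    the original sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vegan,
    randomForest,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    mclust,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
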