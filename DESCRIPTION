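Package: ventcomp
Title: Comparative Genomics and Population Structure of Hydrothermal-Vent Annelids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the comparative and population-genomic analyses used in
    chromosome-level genome studies of deep-sea vent annelids: reciprocal-best-hit
    orthology from Smith-Waterman protein scores, species-pair-averaged amino-acid
    composition matrices and their principal component analysis, Gly-X-Y collagen
    repeat scanning with positional proline statistics, tube-composition distance
    screening, bacterial-contamination classification of taxon-labelled similarity
    hits, gene-family and GO-term enrichment with Benjamini-Hochberg control,
    variant filtering with global and windowed (local) genotype PCA, observed
    heterozygosity, neighbor-joining window trees, and orthology-anchored
    macrosynteny (Oxford grids, ancestral-linkage-group painting and fusion
    detection). Synthetic-data generators with known truth accompany every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    ape,
    vcfR,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
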