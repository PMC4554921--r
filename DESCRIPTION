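Package: SpectroGold
Title: Spectral-Count Proteomics of Subcellular Fractions and Immunogold
    Zonal Quantification
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A pipeline for organelle proteomics by label-free spectral
    counting and for stereological quantification of immunogold electron
    micrographs. Collapses redundant protein identifications into a minimal
    (parsimony) set of protein groups from peptide-spectrum matches, labels
    peptides unique or shared, apportions shared spectra to cognate proteins
    in proportion to their unique evidence, and normalizes to percent of
    total peptides per subcellular fraction with replicate averaging.
    Downstream tools provide hierarchical clustering with uncentred
    correlation distance and Cluster 3.0 compatible CDT/GTR export,
    fraction-enrichment classification, abundance ranking, and functional
    category rollups. A companion module quantifies colloidal-gold particle
    distributions around membrane traces in electron micrographs: signed
    point-to-polyline distances, fixed-increment band histograms,
    reference-band derivation, five-area particle classification, and
    aggregated percentage distributions with antibody controls. A seeded
    synthetic-data generator produces ground-truth proteomes, PSM tables and
    gold scenes for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    Biostrings,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
biocViews: Proteomics, MassSpectrometry, Clustering, Software
RoxygenNote: 7.3.3
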