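Package: coPrecip
Title: Enrichment Analysis of Protein and mRNA Co-Precipitation Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative enrichment analysis for affinity-purification
    experiments scored against a negative-control bait. Implements batch
    total-intensity normalization, replicate averaging and ratio-to-control
    scoring of AP-MS co-immunoprecipitation data (with explicit handling of
    infinite and undefined ratios, peptide-support filtering and fold-change
    tiers), interactome set arithmetic (exclusivity, pairwise bait-vs-bait
    comparison, functional-category summaries), and transcript-level
    enrichment for RIP-seq/CLIP-seq counts (TPM and RPKM abundance measures,
    minimum-read and log2 fold filters, and a replicate-aware beta-binomial
    weighted-proportions test with Benjamini-Hochberg FDR control). A
    synthetic-data generator with ground-truth labels supports end-to-end
    testing without access to raw deposits. Motivated by studies of the
    Trypanosoma brucei EIF4E3/EIF4G4 and EIF4E4/EIF4G3 eIF4F-like complexes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports: methods, stats, utils, tools, S4Vectors, SummarizedExperiment, yaml
Suggests: testthat (>= 3.0.0), jsonlite, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Proteomics, Transcriptomics, MassSpectrometry, Sequencing, Software
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'IntensityExperiment.R'
    'coPrecip-package.R'
    'io.R'
    'ipms.R'
    'pipeline.R'
    'rip.R'
    'sets.R'
    'simulate.R'
    'utils.R'
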