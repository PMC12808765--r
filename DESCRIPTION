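Package: GRsig
Title: Glucocorticoid Receptor Activity Signatures from Time-Course
    Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derives a glucocorticoid receptor (GR) activity gene signature
    from dexamethasone time-course RNA-seq contrasts (shared-effect filtering
    across cell-line models, k-means clustering of mean-centered logCPM,
    onset-based cluster selection) and evaluates it clinically by signature
    scoring, quartile stratification, Kaplan-Meier/Cox survival analysis and
    cross-stratum expression comparison.  Companion modules filter ChIP-seq
    peak sets and assign peaks to genes through GREAT-style basal-plus-
    extension regulatory domains, run pre-ranked gene-set enrichment with a
    gene-permutation null, normalize TMT reporter intensities with protein
    rollup and differential abundance, and test drug-combination synergy
    with a Bliss-style combination index.  A synthetic-data generator with
    planted ground truth emulates every input so the full pipeline is
    testable without external accessions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    survival,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    fgsea,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: GeneExpression, RNASeq, Normalization, DifferentialExpression,
    GeneSetEnrichment, Survival, ChIPSeq, Proteomics, Software
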