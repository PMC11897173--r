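Package: pangene
Title: Pan-Genome Family Classification, Structural-Variant Impact and
    Expression Analysis for Fungal Genome Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for family-level pan-genome analysis of small panels of
    fungal genomes: orthogroup occupancy classification into core, softcore,
    dispensable and private bands; pan/core rarefaction curves by genome-order
    permutation; shared-family (Venn) pattern counts; annotation of structural
    variants (insertions, deletions, duplications, inversions, translocation
    breakends) with gene-level impact classes (high, moderate, low, modifier)
    under an explicit rule table; count-based differential expression with
    Benjamini-Hochberg control; expression level and breadth profiles by
    pan-genome category; association testing between SV-affected homologs and
    differential expression; hypergeometric GO term enrichment; and a
    synthetic-data generator that plants ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    VariantAnnotation,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
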