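Package: kinmeth
Title: Kinship-Aware Differential DNA Methylation Analysis for Reduced
    Representation Bisulfite Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for associating per-CpG methylation counts
    from reduced representation bisulfite sequencing (RRBS) with individual
    phenotypes in small, pedigreed populations. Reads CGmap methylation call
    files, applies coverage filtering and sample uniting, computes bisulfite
    conversion efficiency from an unmethylated lambda spike-in, builds the
    pedigree-based additive relationship matrix, and fits a per-site binomial
    mixed model by penalized quasi-likelihood with a kinship random effect.
    Significant differentially methylated sites are called by a dual-percentile
    outlier rule, aggregated into distance-based clusters, annotated against a
    gene annotation (promoter, exon, intron, intergenic), and carried into
    gene-set hypergeometric enrichment and confidence-filtered interaction
    networks. Includes a synthetic-data generator that emulates a multi-tissue
    RRBS study design with kinship structure for calibration and power checks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    igraph,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
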