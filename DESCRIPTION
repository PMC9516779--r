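Package: epicrispr
Title: Chromatin-Context Analysis of Multicopy CRISPR-Cas9 Target Sites
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Discovers identical multicopy CRISPR-Cas9 target sites (20-nt
    protospacer plus NGG PAM) across a genome, annotates each genomic copy
    with DNA-methylation domains (CG/CHG/CHH weighted levels in 100-bp
    windows), chromatin accessibility and quantitative chromatin-feature
    signal, quantifies editing efficiency and mutation-outcome classes from
    amplicon sequencing reads, and associates efficiency and repair outcomes
    with chromatin features (ANOVA/Tukey grouping, hierarchical clustering,
    Spearman correlation, Mann-Whitney and Kruskal-Wallis comparisons).
    Includes a seeded synthetic-data generator (genomes with planted target
    families, per-cytosine methylation calls, accessibility peaks, signal
    tracks, and edited amplicon read sets with truth logs) so the whole
    pipeline is testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Biostrings,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    rtracklayer,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
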