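Package: ampedit
Title: Editing-Outcome Quantification for CRISPR Amplicon Sequencing and
    Pooled Variant Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing CRISPR gene-editing experiments read out by
    amplicon sequencing. Implements whitelist-based enrichment scoring for
    pooled saturation-mutagenesis (NNK) and combinatorial protein variant
    screens sorted into HDR-positive and HDR-negative pools; a multi-amplicon
    read classifier (global affine-gap alignment against wild-type, HDR and
    gene-conversion references) that partitions editing outcomes into
    WT/HDR/gene-conversion/indel species; statistical partitioning of indel
    species into MMEJ versus NHEJ from paired POLQ-knockdown samples
    (one-sided Welch tests with Benjamini-Hochberg FDR control); colony
    (CFU-seq) genotype calling with depth and allele-fraction filters;
    verification of protein-interface hydrogen-bond contacts from coordinate
    files; and synthetic-data generators with known ground truth for every
    pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    bio3d,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
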