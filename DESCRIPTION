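Package: gallmir
Title: miRNA Microarray Analysis and Target Prediction for Unannotated
    Insect Transcriptomes
Version: 0.3.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline for single-channel miRNA microarray
    differential expression across resistant/susceptible Galleria mellonella
    cohorts and for miRNA target prediction in a transcriptome without
    genome annotation. Covers background subtraction and iterative MA-plot
    lowess normalization, paired t / one-way ANOVA testing with
    Benjamini-Hochberg correction, cohort set bookkeeping (pairwise
    contrasts, duplicate exclusion, Venn partitioning), ORF finding and
    3'UTR extraction from assembled contigs, seed-match scanning, and a
    nearest-neighbor dynamic program for the minimum free energy of
    intermolecular miRNA:mRNA hybrids. A synthetic-data generator plants
    machine-readable ground truth (ORFs, seed sites, fold changes) so every
    stage has a recovery test.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
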