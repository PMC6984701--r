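Package: intrograph
Title: RNA-Seq-Based Introgression Mapping for Synthetic Hexaploid
    Wheat Backcross Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects chromosomal segments introgressed from synthetic
    hexaploid wheat (durum x Aegilops tauschii) into backcross-derived
    bread wheat lines using transcriptome-based SNP genotyping. Calls
    genotypes from per-site allele counts with a depth/allele-fraction
    rule, builds the synthetic donor SNP set by combining the tetraploid
    and diploid parents' read counts, differences each selected line
    against its recurrent cultivar, assigns differing SNPs to the donor,
    counts SNPs per chromosome, segments donor-origin markers into
    introgression blocks, and draws graphical genotypes. Includes a
    forward simulator of the BCnFm backcross breeding scheme (meiosis
    under the Haldane map, phenotype-based selection on a heading-date
    QTL model, RNA-seq-like depth and error sampling) with full
    ground-truth segment bookkeeping for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    IRanges,
    S4Vectors,
    ggplot2,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
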