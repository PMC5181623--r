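Package: cpgherit
Title: Regional SNP Heritability and Genomic Context of CpG Methylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates, for each CpG methylation site, the proportion of
    phenotypic variance explained by SNPs within a +/-1 Mb window (regional
    genomic heritability) by restricted maximum likelihood on a VanRaden
    genomic relationship matrix, with significance assessed by a 50:50
    chi-square boundary-mixture likelihood-ratio test.  Includes genotype
    quality control (call-rate, exact Hardy-Weinberg, MAF and differential
    missingness filters, X-chromosome inbreeding sex check), methylation
    M-value transformation and covariate adjustment, CpG island / shore /
    shelf / sea and genic-context annotation, per-SNP methylation QTL
    association with cis/trans accounting, contextual group comparisons,
    and a synthetic-data generator with known per-site heritability truth
    for calibration and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    vcfR,
    IRanges,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
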