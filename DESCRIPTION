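Package: gbcroh
Title: Genomic Breed Composition and Runs-of-Homozygosity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for assessing breed purity and inbreeding from SNP
    genotypes. Estimates per-animal genomic breed composition (GBC) by
    maximum-likelihood admixture over reference breed allele frequencies,
    classifies purebred and two-breed crossbred animals, detects runs of
    homozygosity (ROH) with a sliding-window scanner, summarizes ROH-based
    inbreeding (F_ROH) by length class and chromosome, dates autozygous
    segments by expected segment length, and locates ROH islands from
    per-SNP incidence. Includes a synthetic-data generator (hierarchical
    Balding-Nichols breed frequencies, Hardy-Weinberg purebred and
    F1/F2/backcross genotypes, planted autozygous segments) with known
    ground truth, PLINK text and binary genotype input/output, and an
    end-to-end reproducible pipeline.
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
    ape,
    yaml,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
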