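Package: pgxcombine
Title: Combined SNV and Copy-Number Analysis of Pharmacogenes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reusable pipeline for joint analysis of single-nucleotide
    variants and copy-number variation in pharmacogenes: variant-level QC
    (missingness, minor allele frequency, Hardy-Weinberg equilibrium),
    EM-based haplotype frequency estimation with linkage-disequilibrium
    statistics and confidence-interval haplotype blocks, sparse Bayesian
    learning segmentation of array-CGH log2-ratio tracks with backward
    elimination and five-level copy-number classification, table-driven
    star-allele diplotype assignment, and combined diplotype-by-CNV
    frequency tables. Includes a synthetic-data module that generates
    genotype and probe-level inputs with known truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    optparse,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
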