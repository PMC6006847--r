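Package: haplodenovo
Title: Haplotype-Resolved Filtering and Phasing of De Novo Mutations in
    Linked-Read Trio Sequencing
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Filters candidate de novo mutations (DNMs) in a
    parent-parent-child trio sequenced with barcoded linked reads.
    Reads are grouped into long molecules by barcode, each molecule is
    assigned to one of the two haplotypes of its phase block by a
    majority vote over phased heterozygous sites, and a haploid
    genotype is called for each of the six trio haplotypes at every
    candidate site.  Candidates whose parental haplotypes carry the
    alternate allele, or whose haploid calls are internally
    inconsistent, are removed as inherited-variant artifacts caused by
    allele-specific coverage dropout; the remainder are reported as
    high- or low-confidence DNMs with parent-of-origin, including
    hemizygous handling of the non-pseudoautosomal X chromosome.  A
    linked-read trio simulator with full ground truth makes the whole
    pipeline testable without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    Rsamtools,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    jsonlite,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
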