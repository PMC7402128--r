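Package: qtlallele
Title: QTL-Allele Matrix Analysis of Stress-Tolerance Traits in Germplasm Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for dissecting stress-tolerance traits in inbred
    germplasm panels: membership-index phenotyping from replicated
    stress/non-stress trials with tolerant and sensitive checks, assembly of
    multi-allele haplotype-block (SNPLDB) markers from SNP genotypes,
    restricted two-stage multi-locus multi-allele association scans with the
    total genetic contribution capped at the trait heritability, organization
    of detected QTL-alleles into accession-by-locus matrices with
    subpopulation differentiation tests, and prediction of optimal biparental
    crosses by progeny simulation.  Includes a synthetic-population generator
    emulating an inbred panel with LD-block structure, two drifted
    subpopulations, additive multi-allele QTL and replicated two-regime trial
    data, so that the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
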