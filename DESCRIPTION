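Package: xcistate
Title: X-Chromosome Inactivation Status Calling from Allelic Expression,
    Promoter Methylation and Sex-Biased Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream inference of X-chromosome inactivation (XCI) status
    in bulk and single-cell transcriptomic data. Provides filtering and
    scoring of allele-specific expression (ASE) at heterozygous SNPs,
    detection and estimation of XCI skewing, binomial upper bounds on the
    fraction of cells with loss of XCI, sex-biased expression testing,
    promoter methylation categorisation, a combined escape/inactive
    classifier, and inference of the inactive-X haplotype in single cells
    from XIST and anchor-gene allelic reads. A synthetic-cohort generator
    with known ground truth (true XCI status, skewing, leak fraction,
    karyotype) makes every stage testable without access to restricted
    human data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
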