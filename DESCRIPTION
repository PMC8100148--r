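Package: xciscope
Title: Allele-Specific Expression Analysis of X-Chromosome Dosage
    Compensation in Preimplantation Embryo scRNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies X-linked dosage compensation in single-cell RNA-seq
    of preimplantation embryos from allele-specific expression. Implements
    embryo sexing from Y-linked expression, embryo-genotype construction and
    per-cell mono/biallelic SNP and gene calling, quantification of X
    inactivation progression, a test discriminating X inactivation from X
    dampening, assessment of active-X upregulation, and X:autosome expression
    ratio estimation with a gene-resampling bootstrap. Includes a synthetic
    data generator that emulates the allelic count and expression structure
    of preimplantation embryo cohorts under configurable dosage-compensation
    regimes, so every stage of the pipeline can be validated by parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    data.table,
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
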