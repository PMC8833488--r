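Package: lofseg
Title: Pedigree-Aware Prioritization of Rare Loss-of-Function Variants in
    Cancer Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for family-based germline variant prioritization in
    autosomal-dominant cancer pedigrees: extended-PED pedigree parsing with
    phenotype events and case/possible-carrier/control role assignment,
    annotated multi-sample VCF ingestion with quality and allele-frequency
    filtering, per-family dominant-model segregation filtering of rare
    loss-of-function variants with last-exon and non-coding exclusions and
    CADD tiering, maximum-entropy 3' splice-site scoring with de novo
    acceptor scanning, HGVS frameshift protein-consequence calling, carrier
    case-control association (odds ratio with Woolf confidence interval),
    and a Mendelian cohort simulator that generates PED/VCF/gene-model/CDS
    fixtures with planted variants and known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    vcfR
Suggests:
    optparse,
    seqinr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
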