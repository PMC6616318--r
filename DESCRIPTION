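Package: xydosage
Title: Dosage Compensation Analysis for Y-Deletion Mutant Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for detecting immediate dosage compensation
    of X-linked genes in panels of Y-chromosome deletion mutants of dioecious
    plants such as Silene latifolia. Builds a deletion map of the Y chromosome
    from PCR marker presence/absence data by breakpoint-minimising marker
    ordering, calls deleted Y-linked genes and hemizygous autosomal genes from
    expression and read-coverage evidence, computes phenotype-matched relative
    expression statistics by gene category (X with deleted or retained Y
    gametolog, Y, autosomal), localises the compensation-triggering Y region
    from the deletion map, and includes companion analyses of bisulfite
    methylation and parent-of-origin allele-specific expression. A synthetic
    data generator with planted ground truth makes every stage testable
    without external sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
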