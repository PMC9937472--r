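Package: pedloss
Title: Family-Based Variant Prioritization for Pregnancy-Loss Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Inheritance-mode classification and variant prioritization for
    whole-genome sequencing of families with recurrent pregnancy loss.
    Reads multi-sample VCFs and extended pedigrees (pregnancy outcome and
    gestational age), classifies each variant by inheritance mode (de novo,
    inherited autosomal dominant, compound heterozygous, X-linked recessive)
    from parental genotypes, applies a prioritization ladder (population
    rarity, predicted impact, loss-versus-live-birth contrast, pLI/LOEUF
    constraint, control-homozygote exclusion, optional phenotype gene list),
    and computes de novo burden and gene-recurrence enrichment statistics.
    Includes a synthetic multi-family cohort simulator with planted variants
    and ground-truth tables so the whole pipeline is testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table (>= 1.14),
    vcfR,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
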