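#!/usr/bin/env Rscript

# Stage 2: sample QC and inheritance-mode classification.
#
# Reads the cohort VCF + pedigree from stage 1, runs the genotype-based
# sex-concordance check, and classifies every (variant, offspring) pair
# into de novo / autosomal dominant / compound het / X-linked recessive
# from the parental genotypes. Live births are classified too: the
# loss-versus-live-birth contrast in stage 3 needs them.

suppressPackageStartupMessages({
  library(pedloss)
  library(data.table)
})

ped <- read_pedigree("results/cohort/cohort.ped")
vs <- read_variants("results/cohort/cohort.vcf", ped)

sexes <- sex_check(vs, ped)
fwrite(sexes, "results/sex_check.tsv", sep = "\t")
n_disc <- sum(!sexes$concordant)
message("sex check: ", nrow(sexes), " samples, ", n_disc, " discordant",
        if (n_disc > 0) " (flagged for exclusion)" else "")

calls <- classify_cohort(vs, ped)
fwrite(calls, "results/inheritance_calls.tsv", sep = "\t")
message("inheritance calls by mode:")
print(calls[, .N, by = mode])
amb <- attr(calls, "comphet_ambiguous")
message(nrow(amb), " ambiguous-phase comp-het sites quarantined")
fwrite(amb, "results/comphet_quarantine.tsv", sep = "\t")
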