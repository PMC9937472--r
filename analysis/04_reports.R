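#!/usr/bin/env Rscript

# Stage 4: cohort summary tables.
#
# Counts of candidate SNVs and distinct genes by family and pregnancy-loss
# epoch (total row deduplicated across families), counts by inheritance
# mode and epoch (compound-het pairs contribute two SNVs), and the
# clinical-style compound-het detail table restricted to pairs seen in
# losses only and never homozygous in population controls.

suppressPackageStartupMessages({
  library(pedloss)
  library(data.table)
})

ped <- read_pedigree("results/cohort/cohort.ped")
cand <- fread("results/candidates.tsv")

tab_epoch <- counts_by_family_epoch(cand)
fwrite(tab_epoch, "results/counts_by_family_epoch.tsv", sep = "\t")
message("SNVs (genes) in losses by family and epoch:")
print(dcast(tab_epoch, family_id ~ epoch,
            value.var = c("n_snvs", "n_genes")))

tab_mode <- counts_by_mode(cand)
fwrite(tab_mode, "results/counts_by_mode.tsv", sep = "\t")
message("candidate SNVs by inheritance mode:")
print(tab_mode[, .(n_snvs = sum(n_snvs)), by = mode])

ch <- comphet_report(cand, ped)
fwrite(ch, "results/comphet_report.tsv", sep = "\t")
message(nrow(ch), " compound-het SNVs retained (loss-only, ",
        "absent from control homozygotes), e.g.:")
print(head(ch, 4))
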