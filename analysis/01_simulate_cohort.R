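#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study cohort.
#
# Three families emulating the study design: two parents, two live births
# and four sampled losses each (one stillbirth at 20w0d, fetal deaths at
# 15w6d/16w0d/13w6d), plus an unsampled 6w6d embryonic loss per family.
# Each sampled loss carries planted variants under every inheritance mode
# (4 de novo with half their impact mass on loss-of-function classes, 2
# dominant, 1 compound-het pair, 1 X-linked recessive) over a 10,000-site
# ascertained background. Writes the VCF, pedigree and truth tables.

suppressPackageStartupMessages(library(pedloss))

out_dir <- "results/cohort"
cfg <- sim_config(seed = 101L)
sim <- simulate_cohort(cfg, dir = out_dir)

n_samples <- sum(sim$pedigree$has_sample)
message("cohort: ", length(unique(sim$pedigree$family_id)), " families, ",
        n_samples, " sampled individuals (",
        sum(sim$pedigree$outcome == "loss" & sim$pedigree$has_sample),
        " losses, ",
        sum(sim$pedigree$outcome == "live_birth" & sim$pedigree$has_sample),
        " live births)")
message("variants: ", nrow(sim$vs$variants), " (",
        sum(sim$truth$planted_mode != "background"), " planted, ",
        sum(sim$truth$planted_mode == "background"), " background)")
message("written: ", sim$vcf, ", ", sim$ped,
        ", truth_variants.tsv, expected_calls.tsv")
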