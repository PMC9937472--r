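#' Counts of SNVs and genes by family and pregnancy-loss epoch
#'
#' The per-family cells count distinct variant keys and distinct gene
#' symbols among candidate calls carried by that family's samples of each
#' epoch; the `Total` row counts distinct keys/genes cohort-wide per
#' epoch, so overlapping SNVs/genes across families are counted once and
#' the total can be smaller than the column sum. SNVs without a gene
#' symbol count toward `n_snvs` but not `n_genes`.
#'
#' @param candidates Candidate table from [prioritize()].
#' @param dedupe Count a variant carried by several samples of the same
#'   family/epoch once (default TRUE); with FALSE, (variant, sample) rows
#'   are counted.
#' @param epochs Epochs to tabulate; defaults to the three loss epochs.
#' @return data.table: `family_id` (including `"Total"`), `epoch`,
#'   `n_snvs`, `n_genes`.
#' @export
counts_by_family_epoch <- function(candidates, dedupe = TRUE,
                                   epochs = c("embryonic_loss", "fetal_death",
                                              "stillbirth")) {
  cand <- as.data.table(candidates)[epoch %in% epochs]
  count_cell <- function(d) {
    if (dedupe) {
      data.table(n_snvs = uniqueN(d$variant_key),
                 n_genes = uniqueN(d$gene[!is.na(d$gene)]))
    } else {
      data.table(n_snvs = nrow(unique(d[, .(variant_key, sample_id)])),
                 n_genes = uniqueN(d$gene[!is.na(d$gene)]))
    }
  }
  grid <- CJ(family_id = unique(cand$family_id), epoch = epochs)
  per_fam <- cand[, count_cell(.SD), by = .(family_id, epoch)]
  per_fam <- per_fam[grid, on = c("family_id", "epoch")]
  per_fam[is.na(n_snvs), `:=`(n_snvs = 0L, n_genes = 0L)]
  total <- cand[, count_cell(.SD), by = epoch]
  total <- total[data.table(epoch = epochs), on = "epoch"]
  total[is.na(n_snvs), `:=`(n_snvs = 0L, n_genes = 0L)]
  total[, family_id := "Total"]
  out <- rbind(per_fam, total, use.names = TRUE)
  setcolorder(out, c("family_id", "epoch", "n_snvs", "n_genes"))
  setorder(out, family_id, epoch)
  out[]
}

#' Counts of candidate SNVs by inheritance mode
#'
#' One row per mode, one column set per (family, epoch); distinct
#' (variant, sample) pairs are counted, so a compound-het pair
#' contributes 2 SNVs. The engine's precedence makes modes disjoint per
#' (variant, sample), so the mode counts partition the candidate calls.
#'
#' @param candidates Candidate table from [prioritize()].
#' @return data.table: `mode`, `family_id`, `epoch`, `n_snvs`.
#' @export
counts_by_mode <- function(candidates) {
  cand <- as.data.table(candidates)
  if (nrow(cand) == 0L)
    return(data.table(mode = character(), family_id = character(),
                      epoch = character(), n_snvs = integer()))
  out <- unique(cand[, .(variant_key, sample_id, mode, family_id, epoch)])[,
    .(n_snvs = .N), by = .(mode, family_id, epoch)]
  setorder(out, mode, family_id, epoch)
  out[]
}

#' Compound-heterozygote detail report
#'
#' One row per SNV of every retained pair (a pair is retained when its
#' calls are flagged loss-only and absent from control homozygotes), with
#' the carrier described as in a clinical table: family, sample
#' description (sex, epoch, gestational age), variant as
#' `chrom:pos:ref:alt`, impact, gene; rows grouped by pair.
#'
#' @param candidates Candidate table from [prioritize()].
#' @param pedigree Pedigree table.
#' @return data.table: `family_id`, `sample_id`, `sample_description`,
#'   `snv`, `impact`, `gene`, `pair_id`.
#' @export
comphet_report <- function(candidates, pedigree) {
  cand <- as.data.table(candidates)
  keep <- cand[mode == "comp_het" & loss_only == TRUE &
                 control_hom_absent == TRUE]
  if (nrow(keep) == 0L)
    return(data.table(family_id = character(), sample_id = character(),
                      sample_description = character(), snv = character(),
                      impact = character(), gene = character(),
                      pair_id = character()))
  label <- c(missense = "Missense", frameshift = "Frameshift",
             inframe_indel = "In-frame indel", stop_gained = "Stop gained",
             stop_retained = "Stop retained", splice_region = "Splice region",
             other = "Other")
  out <- keep[, .(
    family_id, sample_id,
    sample_description = describe_individual(pedigree, sample_id),
    snv = variant_key, impact = label[impact], gene, pair_id)]
  setorder(out, family_id, sample_id, pair_id, snv)
  out[]
}

#' Filter-ladder audit trail
#'
#' Counts of candidate calls surviving each successive flag conjunction
#' of the prioritization ladder, from all candidates down to the full
#' ladder (rarity and impact define candidacy, then loss-only contrast,
#' constraint-based pathogenicity, control-homozygote absence, and the
#' optional phenotype gene list). Counts are monotone non-increasing.
#'
#' @param candidates Candidate table from [prioritize()].
#' @return data.table: `step`, `n_calls`, `n_snvs` (distinct variants).
#' @export
filter_ladder_summary <- function(candidates) {
  cand <- as.data.table(candidates)
  steps <- list(
    all                     = rep(TRUE, nrow(cand)),
    `rare`                  = cand$is_rare,
    `rare+impactful`        = cand$is_rare & cand$is_impactful,
    `rare+impactful+loss_only` =
      cand$is_rare & cand$is_impactful & cand$loss_only,
    `rare+impactful+loss_only+pathogenic` =
      cand$is_rare & cand$is_impactful & cand$loss_only & cand$is_pathogenic,
    `rare+impactful+loss_only+pathogenic+control_hom_absent` =
      cand$is_rare & cand$is_impactful & cand$loss_only &
      cand$is_pathogenic & cand$control_hom_absent,
    `full_ladder` =
      cand$is_rare & cand$is_impactful & cand$loss_only &
      cand$is_pathogenic & cand$control_hom_absent & cand$in_phenotype_genes
  )
  rbindlist(lapply(names(steps), function(s) {
    sel <- steps[[s]] & !is.na(steps[[s]])
    data.table(step = s, n_calls = sum(sel),
               n_snvs = uniqueN(cand$variant_key[sel]))
  }))
}
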