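#' Rarity filter
#'
#' A variant passes when every available population allele frequency is
#' strictly below the ceiling. Missing frequency counts as 0 (a novel
#' allele is maximally rare); the boundary value itself fails
#' (`AF = 0.001` is not `< 0.001`).
#'
#' @param gnomad_af,topmed_af Numeric vectors of population allele
#'   frequencies (NA = not observed).
#' @param af_max Strict upper bound, default 0.001.
#' @return Logical vector.
#' @export
#' @examples
#' filter_rare(c(0.0005, 0.001, NA))  # TRUE FALSE TRUE
filter_rare <- function(gnomad_af, topmed_af = NULL, af_max = 0.001) {
  stopifnot(af_max > 0, af_max <= 1)
  g <- fifelse(is.na(gnomad_af), 0, gnomad_af)
  ok <- g < af_max
  if (!is.null(topmed_af)) {
    t <- fifelse(is.na(topmed_af), 0, topmed_af)
    ok <- ok & t < af_max
  }
  ok
}

#' Impact filter
#'
#' Keeps protein-altering impact classes: missense, frameshift, in-frame
#' insertion/deletion, stop gained/retained, and splice region. Anything
#' else (synonymous, intergenic, ... mapped to `other`) or missing fails.
#'
#' @param impact Character vector of impact classes.
#' @param impactful_classes The accepted set.
#' @return Logical vector.
#' @export
filter_impactful <- function(impact,
                             impactful_classes = default_config()$impactful_classes) {
  !is.na(impact) & impact %in% impactful_classes
}

#' Constraint-based pathogenicity filter
#'
#' A variant is flagged pathogenic when its gene is loss-of-function
#' intolerant on both constraint metrics: `pLI > pli_min` and
#' `LOEUF < loeuf_max`, both strict. Missing constraint fails (asserting
#' pathogenicity needs evidence, unlike rarity where absence of evidence
#' is the evidence).
#'
#' @param pli,loeuf Numeric vectors.
#' @param pli_min Strict lower bound on pLI, default 0.9.
#' @param loeuf_max Strict upper bound on LOEUF, default 0.36.
#' @return Logical vector.
#' @export
#' @examples
#' filter_pathogenic(c(0.95, 0.9, 0.95), c(0.30, 0.30, NA))  # TRUE FALSE FALSE
filter_pathogenic <- function(pli, loeuf, pli_min = 0.9, loeuf_max = 0.36) {
  !is.na(pli) & !is.na(loeuf) & pli > pli_min & loeuf < loeuf_max
}

#' Gene-list filter
#'
#' Membership of the variant's gene in a user-supplied phenotype gene
#' list. An empty list disables the filter (everything passes).
#'
#' @param gene Character vector of gene symbols.
#' @param genes Character vector of accepted symbols (possibly empty).
#' @return Logical vector.
#' @export
filter_gene_list <- function(gene, genes) {
  if (length(genes) == 0L) return(rep(TRUE, length(gene)))
  !is.na(gene) & gene %in% genes
}

#' Read a gene-list file
#'
#' One gene symbol per line; blank lines and `#` comments ignored.
#'
#' @param path File path, or `NULL` for an empty (disabled) list.
#' @return Character vector of symbols.
#' @export
read_gene_list <- function(path) {
  if (is.null(path)) return(character())
  if (!file.exists(path)) stop("gene list file not found: ", path)
  x <- trimws(readLines(path))
  x[!grepl("^(#|$)", x)]
}

#' Loss-versus-live-birth carriage contrast
#'
#' A variant is `loss_only` when at least one pregnancy-loss sample
#' carries the alt allele and no live-birth sample does, cohort-wide (a
#' live-birth carrier in any family refutes lethality regardless of which
#' family or mode bookkeeping produced the call). Carriage is
#' genotype-level: any alt-bearing genotype counts, whatever the call
#' mode. Parents do not enter the contrast.
#'
#' @param vs Variant container.
#' @param pedigree Pedigree table.
#' @return data.table: `variant_key`, `loss_only`, `carrier_epochs`
#'   (comma-joined sorted set of carrier epochs among products of
#'   conception), `n_loss_carriers`, `n_livebirth_carriers`.
#' @export
contrast_losses_vs_livebirths <- function(vs, pedigree) {
  ped <- as.data.table(pedigree)
  poc <- ped[outcome %in% c("loss", "live_birth") & has_sample == TRUE,
             .(sample_id = individual_id, outcome, epoch)]
  g <- as.data.table(vs$genotypes)[gt %in% .alt_bearing]
  g <- g[poc, on = "sample_id", nomatch = NULL]
  res <- g[, .(
    n_loss_carriers = sum(outcome == "loss"),
    n_livebirth_carriers = sum(outcome == "live_birth"),
    carrier_epochs = paste(sort(unique(epoch)), collapse = ",")
  ), by = variant_key]
  all_keys <- as.data.table(vs$variants)[, .(variant_key)]
  res <- res[all_keys, on = "variant_key"]
  res[is.na(n_loss_carriers), `:=`(n_loss_carriers = 0L,
                                   n_livebirth_carriers = 0L,
                                   carrier_epochs = "")]
  res[, loss_only := n_loss_carriers > 0L & n_livebirth_carriers == 0L]
  res[]
}

#' Control-homozygote check for a compound-het pair
#'
#' A pair survives only when neither member has ever been seen homozygous
#' in population controls (`gnomad_hom_count == 0` for both): a healthy
#' control homozygote refutes the biallelic-lethality hypothesis for the
#' gene. Missing counts are treated as 0 with a caveat.
#'
#' @param hom_a,hom_b Integer gnomAD homozygote counts of the two members.
#' @return data.table with `retained` and `caveat` logical columns.
#' @export
control_hom_check <- function(hom_a, hom_b) {
  caveat <- is.na(hom_a) | is.na(hom_b)
  a <- fifelse(is.na(hom_a), 0L, as.integer(hom_a))
  b <- fifelse(is.na(hom_b), 0L, as.integer(hom_b))
  data.table(retained = a == 0L & b == 0L, caveat = caveat)
}

#' Build the candidate table: calls plus the boolean filter ledger
#'
#' Every inheritance call on a rare, impactful variant becomes a
#' candidate row carrying the full flag ledger; nothing downstream of the
#' rarity/impact gate is silently dropped - reports select on flags.
#' Rarity uses `config$af_max` (compound-het calls use
#' `config$af_max_comphet`). `control_hom_absent` requires a zero gnomAD
#' homozygote count for the variant and, for compound-het members, for
#' the partner as well (missing counts treated as 0 and flagged by
#' `control_hom_caveat`). `in_phenotype_genes` applies the optional gene
#' list; `quality_pass` is carried from the engine (only de novo calls
#' can fail it).
#'
#' @param calls Calls from [classify_cohort()].
#' @param vs Variant container.
#' @param pedigree Pedigree table.
#' @param config Pipeline configuration.
#' @param gene_list Character vector of phenotype genes; default read
#'   from `config$gene_list_path` (empty = disabled).
#' @return data.table: the call columns plus `gnomad_af`, `topmed_af`,
#'   `impact`, `pli`, `loeuf`, `gnomad_hom_count`, the flags `is_rare`,
#'   `is_impactful`, `loss_only`, `is_pathogenic`, `control_hom_absent`,
#'   `control_hom_caveat`, `in_phenotype_genes`, and `carrier_epochs`.
#' @export
prioritize <- function(calls, vs, pedigree, config = default_config(),
                       gene_list = read_gene_list(config$gene_list_path)) {
  calls <- as.data.table(calls)
  if (nrow(calls) == 0L) {
    out <- cbind(calls, data.table(
      gnomad_af = numeric(), topmed_af = numeric(), impact = character(),
      pli = numeric(), loeuf = numeric(), gnomad_hom_count = integer(),
      is_rare = logical(), is_impactful = logical(), loss_only = logical(),
      is_pathogenic = logical(), control_hom_absent = logical(),
      control_hom_caveat = logical(), in_phenotype_genes = logical(),
      carrier_epochs = character()))
    return(out)
  }
  ann <- as.data.table(vs$variants)[, .(
    variant_key, gnomad_af, topmed_af, impact, pli, loeuf, gnomad_hom_count)]
  cand <- ann[calls, on = "variant_key"]
  af_ceiling <- fifelse(cand$mode == "comp_het",
                        config$af_max_comphet, config$af_max)
  cand[, is_rare := {
    g <- fifelse(is.na(gnomad_af), 0, gnomad_af)
    t <- fifelse(is.na(topmed_af), 0, topmed_af)
    g < af_ceiling & t < af_ceiling
  }]
  cand[, is_impactful := filter_impactful(impact, config$impactful_classes)]
  contrast <- contrast_losses_vs_livebirths(vs, pedigree)
  cand[contrast, on = "variant_key",
       `:=`(loss_only = i.loss_only, carrier_epochs = i.carrier_epochs)]
  cand[, is_pathogenic := filter_pathogenic(pli, loeuf,
                                            config$pli_min, config$loeuf_max)]
  # control homozygotes: own count, plus the partner's for comp-het members
  hom_of <- stats::setNames(ann$gnomad_hom_count, ann$variant_key)
  partner_hom <- hom_of[cand$partner_variant_key]
  chk <- control_hom_check(cand$gnomad_hom_count,
                           fifelse(cand$mode == "comp_het",
                                   as.integer(partner_hom), 0L))
  cand[, `:=`(control_hom_absent = chk$retained,
              control_hom_caveat = chk$caveat)]
  cand[, in_phenotype_genes := filter_gene_list(gene, gene_list)]
  # the rarity/impact gate defines candidacy; everything after is a flag
  cand <- cand[is_rare == TRUE & is_impactful == TRUE]
  setcolorder(cand, c(names(empty_calls())))
  cand[]
}
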