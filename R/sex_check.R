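#' Genotype-based sex-concordance check
#'
#' Infers each sample's sex from X-chromosome heterozygosity and compares
#' it with the pedigree. The statistic is the heterozygous fraction among
#' the sample's alt-bearing X genotypes (het / (het + hom_alt + hemi_alt)):
#' a female carries most of her rare X alleles heterozygously while a
#' hemizygous male can carry none, so the fraction separates the sexes
#' regardless of how rare-skewed the allele-frequency spectrum is
#' (X sites that are reference-homozygous in a sample carry no sex
#' information). Inference: female if the fraction exceeds
#' `het_female` (default 0.1), male if below `het_male` (default 0.02),
#' otherwise unknown. Samples with fewer than `min_sites` genotyped X
#' sites (default 200) or fewer than `min_alt_sites` alt-bearing X
#' genotypes (default 20) are reported as unknown with a warning, never a
#' hard failure. Unknown inferred or pedigree sex is concordant by
#' default; discordant samples are flagged for exclusion.
#'
#' @param vs Variant container (see [cohort_variants]).
#' @param pedigree Pedigree table.
#' @param config Pipeline configuration; thresholds under
#'   `config$sex_check`.
#' @return data.table with one row per sampled individual: `sample_id`,
#'   `n_sites` (genotyped X sites), `n_alt` (alt-bearing X genotypes),
#'   `n_het`, `het_fraction`, `inferred_sex`, `pedigree_sex`, `concordant`.
#' @export
sex_check <- function(vs, pedigree, config = default_config()) {
  ped <- as.data.table(pedigree)
  sc <- config$sex_check
  xvars <- as.data.table(vs$variants)[chrom == config$x_chrom, variant_key]
  g <- as.data.table(vs$genotypes)[variant_key %in% xvars & gt != "missing"]
  stats <- g[, .(
    n_sites = .N,
    n_alt = sum(gt %in% c("het", "hom_alt", "hemi_alt")),
    n_het = sum(gt == "het")
  ), by = sample_id]
  all_samples <- ped[has_sample == TRUE, individual_id]
  stats <- stats[data.table(sample_id = all_samples), on = "sample_id"]
  for (cn in c("n_sites", "n_alt", "n_het"))
    stats[is.na(get(cn)), (cn) := 0L]
  stats[, het_fraction := fifelse(n_alt > 0L, n_het / n_alt, NA_real_)]
  stats[, inferred_sex := fcase(
    n_sites < sc$min_sites | n_alt < sc$min_alt_sites, "unknown",
    het_fraction > sc$het_female, "female",
    het_fraction < sc$het_male, "male",
    default = "unknown"
  )]
  thin <- stats[n_sites < sc$min_sites, sample_id]
  if (length(thin) > 0L)
    warning("sex_check: fewer than ", sc$min_sites,
            " genotyped X sites for: ", paste(thin, collapse = ", "),
            "; sex reported as unknown")
  stats[, pedigree_sex := ped[match(stats$sample_id, individual_id), sex]]
  stats[, concordant := inferred_sex == "unknown" |
          pedigree_sex == "unknown" | inferred_sex == pedigree_sex]
  stats[]
}
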