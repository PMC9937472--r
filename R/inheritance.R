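#' @name inheritance_engine
#' @title Inheritance-mode classification
#'
#' @description
#' Each (variant, offspring) pair is classified from the trio's genotypes
#' into one of four modes:
#'
#' * `de_novo` - child heterozygous (hemizygous-alt on the male X), both
#'   parents reference; a quality gate (GQ, DP, allele balance, parental
#'   alt reads) separates confident calls from suspect ones.
#' * `autosomal_dominant` - child heterozygous, exactly one parent
#'   heterozygous and the other reference, so the parent of origin is
#'   unambiguous. Sites where both parents carry the allele are not
#'   called (origin would be ambiguous and such calls inflate counts).
#' * `comp_het` - two heterozygous sites in the same gene, one inherited
#'   from each parent. Without read-backed phasing, trans configuration is
#'   asserted only when parental carriage is disjoint between the two
#'   sites; pairs where a parent carries both alleles are quarantined.
#' * `x_linked_recessive` - male child hemizygous-alt with carrier mother
#'   and reference father; female child homozygous-alt with carrier
#'   mother and hemizygous-alt father.
#'
#' Precedence makes the per-(variant, sample) mode assignment disjoint:
#' a de novo call is never also emitted as dominant (the genotype
#' patterns are mutually exclusive anyway), and a variant that is a
#' member of an emitted compound-het pair is not also emitted as
#' dominant, so mode counts partition the call set.
NULL

.alt_bearing <- c("het", "hom_alt", "hemi_alt")

# quality gate for de novo calls; missing values fail (fail-closed: a de
# novo claim needs positive evidence). The allele-balance window applies to
# heterozygous children; a hemizygous-alt child is expected near AB = 1,
# so only the lower bound applies there.
denovo_quality_pass <- function(child, father, mother, qc) {
  ab <- fifelse(!is.na(child$ad_ref) & !is.na(child$ad_alt) &
                  (child$ad_ref + child$ad_alt) > 0L,
                child$ad_alt / (child$ad_ref + child$ad_alt), NA_real_)
  hemi <- child$gt == "hemi_alt"
  pass <- !is.na(child$gq) & child$gq >= qc$gq_min &
    !is.na(child$dp) & child$dp >= qc$dp_min &
    !is.na(father$dp) & father$dp >= qc$dp_min &
    !is.na(mother$dp) & mother$dp >= qc$dp_min &
    !is.na(ab) & ab >= qc$ab_min & (hemi | ab <= qc$ab_max) &
    !is.na(father$ad_alt) & father$ad_alt <= qc$parent_alt_max &
    !is.na(mother$ad_alt) & mother$ad_alt <= qc$parent_alt_max
  pass
}

# assemble the trio genotype table for one offspring
trio_table <- function(vs, child_id, father_id, mother_id) {
  g <- as.data.table(vs$genotypes)
  pick <- function(id, prefix) {
    gg <- g[sample_id == id,
            .(variant_key, gt, gq, dp, ad_ref, ad_alt)]
    setnames(gg, c("gt", "gq", "dp", "ad_ref", "ad_alt"),
             paste0(prefix, c("gt", "gq", "dp", "ad_ref", "ad_alt")))
    gg
  }
  trio <- pick(child_id, "child_")
  trio <- pick(father_id, "father_")[trio, on = "variant_key"]
  trio <- pick(mother_id, "mother_")[trio, on = "variant_key"]
  vars <- as.data.table(vs$variants)[, .(variant_key, chrom, pos, ref, alt, gene)]
  vars[trio, on = "variant_key"]
}

empty_calls <- function() {
  data.table(family_id = character(), sample_id = character(),
             epoch = character(), outcome = character(), mode = character(),
             variant_key = character(), chrom = character(), pos = integer(),
             ref = character(), alt = character(), gene = character(),
             parent_of_origin = character(),
             partner_variant_key = character(), pair_id = character(),
             quality_pass = logical())
}

#' Classify every variant of one family by inheritance mode
#'
#' Applies the four mode callers to every sampled offspring of the family
#' (losses and live births alike: live-birth calls are required by the
#' loss-versus-live-birth contrast downstream). Families without both
#' parents sampled are skipped with a message and yield zero calls.
#'
#' @param vs Variant container.
#' @param pedigree Pedigree table (the whole cohort is fine; only the
#'   requested family is used).
#' @param family One family id.
#' @param config Pipeline configuration; de novo gates under
#'   `config$denovo`.
#' @return data.table of calls: `family_id`, `sample_id`, `epoch`,
#'   `outcome`, `mode`, `variant_key`, `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `parent_of_origin`, `partner_variant_key`, `pair_id`,
#'   `quality_pass`, with attribute `comphet_ambiguous` (quarantined
#'   same-parent / ambiguous-phase gene-sample combinations).
#' @export
classify_family <- function(vs, pedigree, family, config = default_config()) {
  ped <- as.data.table(pedigree)[family_id == family]
  if (nrow(ped) == 0L) stop("unknown family: ", family)
  offspring <- ped[!is.na(father_id) & !is.na(mother_id) & has_sample == TRUE]
  sampled <- ped[has_sample == TRUE, individual_id]
  usable <- offspring[father_id %in% sampled & mother_id %in% sampled]
  if (nrow(usable) == 0L) {
    if (nrow(offspring) > 0L)
      message("classify_family: family ", family,
              " skipped (parents not both sampled)")
    res <- empty_calls()
    setattr(res, "comphet_ambiguous",
            data.table(gene = character(), variant_key = character(),
                       reason = character(), sample_id = character()))
    return(res)
  }
  qc <- config$denovo
  x_chrom <- config$x_chrom
  out <- vector("list", nrow(usable))
  ambiguous <- list()
  for (i in seq_len(nrow(usable))) {
    ch <- usable[i]
    trio <- trio_table(vs, ch$individual_id, ch$father_id, ch$mother_id)
    trio <- trio[child_gt != "missing" & father_gt != "missing" &
                   mother_gt != "missing"]
    if (nrow(trio) == 0L) { out[[i]] <- empty_calls(); next }
    on_x <- trio$chrom == x_chrom
    child_sex <- ch$sex

    calls <- list()
    # --- de novo ---
    dn <- trio[(!on_x & child_gt == "het" &
                  father_gt == "hom_ref" & mother_gt == "hom_ref") |
               (on_x & child_sex == "male" & child_gt == "hemi_alt" &
                  father_gt == "hemi_ref" & mother_gt == "hom_ref") |
               (on_x & child_sex == "female" & child_gt == "het" &
                  father_gt == "hemi_ref" & mother_gt == "hom_ref")]
    if (nrow(dn) > 0L) {
      qp <- denovo_quality_pass(
        data.table(gt = dn$child_gt, gq = dn$child_gq, dp = dn$child_dp,
                   ad_ref = dn$child_ad_ref, ad_alt = dn$child_ad_alt),
        data.table(dp = dn$father_dp, ad_alt = dn$father_ad_alt),
        data.table(dp = dn$mother_dp, ad_alt = dn$mother_ad_alt), qc)
      calls$de_novo <- dn[, .(variant_key, chrom, pos, ref, alt, gene,
                              mode = "de_novo", parent_of_origin = "none",
                              partner_variant_key = NA_character_,
                              pair_id = NA_character_, quality_pass = qp)]
    }
    # --- autosomal dominant ---
    ad <- trio[!on_x & child_gt == "het" &
                 ((father_gt == "het" & mother_gt == "hom_ref") |
                  (mother_gt == "het" & father_gt == "hom_ref"))]
    if (nrow(ad) > 0L) {
      calls$autosomal_dominant <- ad[, .(
        variant_key, chrom, pos, ref, alt, gene,
        mode = "autosomal_dominant",
        parent_of_origin = fifelse(father_gt == "het", "father", "mother"),
        partner_variant_key = NA_character_, pair_id = NA_character_,
        quality_pass = TRUE)]
    }
    # --- X-linked recessive ---
    if (child_sex %in% c("male", "female")) {
      xr <- trio[on_x & (
        (child_sex == "male" & child_gt == "hemi_alt" &
           mother_gt == "het" & father_gt == "hemi_ref") |
        (child_sex == "female" & child_gt == "hom_alt" &
           mother_gt == "het" & father_gt == "hemi_alt"))]
      if (nrow(xr) > 0L) {
        calls$x_linked_recessive <- xr[, .(
          variant_key, chrom, pos, ref, alt, gene,
          mode = "x_linked_recessive",
          parent_of_origin = fifelse(child_sex == "male", "mother", "ambiguous"),
          partner_variant_key = NA_character_, pair_id = NA_character_,
          quality_pass = TRUE)]
      }
    }
    # --- compound heterozygous (autosomal, gene-resolved sites) ---
    chs <- comphet_for_child(trio[!on_x])
    if (nrow(chs$calls) > 0L) calls$comp_het <- chs$calls
    if (nrow(chs$ambiguous) > 0L)
      ambiguous[[length(ambiguous) + 1L]] <-
        chs$ambiguous[, sample_id := ch$individual_id]

    res <- rbindlist(calls, use.names = TRUE)
    if (nrow(res) == 0L) { out[[i]] <- empty_calls(); next }
    # precedence: de_novo > comp_het > autosomal_dominant
    comphet_keys <- res[mode == "comp_het", variant_key]
    res <- res[!(mode == "autosomal_dominant" & variant_key %in% comphet_keys)]
    res[, `:=`(family_id = family, sample_id = ch$individual_id,
               epoch = ch$epoch, outcome = ch$outcome)]
    setcolorder(res, names(empty_calls()))
    out[[i]] <- res
  }
  result <- rbindlist(out, use.names = TRUE)
  setattr(result, "comphet_ambiguous",
          if (length(ambiguous)) rbindlist(ambiguous) else
            data.table(gene = character(), variant_key = character(),
                       reason = character(), sample_id = character()))
  result
}

# comp-het detection for one child's autosomal trio table.
# Trans is asserted only when parental carriage is disjoint across the two
# sites: at each site exactly one parent carries the allele and the
# carrying parents differ. A parent het at both sites cannot exclude cis,
# so such pairs are quarantined, not called.
comphet_for_child <- function(trio) {
  empty <- list(
    calls = empty_calls()[, .(variant_key, chrom, pos, ref, alt, gene, mode,
                              parent_of_origin, partner_variant_key, pair_id,
                              quality_pass)],
    ambiguous = data.table(gene = character(), variant_key = character(),
                           reason = character()))
  hets <- trio[child_gt == "het" & !is.na(gene)]
  if (nrow(hets) < 2L) return(empty)
  hets[, `:=`(
    father_carries = father_gt %in% .alt_bearing,
    mother_carries = mother_gt %in% .alt_bearing
  )]
  hets[, origin := fcase(
    father_carries & !mother_carries, "father",
    mother_carries & !father_carries, "mother",
    father_carries & mother_carries, "ambiguous",
    default = "none"
  )]
  multi_genes <- hets[, .N, by = gene][N >= 2L, gene]
  gh <- hets[gene %in% multi_genes]
  resolved <- gh[origin %in% c("father", "mother")]
  # a member's partner is the first opposite-origin site of the gene (one
  # call per (variant, sample) per mode; additional partners share pair_id
  # conventions through the first site)
  resolved[, `:=`(
    fa_first = variant_key[origin == "father"][1L],
    mo_first = variant_key[origin == "mother"][1L]
  ), by = gene]
  members <- resolved[!is.na(fa_first) & !is.na(mo_first)]
  calls <- if (nrow(members) > 0L) {
    members[, partner_variant_key :=
              fifelse(origin == "father", mo_first, fa_first)]
    members[, pair_id := paste(pmin(variant_key, partner_variant_key),
                               pmax(variant_key, partner_variant_key),
                               sep = "|")]
    members[, .(variant_key, chrom, pos, ref, alt, gene, mode = "comp_het",
                parent_of_origin = origin, partner_variant_key, pair_id,
                quality_pass = TRUE)]
  } else empty$calls
  bad <- gh[origin %in% c("ambiguous", "none")]
  ambiguous <- if (nrow(bad) > 0L) {
    bad[, .(gene, variant_key,
            reason = fifelse(origin == "ambiguous", "both_parents_carry",
                             "no_parent_carries"))]
  } else empty$ambiguous
  list(calls = calls, ambiguous = ambiguous)
}

#' Classify the whole cohort
#'
#' Runs [classify_family()] over every family in the pedigree and binds
#' the calls.
#'
#' @inheritParams classify_family
#' @return Combined calls table (see [classify_family()]); attribute
#'   `comphet_ambiguous` is the row-bound quarantine table.
#' @export
classify_cohort <- function(vs, pedigree, config = default_config()) {
  ped <- as.data.table(pedigree)
  fams <- unique(ped$family_id)
  res <- lapply(fams, function(f) classify_family(vs, ped, f, config))
  amb <- rbindlist(lapply(res, attr, "comphet_ambiguous"), use.names = TRUE)
  calls <- rbindlist(res, use.names = TRUE)
  setattr(calls, "comphet_ambiguous", amb)
  calls
}
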