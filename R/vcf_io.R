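#' @name cohort_variants
#' @title Variant container
#'
#' @description
#' [read_variants()] and [simulate_cohort()] represent a cohort's variants
#' as a list of two data.tables:
#'
#' * `variants`: one row per decomposed biallelic record with columns
#'   `variant_key` (`chrom:pos:ref:alt`), `chrom`, `pos`, `ref`, `alt`,
#'   `gene`, `impact`, `gnomad_af`, `topmed_af`, `gnomad_hom_count`, `pli`,
#'   `loeuf`, `spliceai_max`. Missing annotation is `NA`, never 0: a
#'   variant absent from gnomAD is distinguished from one observed at
#'   frequency zero.
#' * `genotypes`: one row per (variant, sample) with columns `variant_key`,
#'   `sample_id`, `gt` (`hom_ref`, `het`, `hom_alt`, `hemi_ref`,
#'   `hemi_alt`, `missing`), `gq`, `dp`, `ad_ref`, `ad_alt`.
#'
#' Hemizygous states are used for male genotypes on the X chromosome;
#' diploid-coded male X calls are normalized to hemizygous on read.
NULL

.gt_levels <- c("hom_ref", "het", "hom_alt", "hemi_ref", "hemi_alt", "missing")

make_variant_key <- function(chrom, pos, ref, alt) {
  paste(chrom, pos, ref, alt, sep = ":")
}

# split an INFO string into a named character vector
parse_info <- function(info) {
  if (is.na(info) || info == "." || info == "") return(character())
  parts <- strsplit(info, ";", fixed = TRUE)[[1]]
  has_eq <- grepl("=", parts, fixed = TRUE)
  kv <- strsplit(parts[has_eq], "=", fixed = TRUE)
  stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
}

# take the k-th element of a comma-separated per-allele value (or the sole value)
pick_allele <- function(x, k) {
  if (is.na(x)) return(NA_character_)
  parts <- strsplit(x, ",", fixed = TRUE)[[1]]
  if (length(parts) == 1L) parts else parts[min(k, length(parts))]
}

num_or_na <- function(x) {
  suppressWarnings(as.numeric(x))
}
int_or_na <- function(x) {
  suppressWarnings(as.integer(x))
}

#' Read a multi-sample VCF into normalized variant records
#'
#' Multi-allelic sites are decomposed into one biallelic record per alt
#' allele: for the record of allele *k*, genotype alleles equal to *k*
#' count as alt and all others as ref, which conserves the per-sample total
#' alt dosage across the decomposed records. Annotation INFO keys are
#' config-mapped (`config$annotation_keys`); per-allele annotation values
#' (comma lists) are split alongside the alleles. Records on contigs
#' outside `config$contigs` are skipped and counted (attribute
#' `skipped_contigs`). Male genotypes on `config$x_chrom` are normalized
#' to hemizygous states.
#'
#' @param path VCF file (plain or bgzipped).
#' @param pedigree Pedigree table from [read_pedigree()]; every individual
#'   with `has_sample = TRUE` must be a sample column of the VCF.
#' @param config Pipeline configuration, see [default_config()].
#' @return A list with elements `variants` and `genotypes` (see
#'   [cohort_variants]), with attribute `skipped_contigs` = number of
#'   records dropped for being on unlisted contigs.
#' @export
read_variants <- function(path, pedigree, config = default_config()) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  ped <- as.data.table(pedigree)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  gtm <- v@gt
  samples <- colnames(gtm)[-1L]

  need <- ped[has_sample == TRUE, individual_id]
  absent <- setdiff(need, samples)
  if (length(absent) > 0L)
    stop("pedigree individual(s) marked as sampled but absent from VCF: ",
         paste(absent, collapse = ", "))
  extra <- setdiff(samples, ped$individual_id)
  if (length(extra) > 0L)
    warning("VCF sample(s) not in pedigree are ignored: ",
            paste(extra, collapse = ", "))
  samples <- intersect(samples, need)
  male <- stats::setNames(ped$sex == "male", ped$individual_id)[samples]

  keep <- fix[, "CHROM"] %in% config$contigs
  n_skipped <- sum(!keep)
  if (n_skipped > 0L)
    message("read_variants: skipped ", n_skipped,
            " record(s) on unlisted contigs")
  fix <- fix[keep, , drop = FALSE]
  gtm <- gtm[keep, , drop = FALSE]

  keys <- config$annotation_keys
  n_alt_per_row <- lengths(strsplit(fix[, "ALT"], ",", fixed = TRUE))
  fast <- n_alt_per_row == 1L
  fast_out <- if (any(fast)) {
    read_variants_fast(fix[fast, , drop = FALSE], gtm[fast, , drop = FALSE],
                       samples, male, keys, config$x_chrom)
  } else NULL
  slow_rows <- which(!fast)
  var_list <- vector("list", length(slow_rows))
  gt_list <- vector("list", length(slow_rows))
  for (ri in seq_along(slow_rows)) {
    r <- slow_rows[ri]
    chrom <- fix[r, "CHROM"]
    pos <- as.integer(fix[r, "POS"])
    ref <- fix[r, "REF"]
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1]]
    info <- parse_info(fix[r, "INFO"])
    fmt <- strsplit(gtm[r, 1L], ":", fixed = TRUE)[[1]]
    cells <- strsplit(gtm[r, samples], ":", fixed = TRUE)
    gt_i <- match("GT", fmt)
    gq_i <- match("GQ", fmt)
    dp_i <- match("DP", fmt)
    ad_i <- match("AD", fmt)
    if (is.na(gt_i))
      stop("VCF record ", chrom, ":", pos, " has no GT in FORMAT")
    field <- function(cell, i) {
      if (is.na(i) || length(cell) < i) NA_character_ else cell[i]
    }
    gts <- vapply(cells, field, "", gt_i)
    gqs <- int_or_na(vapply(cells, field, "", gq_i))
    dps <- int_or_na(vapply(cells, field, "", dp_i))
    ads <- vapply(cells, field, "", ad_i)
    allele_lists <- strsplit(gts, "[/|]")
    ad_lists <- strsplit(ads, ",", fixed = TRUE)

    is_x <- identical(unname(chrom), config$x_chrom)
    per_allele <- vector("list", length(alts))
    per_geno <- vector("list", length(alts))
    for (k in seq_along(alts)) {
      ann <- function(field_key, conv) {
        key <- keys[[field_key]]
        conv(pick_allele(if (key %in% names(info)) info[[key]] else NA_character_, k))
      }
      per_allele[[k]] <- data.table(
        chrom = chrom, pos = pos, ref = ref, alt = alts[k],
        gene = ann("gene", as.character),
        impact = ann("impact", as.character),
        gnomad_af = ann("gnomad_af", num_or_na),
        topmed_af = ann("topmed_af", num_or_na),
        gnomad_hom_count = ann("gnomad_hom_count", int_or_na),
        pli = ann("pli", num_or_na),
        loeuf = ann("loeuf", num_or_na),
        spliceai_max = ann("spliceai_max", num_or_na)
      )
      gt_code <- character(length(samples))
      ad_ref_k <- rep(NA_integer_, length(samples))
      ad_alt_k <- rep(NA_integer_, length(samples))
      for (s in seq_along(samples)) {
        al <- allele_lists[[s]]
        if (length(al) == 0L || any(al == ".")) {
          gt_code[s] <- "missing"
          next
        }
        ali <- suppressWarnings(as.integer(al))
        if (anyNA(ali)) {
          gt_code[s] <- "missing"
          next
        }
        n_alt_k <- sum(ali == k)
        haploid <- length(ali) == 1L
        if (haploid || (is_x && male[s])) {
          # haploid call, or diploid-coded male X normalized to hemizygous
          gt_code[s] <- if (haploid) {
            if (n_alt_k > 0L) "hemi_alt" else "hemi_ref"
          } else if (n_alt_k == 2L) "hemi_alt"
            else if (n_alt_k == 1L) "het"   # mixed male X call kept as het
            else "hemi_ref"
        } else {
          gt_code[s] <- c("hom_ref", "het", "hom_alt")[n_alt_k + 1L]
        }
        adl <- ad_lists[[s]]
        if (length(adl) >= k + 1L && !is.na(adl[1L]) && adl[1L] != ".") {
          ad_ref_k[s] <- int_or_na(adl[1L])
          ad_alt_k[s] <- int_or_na(adl[k + 1L])
        }
      }
      per_geno[[k]] <- data.table(
        variant_key = make_variant_key(chrom, pos, ref, alts[k]),
        sample_id = samples,
        gt = gt_code, gq = gqs, dp = dps,
        ad_ref = ad_ref_k, ad_alt = ad_alt_k
      )
    }
    var_list[[ri]] <- rbindlist(per_allele)
    gt_list[[ri]] <- rbindlist(per_geno)
  }
  variants <- rbindlist(c(list(fast_out$variants), var_list),
                        use.names = TRUE)
  genotypes <- rbindlist(c(list(fast_out$genotypes), gt_list),
                         use.names = TRUE)
  if (nrow(variants) > 0L) {
    variants[, variant_key := make_variant_key(chrom, pos, ref, alt)]
    setcolorder(variants, "variant_key")
    known <- c("missense", "frameshift", "inframe_indel", "stop_gained",
               "stop_retained", "splice_region", "other")
    variants[!is.na(impact) & !impact %in% known, impact := "other"]
    setorder(variants, chrom, pos, alt)
    setkey(genotypes, variant_key, sample_id)
  }
  out <- list(variants = variants, genotypes = genotypes)
  attr(out, "skipped_contigs") <- n_skipped
  out
}

# vectorized reader for decomposed (single-ALT) records
read_variants_fast <- function(fix, gtm, samples, male, keys, x_chrom) {
  n <- nrow(fix)
  if (n == 0L) return(NULL)
  info <- fix[, "INFO"]
  info_field <- function(key) {
    m <- regexpr(paste0("(^|;)", key, "=([^;]*)"), info)
    out <- rep(NA_character_, n)
    hit <- m > 0L
    val <- regmatches(info, m)
    out[hit] <- sub(paste0("^;?", key, "="), "", val)
    out
  }
  variants <- data.table(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    gene = info_field(keys$gene),
    impact = info_field(keys$impact),
    gnomad_af = num_or_na(info_field(keys$gnomad_af)),
    topmed_af = num_or_na(info_field(keys$topmed_af)),
    gnomad_hom_count = int_or_na(info_field(keys$gnomad_hom_count)),
    pli = num_or_na(info_field(keys$pli)),
    loeuf = num_or_na(info_field(keys$loeuf)),
    spliceai_max = num_or_na(info_field(keys$spliceai_max))
  )
  vkeys <- make_variant_key(variants$chrom, variants$pos,
                            variants$ref, variants$alt)
  gt_map <- c("0/0" = "hom_ref", "0|0" = "hom_ref",
              "0/1" = "het", "1/0" = "het", "0|1" = "het", "1|0" = "het",
              "1/1" = "hom_alt", "1|1" = "hom_alt",
              "0" = "hemi_ref", "1" = "hemi_alt")
  on_x <- variants$chrom == x_chrom
  fmt <- gtm[, 1L]
  geno <- vector("list", length(samples))
  for (s in seq_along(samples)) {
    col <- gtm[, samples[s]]
    gt <- rep("missing", n)
    gq <- rep(NA_integer_, n)
    dp <- rep(NA_integer_, n)
    ad_ref <- rep(NA_integer_, n)
    ad_alt <- rep(NA_integer_, n)
    for (f in unique(fmt)) {
      idx <- which(fmt == f)
      fields <- strsplit(f, ":", fixed = TRUE)[[1]]
      parts <- tstrsplit(col[idx], ":", fixed = TRUE)
      take <- function(name) {
        i <- match(name, fields)
        if (is.na(i) || i > length(parts)) rep(NA_character_, length(idx))
        else parts[[i]]
      }
      g <- gt_map[take("GT")]
      g[is.na(g)] <- "missing"
      gt[idx] <- g
      gq[idx] <- int_or_na(take("GQ"))
      dp[idx] <- int_or_na(take("DP"))
      ad <- take("AD")
      adp <- tstrsplit(ad, ",", fixed = TRUE)
      if (length(adp) >= 2L) {
        ad_ref[idx] <- int_or_na(adp[[1L]])
        ad_alt[idx] <- int_or_na(adp[[2L]])
      }
    }
    if (male[samples[s]]) {
      # normalize diploid-coded male X calls to hemizygous
      gt[on_x & gt == "hom_ref"] <- "hemi_ref"
      gt[on_x & gt == "hom_alt"] <- "hemi_alt"
    }
    geno[[s]] <- data.table(variant_key = vkeys,
                            sample_id = samples[s], gt = gt, gq = gq,
                            dp = dp, ad_ref = ad_ref, ad_alt = ad_alt)
  }
  list(variants = variants, genotypes = rbindlist(geno))
}

fmt_num6 <- function(x) {
  ifelse(is.na(x), NA_character_, sprintf("%.6g", x))
}

#' Write variant records to a VCF 4.2 file
#'
#' Inverse of [read_variants()] for decomposed (biallelic) records:
#' annotations are emitted under the configured INFO keys (missing values
#' omitted, preserving missing-vs-zero), genotypes as `GT:GQ:DP:AD` with
#' hemizygous calls written haploid. Continuous annotations are printed
#' with 6 significant digits, so values stored at that precision round-trip
#' exactly.
#'
#' @param vs Variant container (see [cohort_variants]).
#' @param path Output path.
#' @param config Pipeline configuration (annotation key names, contigs).
#' @param sample_order Optional explicit sample column order.
#' @return `path`, invisibly.
#' @export
write_variants <- function(vs, path, config = default_config(),
                           sample_order = NULL) {
  variants <- as.data.table(vs$variants)
  genotypes <- as.data.table(vs$genotypes)
  if (is.null(sample_order)) sample_order <- sort(unique(genotypes$sample_id))
  keys <- config$annotation_keys

  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=pedloss",
    sprintf("##contig=<ID=%s>", config$contigs),
    sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"Gene symbol\">", keys$gene),
    sprintf("##INFO=<ID=%s,Number=A,Type=String,Description=\"Predicted impact class\">", keys$impact),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"gnomAD allele frequency\">", keys$gnomad_af),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"TopMed allele frequency\">", keys$topmed_af),
    sprintf("##INFO=<ID=%s,Number=A,Type=Integer,Description=\"gnomAD homozygote count\">", keys$gnomad_hom_count),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"pLI of the gene\">", keys$pli),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"LOEUF of the gene\">", keys$loeuf),
    sprintf("##INFO=<ID=%s,Number=A,Type=Float,Description=\"Maximum spliceAI delta\">", keys$spliceai_max),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_order), collapse = "\t")
  )

  variants <- variants[order(chrom, pos, alt)]
  info_of <- function(i) {
    r <- variants[i]
    pieces <- c(
      if (!is.na(r$gene)) paste0(keys$gene, "=", r$gene),
      if (!is.na(r$impact)) paste0(keys$impact, "=", r$impact),
      if (!is.na(r$gnomad_af)) paste0(keys$gnomad_af, "=", fmt_num6(r$gnomad_af)),
      if (!is.na(r$topmed_af)) paste0(keys$topmed_af, "=", fmt_num6(r$topmed_af)),
      if (!is.na(r$gnomad_hom_count)) paste0(keys$gnomad_hom_count, "=", r$gnomad_hom_count),
      if (!is.na(r$pli)) paste0(keys$pli, "=", fmt_num6(r$pli)),
      if (!is.na(r$loeuf)) paste0(keys$loeuf, "=", fmt_num6(r$loeuf)),
      if (!is.na(r$spliceai_max)) paste0(keys$spliceai_max, "=", fmt_num6(r$spliceai_max))
    )
    if (length(pieces) == 0L) "." else paste(pieces, collapse = ";")
  }
  info_str <- vapply(seq_len(nrow(variants)), info_of, "")

  gt_string <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1",
                 hemi_ref = "0", hemi_alt = "1", missing = "./.")
  g <- copy(genotypes)
  g[, cell := paste(
    gt_string[gt],
    ifelse(is.na(gq), ".", as.character(gq)),
    ifelse(is.na(dp), ".", as.character(dp)),
    ifelse(is.na(ad_ref) & is.na(ad_alt), ".",
           paste0(ifelse(is.na(ad_ref), ".", as.character(ad_ref)), ",",
                  ifelse(is.na(ad_alt), ".", as.character(ad_alt)))),
    sep = ":")]
  wide <- dcast(g, variant_key ~ sample_id, value.var = "cell",
                fill = "./.:.:.:.")
  wide <- wide[match(variants$variant_key, variant_key)]
  cell_mat <- as.matrix(wide[, sample_order, with = FALSE])
  cell_mat[is.na(cell_mat)] <- "./.:.:.:."

  body <- paste(
    variants$chrom, variants$pos, ".", variants$ref, variants$alt, ".",
    "PASS", info_str, "GT:GQ:DP:AD",
    apply(cell_mat, 1L, paste, collapse = "\t"),
    sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

utils::globalVariables("cell")

#' Check genotypes for Mendelian consistency
#'
#' For every offspring with both parents present, verifies at each site
#' that the child's genotype can be produced by one transmitted allele from
#' each parent (X-aware: sons receive their X from the mother only,
#' daughters one X from each parent). Artifact and de novo genotypes
#' violate this by construction.
#'
#' @param vs Variant container.
#' @param pedigree Pedigree table.
#' @param config Pipeline configuration (for the X contig name).
#' @return data.table of violations: `variant_key`, `sample_id`.
#' @export
mendelian_violations <- function(vs, pedigree, config = default_config()) {
  ped <- as.data.table(pedigree)
  gts <- as.data.table(vs$genotypes)
  vars <- as.data.table(vs$variants)[, .(variant_key, chrom)]
  gts <- vars[gts, on = "variant_key"]
  dose <- c(hom_ref = 0L, het = 1L, hom_alt = 2L, hemi_ref = 0L, hemi_alt = 1L)
  offspring <- ped[!is.na(father_id) & !is.na(mother_id) & has_sample == TRUE]
  out <- list()
  for (i in seq_len(nrow(offspring))) {
    ch <- offspring$individual_id[i]
    fa <- offspring$father_id[i]
    mo <- offspring$mother_id[i]
    sx <- offspring$sex[i]
    trio <- dcast(gts[sample_id %in% c(ch, fa, mo)],
                  variant_key + chrom ~ sample_id, value.var = "gt")
    setnames(trio, c(ch, fa, mo), c("child_gt", "father_gt", "mother_gt"))
    trio <- trio[child_gt != "missing" & father_gt != "missing" &
                   mother_gt != "missing"]
    cd <- dose[trio$child_gt]; fd <- dose[trio$father_gt]; md <- dose[trio$mother_gt]
    # possible transmitted allele sets: 0 -> {0}, 1 -> {0,1}, 2 -> {1}
    can_give <- function(d, a) (a == 0L & d < 2L) | (a == 1L & d > 0L)
    on_x <- trio$chrom == config$x_chrom
    consistent <- logical(nrow(trio))
    for (ca in 0:2) {
      idx <- cd == ca
      if (!any(idx)) next
      if (ca == 1L) {
        auto_ok <- (can_give(fd, 0L) & can_give(md, 1L)) |
                   (can_give(fd, 1L) & can_give(md, 0L))
      } else {
        a <- if (ca == 0L) 0L else 1L
        auto_ok <- can_give(fd, a) & can_give(md, a)
      }
      x_ok <- if (sx == "male") {
        # son: single X from mother
        a <- if (ca == 0L) 0L else 1L
        if (ca == 2L) rep(FALSE, nrow(trio)) else can_give(md, a)
      } else auto_ok
      consistent[idx] <- ifelse(on_x[idx], x_ok[idx], auto_ok[idx])
    }
    bad <- trio[!consistent, .(variant_key)]
    if (nrow(bad) > 0L) out[[length(out) + 1L]] <- bad[, sample_id := ch]
  }
  if (length(out) == 0L)
    return(data.table(variant_key = character(), sample_id = character()))
  rbindlist(out)
}
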