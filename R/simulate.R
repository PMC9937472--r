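#' Default per-family offspring design
#'
#' Mirrors the sampled products of conception of the study design the
#' simulator emulates: two parents, two healthy live births, and four
#' sampled losses (one stillbirth at 20w0d and fetal deaths at 15w6d,
#' 16w0d and 13w6d, all male), plus one unsampled female embryonic loss
#' at 6w6d so the pedigree carries a conceptus without a WGS sample.
#'
#' @return data.table with columns `outcome`, `sex`, `ga`, `sampled`.
#' @export
default_family_design <- function() {
  data.table(
    outcome = c("live_birth", "live_birth", "loss", "loss", "loss", "loss",
                "loss"),
    sex     = c("male", "female", "male", "male", "male", "male", "female"),
    ga      = c(NA, NA, "20w0d", "15w6d", "16w0d", "13w6d", "6w6d"),
    sampled = c(TRUE, TRUE, TRUE, TRUE, TRUE, TRUE, FALSE)
  )
}

#' Build a simulation configuration
#'
#' All the knobs of the synthetic cohort generator with defaults chosen to
#' emulate the study design: three families (parents + live births +
#' losses, see [default_family_design()]), a rare-skewed background
#' allele-frequency spectrum with a novel and a common component, an
#' impact spectrum dominated by missense, a configurable fraction of
#' constrained (pLI/LOEUF-pathogenic) genes, planted variants per
#' inheritance mode in each sampled loss (4 de novo with half their mass
#' on loss-of-function classes, so the expected de novo LoF mean per loss
#' is 2; 2 dominant; 1 compound-het pair; 1 X-linked recessive), and
#' optional genotype-error and FFPE-artifact noise (both default 0).
#'
#' @param n_families Number of families.
#' @param family_design Offspring design table, see
#'   [default_family_design()].
#' @param planted Named list of planted counts per sampled loss:
#'   `de_novo`, `autosomal_dominant`, `comp_het` (pairs),
#'   `x_linked_recessive`.
#' @param background_variants Number of background sites.
#' @param x_background_frac Fraction of background sites on the X.
#' @param af_spec Background allele-frequency mixture: `p_novel` (AF
#'   missing), `p_common` (AF ~ U(0.01, 0.5)), remainder
#'   Beta(`beta_shape1`, `beta_shape2`).
#' @param impact_probs Named probabilities over impact classes for
#'   background sites.
#' @param planted_impact_probs List with elements `de_novo` and `default`:
#'   impact distributions for planted sites.
#' @param constraint `p_missing` (no pLI/LOEUF annotation) and
#'   `p_pathogenic` (gene in the constrained region pLI > 0.9,
#'   LOEUF < 0.36).
#' @param planted_pathogenic_frac Fraction of planted variants in
#'   constrained genes.
#' @param genotype_error_rate Per-genotype probability of replacement by a
#'   random different genotype.
#' @param ffpe_artifact_rate Per-genotype probability of a false
#'   low-allele-balance het call, loss samples only, with C>T/G>A bias.
#' @param ffpe_bias_odds Odds multiplier of artifact injection at C>T or
#'   G>A sites relative to other substitutions.
#' @param n_genes Named list: `autosomal`, `x` gene counts, and
#'   `reserve_planted` - how many autosomal genes are reserved for planted
#'   variants (background sites never land in them, so a planted site's
#'   gene context is fully controlled by the design).
#' @param gene_length Length of each synthetic gene interval (bp).
#' @param depth Mean sequencing depth for simulated genotype quality.
#' @param seed Random seed; a fixed seed makes the whole cohort (VCF
#'   bytes included) reproducible.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_families = 3L,
                       family_design = default_family_design(),
                       planted = list(de_novo = 4L, autosomal_dominant = 2L,
                                      comp_het = 1L, x_linked_recessive = 1L),
                       background_variants = 10000L,
                       x_background_frac = 0.1,
                       af_spec = list(p_novel = 0.1, p_common = 0.3,
                                      beta_shape1 = 0.5, beta_shape2 = 50),
                       impact_probs = c(other = 0.45, missense = 0.35,
                                        splice_region = 0.07, frameshift = 0.05,
                                        inframe_indel = 0.04, stop_gained = 0.03,
                                        stop_retained = 0.01),
                       planted_impact_probs = list(
                         de_novo = c(missense = 0.45, frameshift = 0.2,
                                     splice_region = 0.2, inframe_indel = 0.05,
                                     stop_gained = 0.1),
                         default = c(missense = 0.6, frameshift = 0.1,
                                     splice_region = 0.15, inframe_indel = 0.1,
                                     stop_gained = 0.05)),
                       constraint = list(p_missing = 0.1, p_pathogenic = 0.1),
                       planted_pathogenic_frac = 0.5,
                       genotype_error_rate = 0,
                       ffpe_artifact_rate = 0,
                       ffpe_bias_odds = 4,
                       n_genes = list(autosomal = 400L, x = 50L,
                                      reserve_planted = 60L),
                       gene_length = 20000L,
                       depth = 30L,
                       seed = 1L) {
  rates <- c(af_spec$p_novel, af_spec$p_common, genotype_error_rate,
             ffpe_artifact_rate)
  stopifnot(all(rates >= 0 & rates <= 1),
            all(unlist(planted) >= 0), background_variants >= 0)
  structure(mget(names(formals())), class = "sim_config")
}

build_sim_pedigree <- function(cfg) {
  fams <- lapply(seq_len(cfg$n_families), function(i) {
    fam <- sprintf("F%d", i)
    des <- as.data.table(cfg$family_design)
    kids <- data.table(
      individual_id = sprintf("%s_C%d", fam, seq_len(nrow(des))),
      family_id = fam,
      father_id = paste0(fam, "_father"),
      mother_id = paste0(fam, "_mother"),
      sex = des$sex, outcome = des$outcome
    )
    ga <- parse_ga(des$ga)
    kids[, `:=`(ga_weeks = ga$ga_weeks, ga_days = ga$ga_days,
                has_sample = des$sampled)]
    parents <- data.table(
      individual_id = paste0(fam, c("_father", "_mother")),
      family_id = fam, father_id = NA_character_, mother_id = NA_character_,
      sex = c("male", "female"), outcome = "parent",
      ga_weeks = NA_integer_, ga_days = NA_integer_, has_sample = TRUE)
    rbind(parents, kids)
  })
  ped <- rbindlist(fams)
  ped[, epoch := "not_applicable"]
  ped[outcome == "live_birth", epoch := "live_birth"]
  ped[outcome == "loss", epoch := classify_epoch(ga_weeks, ga_days)]
  if (ped[has_sample == TRUE & outcome != "parent" & sex == "unknown", .N] > 0L)
    stop("the simulator requires a known sex for every sampled offspring")
  setcolorder(ped, c("individual_id", "family_id", "father_id", "mother_id",
                     "sex", "outcome", "ga_weeks", "ga_days", "epoch",
                     "has_sample"))
  ped[]
}

build_sim_genes <- function(cfg) {
  n_auto <- cfg$n_genes$autosomal
  n_x <- cfg$n_genes$x
  gap <- 2L * cfg$gene_length
  place <- function(chrom, n, offset = 0L) {
    start <- offset + seq_len(n) * gap
    data.table(gene = character(n), chrom = chrom, start = start,
               end = start + cfg$gene_length - 1L)
  }
  g1 <- place("chr1", ceiling(n_auto / 2))
  g2 <- place("chr2", floor(n_auto / 2))
  gx <- place("chrX", n_x)
  genes <- rbind(g1, g2, gx)
  genes[, gene := sprintf("GENE%04d", .I)]
  genes[]
}

# draw background annotations for n sites
sim_annotations <- function(n, cfg) {
  u <- runif(n)
  af <- rep(NA_real_, n)
  common <- u >= cfg$af_spec$p_novel &
    u < cfg$af_spec$p_novel + cfg$af_spec$p_common
  rare <- u >= cfg$af_spec$p_novel + cfg$af_spec$p_common
  af[common] <- runif(sum(common), 0.01, 0.5)
  af[rare] <- rbeta(sum(rare), cfg$af_spec$beta_shape1, cfg$af_spec$beta_shape2)
  af <- signif(af, 6)
  topmed <- rep(NA_real_, n)
  has_tm <- !is.na(af) & runif(n) < 0.9
  topmed[has_tm] <- signif(pmin(1, af[has_tm] * runif(sum(has_tm), 0.5, 1.5)), 6)
  impact <- sample(names(cfg$impact_probs), n, replace = TRUE,
                   prob = cfg$impact_probs)
  pli <- rep(NA_real_, n); loeuf <- rep(NA_real_, n)
  has_con <- runif(n) >= cfg$constraint$p_missing
  patho <- has_con & runif(n) < cfg$constraint$p_pathogenic
  benign <- has_con & !patho
  pli[patho] <- signif(runif(sum(patho), 0.905, 0.999), 6)
  loeuf[patho] <- signif(runif(sum(patho), 0.01, 0.35), 6)
  pli[benign] <- signif(runif(sum(benign), 0, 0.89), 6)
  loeuf[benign] <- signif(runif(sum(benign), 0.37, 1.9), 6)
  hom <- integer(n)
  has_af <- !is.na(af)
  hom[has_af] <- rpois(sum(has_af), pmin(50, af[has_af]^2 * 140000))
  spliceai <- rep(NA_real_, n)
  spl <- impact == "splice_region"
  spliceai[spl] <- signif(runif(sum(spl), 0.2, 1), 6)
  other_sa <- !spl & runif(n) < 0.5
  spliceai[other_sa] <- signif(runif(sum(other_sa), 0, 0.2), 6)
  data.table(gnomad_af = af, topmed_af = topmed, impact = impact,
             pli = pli, loeuf = loeuf, gnomad_hom_count = hom,
             spliceai_max = spliceai)
}

.bases <- c("A", "C", "G", "T")

draw_ref_alt <- function(n) {
  ref <- sample(.bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(.bases, r), 1L), "")
  data.table(ref = ref, alt = unname(alt))
}

# position registry to keep (chrom, pos) unique
new_pos_registry <- function() new.env(parent = emptyenv())
claim_positions <- function(reg, chrom, start, end, n) {
  used <- if (is.null(reg[[chrom]])) integer() else reg[[chrom]]
  out <- integer(0)
  while (length(out) < n) {
    cand <- sample.int(end - start + 1L, n - length(out), replace = FALSE) +
      start - 1L
    cand <- setdiff(unique(cand), c(used, out))
    out <- c(out, cand)
  }
  reg[[chrom]] <- c(used, out)
  out
}

#' Simulate a multi-family cohort with planted variants
#'
#' Generates a pedigree, a multi-sample VCF and ground-truth tables for a
#' synthetic recurrent-pregnancy-loss cohort. Background variants get
#' Hardy-Weinberg parental genotypes from their allele frequency and
#' Mendelian random transmission to offspring (X-aware). Planted variants
#' realize each inheritance mode exactly in each sampled loss: de novo
#' (child het, parents reference, clean allele balance), autosomal
#' dominant (one het parent transmits), compound-het pairs (two sites in
#' one gene, one from each parent), and X-linked recessive
#' (sex-consistent hemizygous pattern). Optional noise: uniform genotype
#' errors, and FFPE-style artifacts - false low-allele-balance het calls
#' injected only into loss samples at background autosomal sites, with a
#' configurable odds bias toward C>T/G>A substitutions.
#'
#' An expected-call table is derived from the generator's internal,
#' noise-free dosage matrix for all variants (planted and background):
#' background sites realize genuine inherited-mode configurations by
#' Mendelian chance, and those are correct calls, so recovery is scored
#' against this table rather than against planted sites alone.
#'
#' @param cfg Configuration from [sim_config()].
#' @param dir Output directory (created if needed).
#' @return List: `vcf`, `ped` (file paths), `vs` (variant container),
#'   `pedigree`, `truth` (per-variant table: `variant_key`,
#'   `planted_mode` with `"background"` for unplanted sites,
#'   `target_sample`, flags), `expected_calls`, `artifacts`
#'   (variant/sample cells that received an FFPE artifact), `genes`, and
#'   `config`.
#' @export
simulate_cohort <- function(cfg = sim_config(), dir = tempfile("cohort")) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ped <- build_sim_pedigree(cfg)
  genes <- build_sim_genes(cfg)
  samples <- ped[has_sample == TRUE, individual_id]
  male <- stats::setNames(ped$sex == "male", ped$individual_id)[samples]
  reg <- new_pos_registry()

  ## ---- gene pools: planted autosomal sites live in reserved genes ----
  reserve <- cfg$n_genes$reserve_planted
  auto_genes <- genes[chrom != "chrX"]
  gene_pool_x <- genes[chrom == "chrX"]
  gene_pool_a <- auto_genes[seq_len(nrow(auto_genes) - reserve)]
  gene_pool_res <- auto_genes[seq_len(reserve) + nrow(auto_genes) - reserve]
  per_child_genes <- cfg$planted$de_novo + cfg$planted$autosomal_dominant +
    cfg$planted$comp_het
  if (per_child_genes > nrow(gene_pool_res))
    stop("infeasible design: ", per_child_genes, " planted autosomal events ",
         "per loss but only ", nrow(gene_pool_res), " reserved genes; ",
         "raise n_genes$reserve_planted")
  if (cfg$planted$x_linked_recessive > 0L && nrow(gene_pool_x) == 0L)
    stop("infeasible design: X-linked planting requested with no X genes")

  ## ---- background sites ----
  n_bg <- cfg$background_variants
  on_x_bg <- runif(n_bg) < cfg$x_background_frac
  gidx <- integer(n_bg)
  gidx[!on_x_bg] <- sample.int(nrow(gene_pool_a), sum(!on_x_bg), replace = TRUE)
  gidx[on_x_bg] <- sample.int(nrow(gene_pool_x), sum(on_x_bg), replace = TRUE)
  bg_gene <- rbind(gene_pool_a[gidx[!on_x_bg]], gene_pool_x[gidx[on_x_bg]])
  # keep original interleaving order
  ord <- order(c(which(!on_x_bg), which(on_x_bg)))
  bg_gene <- bg_gene[ord]
  pos <- integer(n_bg)
  for (g in unique(bg_gene$gene)) {
    idx <- which(bg_gene$gene == g)
    row <- genes[gene == g]
    pos[idx] <- claim_positions(reg, row$chrom, row$start, row$end, length(idx))
  }
  ra <- draw_ref_alt(n_bg)
  bg <- cbind(
    data.table(chrom = bg_gene$chrom, pos = pos, ref = ra$ref, alt = ra$alt,
               gene = bg_gene$gene),
    sim_annotations(n_bg, cfg)
  )

  ## ---- background genotypes (dosage matrix) ----
  # Parental alleles are drawn conditioned on at least one alt allele in the
  # cohort's parents: a cohort VCF only contains sites somebody carries, so
  # the allele count over the parental allele slots is truncated-binomial
  # (>= 1) with the site's population frequency, alleles placed uniformly
  # over the slots. Offspring then receive Mendelian random transmissions.
  all_vars <- copy(bg)
  dose <- matrix(0L, nrow = n_bg, ncol = length(samples),
                 dimnames = list(NULL, samples))
  p_alt <- fifelse(is.na(bg$gnomad_af), 1e-4, bg$gnomad_af)
  is_x <- bg$chrom == "chrX"
  fathers <- ped[outcome == "parent" & sex == "male", individual_id]
  mothers <- ped[outcome == "parent" & sex == "female", individual_id]
  auto_slots <- rep(c(fathers, mothers), each = 2L)
  x_slots <- c(fathers, rep(mothers, each = 2L))   # fathers have one X
  n_slots <- fifelse(is_x, length(x_slots), length(auto_slots))
  p0 <- stats::pbinom(0L, n_slots, p_alt)
  k_alt <- stats::qbinom(p0 + runif(n_bg) * (1 - p0), n_slots, p_alt)
  k_alt <- pmax(1L, k_alt)
  for (r in seq_len(n_bg)) {
    owners <- if (is_x[r]) x_slots else auto_slots
    hit <- sample.int(length(owners), k_alt[r])
    for (o in owners[hit]) dose[r, o] <- dose[r, o] + 1L
  }
  transmit <- function(d, ploidy = 2L) rbinom(length(d), 1L, d / ploidy)
  for (f in unique(ped$family_id)) {
    fa_id <- ped[family_id == f & outcome == "parent" & sex == "male",
                 individual_id]
    mo_id <- ped[family_id == f & outcome == "parent" & sex == "female",
                 individual_id]
    fa <- dose[, fa_id]
    mo <- dose[, mo_id]
    kids <- ped[family_id == f & outcome != "parent" & has_sample == TRUE]
    for (i in seq_len(nrow(kids))) {
      ch <- rbinom(n_bg, 1L, fa / 2) + transmit(mo)
      if (kids$sex[i] == "male") {
        ch[is_x] <- transmit(mo[is_x])          # son's X comes from mother
      } else {
        ch[is_x] <- fa[is_x] + transmit(mo[is_x]) # daughter: paternal X fixed
      }
      dose[, kids$individual_id[i]] <- ch
    }
  }

  ## ---- planted variants ----
  planted_vars <- list()
  planted_dose <- list()
  truth_rows <- list()
  plant_site <- function(gene_row, mode, target, fam) {
    pos <- claim_positions(reg, gene_row$chrom, gene_row$start, gene_row$end, 1L)
    ra <- draw_ref_alt(1L)
    probs <- if (mode == "de_novo") cfg$planted_impact_probs$de_novo else
      cfg$planted_impact_probs$default
    patho <- runif(1) < cfg$planted_pathogenic_frac
    af <- if (runif(1) < 0.2) NA_real_ else signif(runif(1, 0, 0.0008), 6)
    data.table(
      chrom = gene_row$chrom, pos = pos, ref = ra$ref, alt = ra$alt,
      gene = gene_row$gene,
      gnomad_af = af,
      topmed_af = if (is.na(af)) NA_real_ else signif(af * runif(1, 0.5, 1.2), 6),
      impact = sample(names(probs), 1L, prob = probs),
      pli = if (patho) signif(runif(1, 0.905, 0.999), 6) else
        signif(runif(1, 0, 0.89), 6),
      loeuf = if (patho) signif(runif(1, 0.01, 0.35), 6) else
        signif(runif(1, 0.37, 1.9), 6),
      gnomad_hom_count = 0L,
      spliceai_max = NA_real_,
      planted_mode = mode, target_sample = target, family_id = fam,
      planted_pathogenic = patho
    )
  }
  losses <- ped[outcome == "loss" & has_sample == TRUE]
  for (i in seq_len(nrow(losses))) {
    ch <- losses[i]
    fam <- ch$family_id
    fa_id <- ch$father_id; mo_id <- ch$mother_id
    zero <- stats::setNames(rep(0L, length(samples)), samples)
    # one reserved gene per autosomal planted event, distinct within a child
    res_idx <- sample.int(nrow(gene_pool_res), per_child_genes)
    gene_iter <- 0L
    next_gene <- function() {
      gene_iter <<- gene_iter + 1L
      gene_pool_res[res_idx[gene_iter]]
    }
    # de novo: child het, everyone else reference
    for (k in seq_len(cfg$planted$de_novo)) {
      g <- next_gene()
      v <- plant_site(g, "de_novo", ch$individual_id, fam)
      d <- zero; d[ch$individual_id] <- 1L
      planted_vars[[length(planted_vars) + 1L]] <- v
      planted_dose[[length(planted_dose) + 1L]] <- d
    }
    # autosomal dominant: alternate transmitting parent
    for (k in seq_len(cfg$planted$autosomal_dominant)) {
      g <- next_gene()
      v <- plant_site(g, "autosomal_dominant", ch$individual_id, fam)
      d <- zero
      d[if (k %% 2L == 1L) fa_id else mo_id] <- 1L
      d[ch$individual_id] <- 1L
      planted_vars[[length(planted_vars) + 1L]] <- v
      planted_dose[[length(planted_dose) + 1L]] <- d
    }
    # compound-het pairs: one site from each parent in a shared gene
    for (k in seq_len(cfg$planted$comp_het)) {
      g <- next_gene()
      vA <- plant_site(g, "comp_het", ch$individual_id, fam)
      vB <- plant_site(g, "comp_het", ch$individual_id, fam)
      dA <- zero; dA[fa_id] <- 1L; dA[ch$individual_id] <- 1L
      dB <- zero; dB[mo_id] <- 1L; dB[ch$individual_id] <- 1L
      planted_vars[[length(planted_vars) + 1L]] <- vA
      planted_dose[[length(planted_dose) + 1L]] <- dA
      planted_vars[[length(planted_vars) + 1L]] <- vB
      planted_dose[[length(planted_dose) + 1L]] <- dB
    }
    # X-linked recessive: carrier mother; hemizygous son or biallelic daughter
    for (k in seq_len(cfg$planted$x_linked_recessive)) {
      g <- gene_pool_x[sample.int(nrow(gene_pool_x), 1L)]
      v <- plant_site(g, "x_linked_recessive", ch$individual_id, fam)
      d <- zero
      d[mo_id] <- 1L
      if (ch$sex == "male") {
        d[ch$individual_id] <- 1L
      } else {
        d[fa_id] <- 1L
        d[ch$individual_id] <- 2L
      }
      planted_vars[[length(planted_vars) + 1L]] <- v
      planted_dose[[length(planted_dose) + 1L]] <- d
    }
  }
  if (length(planted_vars) > 0L) {
    pv <- rbindlist(planted_vars)
    pd <- do.call(rbind, planted_dose)
    all_vars <- rbind(
      cbind(bg, data.table(planted_mode = "background",
                           target_sample = NA_character_,
                           family_id = NA_character_,
                           planted_pathogenic = NA)),
      pv)
    dose <- rbind(dose, pd)
  } else {
    all_vars <- cbind(bg, data.table(planted_mode = "background",
                                     target_sample = NA_character_,
                                     family_id = NA_character_,
                                     planted_pathogenic = NA))
  }
  all_vars[, variant_key := make_variant_key(chrom, pos, ref, alt)]

  ## ---- expected calls from the noise-free dosage matrix ----
  expected <- expected_calls_from_dosage(dose, all_vars, ped)

  ## ---- noise: genotype errors, then FFPE artifacts ----
  is_x_all <- all_vars$chrom == "chrX"
  if (cfg$genotype_error_rate > 0) {
    for (s in samples) {
      hit <- which(runif(nrow(dose)) < cfg$genotype_error_rate)
      for (r in hit) {
        domain <- if (is_x_all[r] && male[s]) 0:1 else 0:2
        dose[r, s] <- sample(setdiff(domain, dose[r, s]), 1L)
      }
    }
  }
  artifact_cells <- data.table(variant_key = character(),
                               sample_id = character())
  if (cfg$ffpe_artifact_rate > 0) {
    bg_auto <- which(all_vars$planted_mode == "background" & !is_x_all)
    ct_ga <- (all_vars$ref == "C" & all_vars$alt == "T") |
      (all_vars$ref == "G" & all_vars$alt == "A")
    w <- fifelse(ct_ga[bg_auto], cfg$ffpe_bias_odds, 1)
    p_cell <- pmin(1, cfg$ffpe_artifact_rate * w / mean(w))
    loss_samples <- losses$individual_id
    hits <- list()
    for (s in loss_samples) {
      eligible <- bg_auto[dose[bg_auto, s] == 0L]
      p <- p_cell[match(eligible, bg_auto)]
      hit <- eligible[runif(length(eligible)) < p]
      if (length(hit) > 0L) {
        dose[hit, s] <- 1L
        hits[[s]] <- data.table(variant_key = all_vars$variant_key[hit],
                                sample_id = s)
      }
    }
    if (length(hits) > 0L) artifact_cells <- rbindlist(hits)
  }

  ## ---- genotype quality and the long genotype table ----
  n_var <- nrow(all_vars)
  long <- data.table(
    variant_key = rep(all_vars$variant_key, times = length(samples)),
    sample_id = rep(samples, each = n_var),
    d = as.vector(dose),
    haploid = rep(is_x_all, times = length(samples)) &
      rep(unname(male), each = n_var)
  )
  long[, dp := rpois(.N, cfg$depth)]
  long[dp < 1L, dp := 1L]
  long[, gq := sample(40:99, .N, replace = TRUE)]
  long[, gt := fcase(
    haploid & d == 0L, "hemi_ref",
    haploid & d >= 1L, "hemi_alt",
    d == 0L, "hom_ref",
    d == 1L, "het",
    d == 2L, "hom_alt"
  )]
  long[, ad_alt := fcase(
    gt %in% c("hom_ref", "hemi_ref"), 0L,
    gt %in% c("hom_alt", "hemi_alt"), dp,
    gt == "het", rbinom(.N, dp, 0.5)
  )]
  long[, ad_ref := dp - ad_alt]

  # clean quality for planted de novo trios (a de novo claim must pass gates)
  dn <- all_vars[planted_mode == "de_novo"]
  if (nrow(dn) > 0L) {
    trios <- ped[match(dn$target_sample, individual_id)]
    fix_cells <- rbind(
      data.table(variant_key = dn$variant_key, sample_id = dn$target_sample,
                 is_child = TRUE),
      data.table(variant_key = dn$variant_key, sample_id = trios$father_id,
                 is_child = FALSE),
      data.table(variant_key = dn$variant_key, sample_id = trios$mother_id,
                 is_child = FALSE))
    long[fix_cells, on = c("variant_key", "sample_id"),
         `:=`(dp = 30L, gq = 60L)]
    long[fix_cells[is_child == TRUE], on = c("variant_key", "sample_id"),
         `:=`(ad_ref = 15L, ad_alt = 15L)]
    long[fix_cells[is_child == FALSE], on = c("variant_key", "sample_id"),
         `:=`(ad_ref = 30L, ad_alt = 0L)]
  }
  # FFPE artifacts: low allele balance, shakier depth/quality
  if (nrow(artifact_cells) > 0L) {
    n_a <- nrow(artifact_cells)
    adp <- rpois(n_a, 25) + 5L
    ab <- runif(n_a, 0.08, 0.35)
    aalt <- pmax(1L, as.integer(round(adp * ab)))
    long[artifact_cells, on = c("variant_key", "sample_id"),
         `:=`(dp = adp, gq = sample(20:70, n_a, replace = TRUE),
              ad_alt = aalt, ad_ref = adp - aalt)]
  }

  vs <- list(
    variants = all_vars[, .(variant_key, chrom, pos, ref, alt, gene, impact,
                            gnomad_af, topmed_af, gnomad_hom_count, pli,
                            loeuf, spliceai_max)],
    genotypes = long[, .(variant_key, sample_id, gt, gq, dp, ad_ref, ad_alt)]
  )
  setorder(vs$variants, chrom, pos, alt)
  setkey(vs$genotypes, variant_key, sample_id)

  truth <- all_vars[, .(
    variant_key, planted_mode, target_sample, family_id, gene, impact,
    rare = filter_rare(gnomad_af, topmed_af),
    impactful = filter_impactful(impact),
    pathogenic = filter_pathogenic(pli, loeuf),
    control_hom_zero = !is.na(gnomad_hom_count) & gnomad_hom_count == 0L
  )]

  vcf_path <- file.path(dir, "cohort.vcf")
  ped_path <- file.path(dir, "cohort.ped")
  write_variants(vs, vcf_path, sample_order = samples)
  write_pedigree(ped, ped_path)
  fwrite(truth, file.path(dir, "truth_variants.tsv"), sep = "\t")
  fwrite(expected, file.path(dir, "expected_calls.tsv"), sep = "\t")
  fwrite(artifact_cells, file.path(dir, "artifacts.tsv"), sep = "\t")

  list(vcf = vcf_path, ped = ped_path, vs = vs, pedigree = ped,
       truth = truth, expected_calls = expected,
       artifacts = artifact_cells, genes = genes, config = cfg)
}

# derive the calls the engine should produce, from dosage matrices.
# Runs inside the generator on its internal representation; the engine
# works from the written VCF, so agreement exercises the whole I/O path.
expected_calls_from_dosage <- function(dose, vars, ped) {
  on_x <- vars$chrom == "chrX"
  out <- list()
  offspring <- ped[!is.na(father_id) & !is.na(mother_id) & has_sample == TRUE]
  sampled <- ped[has_sample == TRUE, individual_id]
  offspring <- offspring[father_id %in% sampled & mother_id %in% sampled]
  for (i in seq_len(nrow(offspring))) {
    ch <- offspring[i]
    cd <- dose[, ch$individual_id]
    fd <- dose[, ch$father_id]
    md <- dose[, ch$mother_id]
    emit <- function(idx, mode, origin) {
      if (length(idx) == 0L) return(NULL)
      data.table(variant_key = vars$variant_key[idx],
                 sample_id = ch$individual_id, family_id = ch$family_id,
                 mode = mode, parent_of_origin = origin)
    }
    dn <- which(cd == 1L & fd == 0L & md == 0L)
    res <- list(emit(dn, "de_novo", "none"))
    dom_f <- which(!on_x & cd == 1L & fd == 1L & md == 0L)
    dom_m <- which(!on_x & cd == 1L & md == 1L & fd == 0L)
    if (ch$sex == "male") {
      xr <- which(on_x & cd == 1L & md == 1L & fd == 0L)
      res <- c(res, list(emit(xr, "x_linked_recessive", "mother")))
    } else if (ch$sex == "female") {
      xr <- which(on_x & cd == 2L & md == 1L & fd == 1L)
      res <- c(res, list(emit(xr, "x_linked_recessive", "ambiguous")))
    }
    # compound hets: autosomal child-het sites with unambiguous, opposite origins
    het_idx <- which(!on_x & cd == 1L & !is.na(vars$gene))
    if (length(het_idx) >= 2L) {
      hh <- data.table(idx = het_idx, gene = vars$gene[het_idx],
                       fa_car = fd[het_idx] > 0L, mo_car = md[het_idx] > 0L)
      hh[, origin := fcase(fa_car & !mo_car, "father",
                           mo_car & !fa_car, "mother",
                           default = "other")]
      counts <- hh[origin %in% c("father", "mother"),
                   .(nf = sum(origin == "father"), nm = sum(origin == "mother")),
                   by = gene]
      ch_genes <- counts[nf >= 1L & nm >= 1L, gene]
      chh <- hh[gene %in% ch_genes & origin %in% c("father", "mother")]
      res <- c(res, list(emit(chh$idx, "comp_het", chh$origin)))
      # precedence: comp-het members are not also dominant calls
      dom_f <- setdiff(dom_f, chh$idx)
      dom_m <- setdiff(dom_m, chh$idx)
    }
    res <- c(res, list(emit(dom_f, "autosomal_dominant", "father"),
                       emit(dom_m, "autosomal_dominant", "mother")))
    out[[i]] <- rbindlist(res)
  }
  rbindlist(out)
}

#' Simulate null de novo count replicates
#'
#' Calibration harness for [de_novo_burden()]: draws per-sample de novo
#' LoF counts from the null Poisson model at the expected rate, many
#' replicates at a time, so the test's type-I error can be estimated
#' empirically.
#'
#' @param n_samples Samples per replicate.
#' @param expected_rate Per-sample Poisson rate (> 0).
#' @param n_replicates Number of replicate cohorts.
#' @param seed Random seed.
#' @return Integer matrix `n_replicates x n_samples` of de novo counts.
#' @export
simulate_null_burden <- function(n_samples, expected_rate, n_replicates,
                                 seed = 1L) {
  stopifnot(expected_rate > 0, n_samples >= 1, n_replicates >= 1)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  matrix(rpois(n_samples * n_replicates, expected_rate),
         nrow = n_replicates, ncol = n_samples)
}
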