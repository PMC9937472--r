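test_that("rarity uses strict thresholds and treats missing frequency as novel", {
  expect_identical(filter_rare(c(0.0005, 0.001, NA_real_)),
                   c(TRUE, FALSE, TRUE))
  # both population panels must pass
  expect_false(filter_rare(0.0005, topmed_af = 0.002))
  expect_true(filter_rare(0.0005, topmed_af = 0.0004))
  expect_true(filter_rare(NA_real_, topmed_af = NA_real_))
  # configurable ceiling (e.g. the laxer compound-het setting)
  expect_true(filter_rare(0.004, af_max = 0.006))
})

test_that("impact filter keeps exactly the protein-altering classes", {
  expect_identical(
    filter_impactful(c("missense", "frameshift", "inframe_indel",
                       "stop_gained", "stop_retained", "splice_region",
                       "other", NA)),
    c(rep(TRUE, 6), FALSE, FALSE))
})

test_that("constraint-based pathogenicity requires both metrics, strictly", {
  expect_identical(
    filter_pathogenic(pli = c(0.95, 0.90, 0.95, NA, 0.95),
                      loeuf = c(0.30, 0.30, 0.36, 0.30, NA)),
    c(TRUE, FALSE, FALSE, FALSE, FALSE))
})

test_that("control-homozygote check rejects any observed homozygote", {
  chk <- control_hom_check(c(0L, 0L, NA), c(0L, 3L, 0L))
  expect_identical(chk$retained, c(TRUE, FALSE, TRUE))
  expect_identical(chk$caveat, c(FALSE, FALSE, TRUE))
})

test_that("gene-list filter is set membership with an empty-list bypass", {
  genes <- c("DICER1", "FBN2", "FLT4", "HERC1", "TAOK1")
  expect_true(filter_gene_list("FBN2", genes))
  expect_false(filter_gene_list("MUC16", genes))
  expect_true(all(filter_gene_list(c("MUC16", NA, "X"), character())))
  f <- write_lines_tmp(c("# phenotype genes", "DICER1", "", "FBN2"))
  expect_identical(read_gene_list(f), c("DICER1", "FBN2"))
  expect_error(read_gene_list("/nonexistent/genes.txt"), "not found")
})

contrast_fixture <- function() {
  ped <- quad_ped()
  v1 <- var_row(pos = 1L)   # only the loss carries it
  v2 <- var_row(pos = 2L)   # loss and live-birth sibling carry it
  v3 <- var_row(pos = 3L)   # only a parent carries it
  geno <- rbind(
    geno_row(v1$variant_key, "kid", "het"),
    geno_row(v1$variant_key, "sib", "hom_ref"),
    geno_row(v2$variant_key, "kid", "het"),
    geno_row(v2$variant_key, "sib", "het"),
    geno_row(v3$variant_key, "dad", "het"),
    geno_row(v3$variant_key, "kid", "hom_ref"))
  list(vs = make_vs(rbind(v1, v2, v3), geno), ped = ped)
}

test_that("loss-versus-live-birth contrast is cohort-wide, genotype-level", {
  fx <- contrast_fixture()
  ct <- contrast_losses_vs_livebirths(fx$vs, fx$ped)
  expect_identical(ct[order(variant_key)]$loss_only,
                   ct[order(variant_key)][, variant_key == "chr1:1:A:G"])
  expect_equal(ct[variant_key == "chr1:1:A:G", carrier_epochs], "fetal_death")
  # a parent carrier does not enter the contrast at all
  expect_false(ct[variant_key == "chr1:3:A:G", loss_only])
})

test_that("removing a live-birth carrier can only turn loss_only on, never off", {
  sc <- small_cohort()
  vs <- sc$pipe$vs
  ped <- sc$pipe$pedigree
  before <- contrast_losses_vs_livebirths(vs, ped)
  lb <- ped[outcome == "live_birth" & has_sample == TRUE, individual_id][1]
  vs2 <- list(variants = vs$variants,
              genotypes = vs$genotypes[sample_id != lb])
  after <- contrast_losses_vs_livebirths(vs2, ped[individual_id != lb])
  m <- merge(before[, .(variant_key, before = loss_only)],
             after[, .(variant_key, after = loss_only)], by = "variant_key")
  expect_false(any(m$before & !m$after))
  expect_gt(sum(!m$before & m$after), 0L)  # some variants do flip on
})

test_that("prioritize gates candidacy on rarity and impact and flags the rest", {
  ped <- quad_ped()
  vars <- rbind(
    var_row(pos = 10L, gnomad_af = 0.05),                      # common
    var_row(pos = 20L, impact = "other"),                      # not impactful
    var_row(pos = 30L, pli = 0.95, loeuf = 0.2),               # full pass
    var_row(pos = 40L, gnomad_hom_count = 3L))                 # control homs
  geno <- rbindlist(lapply(vars$variant_key, function(k) rbind(
    geno_row(k, "kid", "het"), geno_row(k, "dad", "hom_ref"),
    geno_row(k, "mum", "het"), geno_row(k, "sib", "hom_ref"))))
  vs <- make_vs(vars, geno)
  calls <- suppressMessages(classify_cohort(vs, ped))
  cand <- prioritize(calls, vs, ped)
  expect_setequal(cand$variant_key,
                  c("chr1:30:A:G", "chr1:40:A:G"))
  expect_true(cand[variant_key == "chr1:30:A:G", is_pathogenic])
  expect_true(cand[variant_key == "chr1:30:A:G", loss_only])
  expect_false(cand[variant_key == "chr1:40:A:G", control_hom_absent])
  expect_true(all(cand$mode == "autosomal_dominant"))
})

test_that("a comp-het member inherits its partner's control-homozygote evidence", {
  ped <- quad_ped()
  vars <- rbind(
    var_row(pos = 100L, gene = "GENEX", gnomad_hom_count = 0L),
    var_row(pos = 200L, gene = "GENEX", gnomad_hom_count = 2L))
  geno <- rbind(
    geno_row(vars$variant_key[1], "kid", "het"),
    geno_row(vars$variant_key[1], "dad", "het"),
    geno_row(vars$variant_key[1], "mum", "hom_ref"),
    geno_row(vars$variant_key[1], "sib", "hom_ref"),
    geno_row(vars$variant_key[2], "kid", "het"),
    geno_row(vars$variant_key[2], "dad", "hom_ref"),
    geno_row(vars$variant_key[2], "mum", "het"),
    geno_row(vars$variant_key[2], "sib", "hom_ref"))
  vs <- make_vs(vars, geno)
  cand <- prioritize(suppressMessages(classify_cohort(vs, ped)), vs, ped)
  ch <- cand[mode == "comp_het"]
  expect_equal(nrow(ch), 2L)
  # the clean member is poisoned by its partner's homozygote count
  expect_false(any(ch$control_hom_absent))
})

test_that("flags are pure: recomputation and row order do not change them", {
  sc <- small_cohort()
  a <- prioritize(sc$pipe$calls, sc$pipe$vs, sc$pipe$pedigree)
  b <- prioritize(sc$pipe$calls[sample(.N)], sc$pipe$vs, sc$pipe$pedigree)
  key <- c("variant_key", "sample_id", "mode")
  setkeyv(a, key); setkeyv(b, key)
  expect_identical(as.data.frame(a), as.data.frame(b))
})

test_that("per-mode frequency ceilings apply to compound hets separately", {
  ped <- quad_ped()
  vars <- rbind(
    var_row(pos = 100L, gene = "GENEX", gnomad_af = 0.004),
    var_row(pos = 200L, gene = "GENEX", gnomad_af = 0.004))
  geno <- rbind(
    geno_row(vars$variant_key[1], "kid", "het"),
    geno_row(vars$variant_key[1], "dad", "het"),
    geno_row(vars$variant_key[1], "mum", "hom_ref"),
    geno_row(vars$variant_key[1], "sib", "hom_ref"),
    geno_row(vars$variant_key[2], "kid", "het"),
    geno_row(vars$variant_key[2], "dad", "hom_ref"),
    geno_row(vars$variant_key[2], "mum", "het"),
    geno_row(vars$variant_key[2], "sib", "hom_ref"))
  vs <- make_vs(vars, geno)
  calls <- suppressMessages(classify_cohort(vs, ped))
  cfg <- default_config()
  expect_equal(nrow(prioritize(calls, vs, ped, cfg)), 0L)  # 0.004 > 0.001
  cfg$af_max_comphet <- 0.006
  cand <- prioritize(calls, vs, ped, cfg)
  expect_equal(sort(cand$mode), c("comp_het", "comp_het"))
})
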