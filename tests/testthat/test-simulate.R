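test_that("a fixed seed reproduces the cohort byte for byte", {
  cfg <- sim_config(background_variants = 400L, seed = 7L)
  s1 <- simulate_cohort(cfg, dir = tempfile())
  s2 <- simulate_cohort(cfg, dir = tempfile())
  expect_identical(readLines(s1$vcf), readLines(s2$vcf))
  expect_identical(readLines(s1$ped), readLines(s2$ped))
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$expected_calls, s2$expected_calls)
})

test_that("truth bookkeeping is complete and matches the planted design", {
  sc <- small_cohort()
  cfg <- sc$sim$config
  truth <- sc$sim$truth
  n_loss <- sc$sim$pedigree[outcome == "loss" & has_sample == TRUE, .N]
  expect_equal(truth[planted_mode == "de_novo", .N],
               cfg$planted$de_novo * n_loss)
  expect_equal(truth[planted_mode == "autosomal_dominant", .N],
               cfg$planted$autosomal_dominant * n_loss)
  expect_equal(truth[planted_mode == "comp_het", .N],
               2L * cfg$planted$comp_het * n_loss)
  expect_equal(truth[planted_mode == "x_linked_recessive", .N],
               cfg$planted$x_linked_recessive * n_loss)
  # every VCF record is either planted or labeled background
  expect_setequal(sc$sim$vs$variants$variant_key, truth$variant_key)
  expect_true(all(truth$planted_mode %in%
                    c("background", "de_novo", "autosomal_dominant",
                      "comp_het", "x_linked_recessive")))
  # planted variants are rare, impactful, and unseen in control homozygotes
  planted <- truth[planted_mode != "background"]
  expect_true(all(planted$rare))
  expect_true(all(planted$impactful))
  expect_true(all(planted$control_hom_zero))
})

test_that("the pedigree mirrors the family design, including unsampled losses", {
  sc <- small_cohort()
  ped <- sc$sim$pedigree
  expect_equal(ped[, .N], 3L * (2L + nrow(default_family_design())))
  expect_equal(ped[outcome == "loss" & has_sample == FALSE, unique(epoch)],
               "embryonic_loss")
  expect_equal(ped[has_sample == TRUE & outcome == "loss", .N] / 3L, 4L)
})

test_that("background allele frequencies follow the configured mixture", {
  sim <- acceptance_cohort()$sim
  af <- sim$truth[planted_mode == "background"]
  af <- sim$vs$variants[af, on = "variant_key"]$gnomad_af
  spec <- sim$config$af_spec
  expect_equal(mean(is.na(af)), spec$p_novel, tolerance = 0.15)
  x <- sort(af[!is.na(af)])
  w_common <- spec$p_common / (1 - spec$p_novel)
  mix_cdf <- function(q) (1 - w_common) * pbeta(q, spec$beta_shape1, spec$beta_shape2) +
    w_common * punif(q, 0.01, 0.5)
  ks <- max(abs(seq_along(x) / length(x) - mix_cdf(x)))
  expect_lt(ks, 0.025)
})

test_that("Mendelian transmission holds everywhere except planted de novo sites", {
  sc <- small_cohort()
  viol <- mendelian_violations(sc$sim$vs, sc$sim$pedigree)
  dn <- sc$sim$truth[planted_mode == "de_novo",
                     .(variant_key, sample_id = target_sample)]
  expect_equal(nrow(viol[!dn, on = c("variant_key", "sample_id")]), 0L)
})

test_that("male X genotypes are hemizygous throughout", {
  sc <- small_cohort()
  males <- sc$sim$pedigree[sex == "male" & has_sample == TRUE, individual_id]
  xkeys <- sc$sim$vs$variants[chrom == "chrX", variant_key]
  gx <- sc$sim$vs$genotypes[variant_key %in% xkeys & sample_id %in% males]
  expect_true(all(gx$gt %in% c("hemi_ref", "hemi_alt")))
})

test_that("FFPE artifacts hit only loss samples with the configured C>T/G>A bias", {
  cfg <- sim_config(background_variants = 4000L, ffpe_artifact_rate = 0.05,
                    seed = 99L)
  sim <- simulate_cohort(cfg, dir = tempfile())
  art <- sim$artifacts
  expect_gt(nrow(art), 50L)
  losses <- sim$pedigree[outcome == "loss" & has_sample == TRUE, individual_id]
  expect_true(all(art$sample_id %in% losses))
  # artifacts are false het calls at background autosomal sites
  av <- sim$vs$variants[art, on = "variant_key"]
  expect_true(all(av$chrom != "chrX"))
  expect_true(all(sim$truth[variant_key %in% art$variant_key,
                            planted_mode == "background"]))
  ag <- sim$vs$genotypes[art, on = c("variant_key", "sample_id")]
  expect_true(all(ag$gt == "het"))
  # substitution bias: relative artifact rate at C>T / G>A sites vs others
  bg <- sim$vs$variants[sim$truth[planted_mode == "background"],
                        on = "variant_key"][chrom != "chrX"]
  bg[, ct_ga := (ref == "C" & alt == "T") | (ref == "G" & alt == "A")]
  hit <- bg$variant_key %in% art$variant_key
  odds <- (mean(hit[bg$ct_ga]) / mean(hit[!bg$ct_ga]))
  expect_gt(odds, cfg$ffpe_bias_odds * 0.6)
  expect_lt(odds, cfg$ffpe_bias_odds * 1.6)
})

test_that("infeasible designs fail with a named constraint", {
  expect_error(simulate_cohort(
    sim_config(planted = list(de_novo = 50L, autosomal_dominant = 50L,
                              comp_het = 10L, x_linked_recessive = 0L))),
    "reserved genes")
  expect_error(simulate_cohort(
    sim_config(n_genes = list(autosomal = 100L, x = 0L,
                              reserve_planted = 20L),
               x_background_frac = 0)),
    "no X genes")
})

test_that("null burden replicates are seeded draws at the expected rate", {
  m <- simulate_null_burden(6, 0.2, 1000, seed = 3L)
  expect_equal(dim(m), c(1000L, 6L))
  expect_equal(mean(m), 0.2, tolerance = 0.05)
  expect_identical(m, simulate_null_burden(6, 0.2, 1000, seed = 3L))
})
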