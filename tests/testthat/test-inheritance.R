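classify1 <- function(vs, ped = quad_ped(), cfg = default_config()) {
  suppressMessages(classify_family(vs, ped, "FAM1", cfg))
}
kid_calls <- function(vs, ...) classify1(vs, ...)[sample_id == "kid"]

test_that("canonical de novo configuration is called with passing quality", {
  vs <- trio_vs("het", "hom_ref", "hom_ref",
                child_q = list(gq = 50L, dp = 30L, ad_alt = 16L))
  calls <- kid_calls(vs)
  expect_equal(calls$mode, "de_novo")
  expect_equal(calls$parent_of_origin, "none")
  expect_true(calls$quality_pass)
})

test_that("a transmitted allele is never de novo", {
  expect_equal(nrow(kid_calls(trio_vs("het", "het", "hom_ref"))[mode == "de_novo"]), 0L)
  expect_equal(nrow(kid_calls(trio_vs("hom_ref", "het", "hom_ref"))), 0L)
})

test_that("the de novo allele-balance accept region is exactly [0.2, 0.8]", {
  passes <- vapply(0:20, function(k) {
    vs <- trio_vs("het", "hom_ref", "hom_ref",
                  child_q = list(dp = 20L, ad_alt = k))
    kid_calls(vs)$quality_pass
  }, logical(1))
  expect_identical(passes, 0:20 >= 4L & 0:20 <= 16L)  # 0.2*20 .. 0.8*20
})

test_that("de novo quality gates fail closed on missing or bad evidence", {
  base <- function(...) kid_calls(trio_vs("het", "hom_ref", "hom_ref", ...))
  expect_false(base(child_q = list(gq = 19L))$quality_pass)       # low GQ
  expect_false(base(child_q = list(dp = 9L, ad_alt = 4L))$quality_pass) # low DP
  expect_false(base(father_q = list(dp = 8L))$quality_pass)       # parent DP
  expect_false(base(father_q = list(ad_alt = 1L))$quality_pass)   # parent alt read
  # missing quality fields fail the gate (fail-closed)
  vs <- trio_vs("het", "hom_ref", "hom_ref")
  vs$genotypes[sample_id == "kid", `:=`(gq = NA_integer_)]
  expect_false(kid_calls(vs)$quality_pass)
})

test_that("raising quality thresholds never admits more de novo calls", {
  set.seed(99)
  n_pass <- vapply(c(10L, 20L, 40L, 60L, 80L), function(gq_min) {
    cfg <- default_config()
    cfg$denovo$gq_min <- gq_min
    sum(vapply(1:25, function(i) {
      set.seed(1000L + i)
      vs <- trio_vs("het", "hom_ref", "hom_ref",
                    child_q = list(gq = sample(5:95, 1), dp = 30L, ad_alt = 15L))
      kid_calls(vs, cfg = cfg)$quality_pass
    }, logical(1)))
  }, integer(1))
  expect_true(all(diff(n_pass) <= 0L))
})

test_that("autosomal dominant requires exactly one heterozygous parent", {
  d <- kid_calls(trio_vs("het", "hom_ref", "het"))
  expect_equal(d$mode, "autosomal_dominant")
  expect_equal(d$parent_of_origin, "mother")
  # ambiguous origin (both parents het) is not called
  expect_equal(nrow(kid_calls(trio_vs("het", "het", "het"))), 0L)
  # hom-alt carrier parent is not an unambiguous dominant configuration
  expect_equal(nrow(kid_calls(trio_vs("het", "hom_alt", "hom_ref"))), 0L)
  # hom-alt children are outside the four modes
  expect_equal(nrow(kid_calls(trio_vs("hom_alt", "het", "het"))), 0L)
})

test_that("X-linked recessive follows the sex-specific hemizygous patterns", {
  xr <- kid_calls(trio_vs("hemi_alt", "hemi_ref", "het", chrom = "chrX"))
  expect_equal(xr$mode, "x_linked_recessive")
  expect_equal(xr$parent_of_origin, "mother")
  # mother without the allele: candidate de novo, not XLR
  dn <- kid_calls(trio_vs("hemi_alt", "hemi_ref", "hom_ref", chrom = "chrX"))
  expect_equal(dn$mode, "de_novo")
  # female carrier (het) on X is not affected-recessive
  ped <- quad_ped()
  vsf <- trio_vs("het", "hemi_alt", "het", chrom = "chrX")
  ped[individual_id == "kid", sex := "female"]
  expect_equal(nrow(kid_calls(vsf, ped = ped)[mode == "x_linked_recessive"]), 0L)
  # affected female: hom_alt with carrier mother and hemizygous-alt father
  vsf2 <- trio_vs("hom_alt", "hemi_alt", "het", chrom = "chrX")
  xrf <- kid_calls(vsf2, ped = ped)
  expect_equal(xrf$mode, "x_linked_recessive")
  expect_equal(xrf$parent_of_origin, "ambiguous")
})

comphet_vs <- function(gts) {
  # gts: list of c(kid, dad, mum) per site, all in gene GENE0001
  vars <- rbindlist(lapply(seq_along(gts), function(i)
    var_row(pos = 1000L + i, gene = "GENE0001")))
  geno <- rbindlist(lapply(seq_along(gts), function(i) rbind(
    geno_row(vars$variant_key[i], "kid", gts[[i]][1]),
    geno_row(vars$variant_key[i], "dad", gts[[i]][2]),
    geno_row(vars$variant_key[i], "mum", gts[[i]][3]),
    geno_row(vars$variant_key[i], "sib", "hom_ref"))))
  make_vs(vars, geno)
}

test_that("compound hets are called only in trans with disjoint parental carriage", {
  calls <- kid_calls(comphet_vs(list(c("het", "het", "hom_ref"),
                                     c("het", "hom_ref", "het"))))
  ch <- calls[mode == "comp_het"]
  expect_equal(nrow(ch), 2L)
  expect_setequal(ch$parent_of_origin, c("father", "mother"))
  expect_equal(ch$partner_variant_key, rev(ch$variant_key))
  expect_equal(uniqueN(ch$pair_id), 1L)
  # both alleles from the mother: cis cannot be excluded, nothing emitted
  cis <- classify1(comphet_vs(list(c("het", "hom_ref", "het"),
                                   c("het", "hom_ref", "het"))))
  expect_equal(nrow(cis[mode == "comp_het"]), 0L)
  amb <- attr(cis, "comphet_ambiguous")
  expect_equal(nrow(amb), 0L)  # same-parent sites are dominant-resolvable, not ambiguous
  # a parent carrying at both sites quarantines the ambiguous site
  both <- classify1(comphet_vs(list(c("het", "het", "hom_ref"),
                                    c("het", "het", "het"))))
  expect_equal(nrow(both[mode == "comp_het"]), 0L)
  amb2 <- attr(both, "comphet_ambiguous")
  expect_equal(amb2$reason, "both_parents_carry")
})

test_that("comp-het members are not double-counted as dominant calls", {
  calls <- kid_calls(comphet_vs(list(c("het", "het", "hom_ref"),
                                     c("het", "hom_ref", "het"))))
  expect_equal(nrow(calls[mode == "autosomal_dominant"]), 0L)
  # but a lone site in another gene still yields its dominant call
  vs <- comphet_vs(list(c("het", "het", "hom_ref"),
                        c("het", "hom_ref", "het")))
  lone <- var_row(pos = 5000L, gene = "GENE0002")
  vs$variants <- rbind(vs$variants, lone)
  vs$genotypes <- rbind(vs$genotypes, rbind(
    geno_row(lone$variant_key, "kid", "het"),
    geno_row(lone$variant_key, "dad", "hom_ref"),
    geno_row(lone$variant_key, "mum", "het"),
    geno_row(lone$variant_key, "sib", "hom_ref")))
  setkey(vs$genotypes, variant_key, sample_id)
  calls2 <- kid_calls(vs)
  expect_equal(calls2[variant_key == lone$variant_key, mode],
               "autosomal_dominant")
})

test_that("families without both sampled parents are skipped with a message", {
  ped <- quad_ped()
  ped[individual_id == "dad", has_sample := FALSE]
  vs <- trio_vs("het", "hom_ref", "hom_ref")
  vs$genotypes <- vs$genotypes[sample_id != "dad"]
  expect_message(calls <- classify_family(vs, ped, "FAM1"), "skipped")
  expect_equal(nrow(calls), 0L)
})

test_that("no variant-sample pair is both de novo and dominant, and pairs are symmetric", {
  calls <- acceptance_cohort()$pipe$calls
  wide <- calls[mode %in% c("de_novo", "autosomal_dominant"),
                .N, by = .(variant_key, sample_id)]
  expect_true(all(wide$N == 1L))
  pairs <- calls[mode == "comp_het"]
  # every member's partner is itself a comp-het call for the same child,
  # with the opposite parent of origin
  m <- merge(
    pairs[, .(sample_id, variant_key, parent_of_origin, partner_variant_key)],
    pairs[, .(sample_id, partner_variant_key = variant_key,
              partner_origin = parent_of_origin)],
    by = c("sample_id", "partner_variant_key"))
  expect_equal(nrow(m), nrow(pairs))
  expect_true(all(m$parent_of_origin != m$partner_origin))
})

test_that("live births are classified too, for the downstream contrast", {
  calls <- acceptance_cohort()$pipe$calls
  expect_gt(nrow(calls[outcome == "live_birth"]), 0L)
})
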