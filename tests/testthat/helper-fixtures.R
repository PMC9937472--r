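# shared fixtures: hand-built containers, pedigree files, cached cohorts

library(data.table)

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# standard test trio/quad pedigree: parents, male loss (15w6d), female live birth
quad_ped <- function() {
  f <- write_lines_tmp(c(
    "FAM1 dad 0 0 1 0 parent . 1",
    "FAM1 mum 0 0 2 0 parent . 1",
    "FAM1 kid dad mum 1 0 loss 15w6d 1",
    "FAM1 sib dad mum 2 0 live_birth . 1"
  ), ".ped")
  read_pedigree(f)
}

# annotation defaults for a hand-built variant row
var_row <- function(variant_key = NULL, chrom = "chr1", pos = 1000L,
                    ref = "A", alt = "G", gene = "GENE0001",
                    impact = "missense", gnomad_af = 1e-4, topmed_af = NA_real_,
                    gnomad_hom_count = 0L, pli = NA_real_, loeuf = NA_real_,
                    spliceai_max = NA_real_) {
  if (is.null(variant_key))
    variant_key <- paste(chrom, pos, ref, alt, sep = ":")
  data.table(variant_key = variant_key, chrom = chrom, pos = as.integer(pos),
             ref = ref, alt = alt, gene = gene, impact = impact,
             gnomad_af = gnomad_af, topmed_af = topmed_af,
             gnomad_hom_count = as.integer(gnomad_hom_count), pli = pli,
             loeuf = loeuf, spliceai_max = spliceai_max)
}

# genotype row with clean quality defaults consistent with the gt state
geno_row <- function(variant_key, sample_id, gt, gq = 60L, dp = 30L,
                     ad_alt = NULL) {
  if (is.null(ad_alt))
    ad_alt <- switch(gt, hom_ref = 0L, hemi_ref = 0L, het = dp %/% 2L,
                     hom_alt = dp, hemi_alt = dp, missing = NA_integer_)
  dp_use <- if (gt == "missing") NA_integer_ else as.integer(dp)
  data.table(variant_key = variant_key, sample_id = sample_id, gt = gt,
             gq = if (gt == "missing") NA_integer_ else as.integer(gq),
             dp = dp_use,
             ad_ref = if (is.na(dp_use)) NA_integer_ else dp_use - as.integer(ad_alt),
             ad_alt = as.integer(ad_alt))
}

make_vs <- function(variants, genotypes) {
  variants <- rbindlist(list(variants))
  genotypes <- rbindlist(list(genotypes))
  setkey(genotypes, variant_key, sample_id)
  list(variants = variants, genotypes = genotypes)
}

# one-variant trio container on the quad pedigree
trio_vs <- function(child_gt, father_gt, mother_gt, chrom = "chr1", ...,
                    child_q = list(), father_q = list(), mother_q = list()) {
  v <- var_row(chrom = chrom, ...)
  g <- rbind(
    do.call(geno_row, c(list(v$variant_key, "kid", child_gt), child_q)),
    do.call(geno_row, c(list(v$variant_key, "dad", father_gt), father_q)),
    do.call(geno_row, c(list(v$variant_key, "mum", mother_gt), mother_q)),
    geno_row(v$variant_key, "sib",
             if (chrom == "chrX") "hom_ref" else "hom_ref")
  )
  make_vs(v, g)
}

# a small hand-written VCF exercising decomposition, missingness and
# contig filtering; samples match quad_ped()
fixture_vcf <- function() {
  write_lines_tmp(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chr1>",
    "##contig=<ID=chrX>",
    "##INFO=<ID=GENE,Number=A,Type=String,Description=\"g\">",
    "##INFO=<ID=IMPACT,Number=A,Type=String,Description=\"i\">",
    "##INFO=<ID=GNOMAD_AF,Number=A,Type=Float,Description=\"af\">",
    "##INFO=<ID=PLI,Number=A,Type=Float,Description=\"p\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"gq\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"dp\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "dad", "mum", "kid", "sib"), collapse = "\t"),
    # multi-allelic site: ALT A,T with per-allele annotations
    paste(c("chr1", "100", ".", "G", "A,T", ".", "PASS",
            "GENE=GENE0001,GENE0001;IMPACT=missense,stop_gained;GNOMAD_AF=0.0005,0.002",
            "GT:GQ:DP:AD", "0/1:50:30:20,10,0", "0/2:40:28:14,0,14",
            "1/2:60:32:0,16,16", "0/0:55:30:30,0,0"), collapse = "\t"),
    # biallelic with no PLI annotation and a missing genotype
    paste(c("chr1", "200", ".", "C", "T", ".", "PASS",
            "GENE=GENE0002;IMPACT=splice_region;GNOMAD_AF=0.1",
            "GT:GQ:DP:AD", "0/1:50:30:15,15", "./.:.:.:.",
            "1/1:60:30:0,30", "0/1:45:22:11,11"), collapse = "\t"),
    # X site: males haploid, one diploid-coded male call to normalize
    paste(c("chrX", "300", ".", "A", "C", ".", "PASS",
            "GENE=GENE0003;IMPACT=missense;GNOMAD_AF=0.0001;PLI=0.95",
            "GT:GQ:DP", "1:50:30", "0/1:40:28", "1/1:60:32", "0/1:45:22"),
          collapse = "\t"),
    # record on an unplaced contig: skipped
    paste(c("chrUn_KI270302v1", "400", ".", "A", "G", ".", "PASS",
            "GENE=GENE0004", "GT", "0/1", "0/0", "0/0", "0/0"), collapse = "\t")
  ), ".vcf")
}

# --- cached expensive cohorts (built once per test run) ---
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, build) {
  if (is.null(.fixture_cache[[name]])) .fixture_cache[[name]] <- build()
  .fixture_cache[[name]]
}

# conditions for the recovery checks: >= 50 planted variants per mode
# (12 sampled losses) over a 10,000-site background, error-free, seeded
acceptance_sim_cfg <- function(seed = 4242L, ...) {
  sim_config(planted = list(de_novo = 5L, autosomal_dominant = 5L,
                            comp_het = 3L, x_linked_recessive = 5L),
             seed = seed, ...)
}

acceptance_cohort <- function() {
  cached("acc_cohort", function() {
    sim <- simulate_cohort(acceptance_sim_cfg(),
                           dir = file.path(tempdir(), "acc_cohort"))
    pipe <- run_pipeline(sim$vcf, sim$ped)
    list(sim = sim, pipe = pipe)
  })
}

small_cohort <- function() {
  cached("small_cohort", function() {
    sim <- simulate_cohort(sim_config(background_variants = 1500L,
                                      seed = 515L),
                           dir = file.path(tempdir(), "small_cohort"))
    pipe <- suppressWarnings(run_pipeline(sim$vcf, sim$ped))
    list(sim = sim, pipe = pipe)
  })
}
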