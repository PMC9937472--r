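#' Score engine calls against a simulated expected-call table
#'
#' Compares the inheritance engine's output with the expected calls a
#' simulated cohort should yield (see [simulate_cohort()]), per mode, on
#' the identity (variant_key, sample_id, mode, parent_of_origin).
#' De novo calls are scored at `quality_pass = TRUE` (the pipeline's
#' fail-closed convention for de novo claims).
#'
#' @param calls Calls from [classify_cohort()].
#' @param expected Expected-call table (`expected_calls` element of
#'   [simulate_cohort()] output).
#' @return data.table per mode: `n_expected`, `n_observed`, `n_correct`,
#'   `sensitivity`, `precision`.
#' @export
recovery_metrics <- function(calls, expected) {
  obs <- as.data.table(calls)[
    mode != "de_novo" | quality_pass == TRUE,
    .(variant_key, sample_id, mode, parent_of_origin)]
  obs <- unique(obs)
  exp <- unique(as.data.table(expected)[,
    .(variant_key, sample_id, mode, parent_of_origin)])
  modes <- sort(unique(c(obs$mode, exp$mode)))
  rbindlist(lapply(modes, function(m) {
    o <- obs[mode == m]
    e <- exp[mode == m]
    hit <- nrow(fintersect(o, e))
    data.table(mode = m, n_expected = nrow(e), n_observed = nrow(o),
               n_correct = hit,
               sensitivity = if (nrow(e) > 0L) hit / nrow(e) else NA_real_,
               precision = if (nrow(o) > 0L) hit / nrow(o) else NA_real_)
  }))
}

#' Run the full prioritization pipeline on files
#'
#' Convenience wrapper: read pedigree and VCF, classify inheritance,
#' prioritize. The numbered analysis scripts and the acceptance checks
#' are thin drivers over this.
#'
#' @param vcf,ped File paths.
#' @param config Pipeline configuration.
#' @return List: `pedigree`, `vs`, `calls`, `candidates`, `sex_check`.
#' @export
run_pipeline <- function(vcf, ped, config = default_config()) {
  pedigree <- read_pedigree(ped)
  vs <- read_variants(vcf, pedigree, config)
  sexes <- sex_check(vs, pedigree, config)
  calls <- classify_cohort(vs, pedigree, config)
  candidates <- prioritize(calls, vs, pedigree, config)
  list(pedigree = pedigree, vs = vs, calls = calls,
       candidates = candidates, sex_check = sexes)
}
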