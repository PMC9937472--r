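#' Default pipeline configuration
#'
#' One list drives the whole pipeline: contig whitelist, VCF annotation key
#' names (the INFO fields the annotation tool wrote, which differ between
#' tools and are therefore mapped rather than hard-coded), filter thresholds
#' and de novo quality gates.
#'
#' Key defaults: gnomAD/TopMed allele-frequency ceiling `af_max = 0.001`
#' (strict inequality; the compound-het ladder has its own
#' `af_max_comphet`), constraint gates `pli_min = 0.9` and
#' `loeuf_max = 0.36` (both strict), and de novo quality gates
#' GQ >= 20, DP >= 10 in all trio members, child allele balance in
#' [0.2, 0.8], and zero alt-supporting reads in either parent.
#'
#' @return A nested named list of configuration values.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$af_max
default_config <- function() {
  list(
    # contigs the pipeline keeps; records elsewhere are counted and skipped
    contigs = c("chr1", "chr2", "chrX"),
    x_chrom = "chrX",
    annotation_keys = list(
      gene             = "GENE",
      impact           = "IMPACT",
      gnomad_af        = "GNOMAD_AF",
      topmed_af        = "TOPMED_AF",
      gnomad_hom_count = "GNOMAD_NHOMALT",
      pli              = "PLI",
      loeuf            = "LOEUF",
      spliceai_max     = "SPLICEAI_MAX"
    ),
    af_max         = 0.001,
    af_max_comphet = 0.001,
    pli_min        = 0.9,
    loeuf_max      = 0.36,
    gene_list_path = NULL,
    impactful_classes = c("missense", "frameshift", "inframe_indel",
                          "stop_gained", "stop_retained", "splice_region"),
    lof_classes = c("frameshift", "stop_gained", "splice_region"),
    denovo = list(
      gq_min = 20L,
      dp_min = 10L,
      ab_min = 0.2,
      ab_max = 0.8,
      parent_alt_max = 0L
    ),
    sex_check = list(
      min_sites  = 200L,
      min_alt_sites = 20L,
      het_female = 0.1,
      het_male   = 0.02
    ),
    expected_dn_rate = 0.2
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the matching entries of
#' [default_config()]; everything else keeps its default, so a config file
#' only needs the keys it changes.
#'
#' @param path Path to a YAML file, or `NULL` for pure defaults.
#' @return Configuration list as from [default_config()].
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("configuration file not found: ", path)
  user <- yaml::read_yaml(path)
  if (!is.list(user)) stop("configuration file must contain a YAML mapping: ", path)
  utils::modifyList(cfg, user)
}

# internal: merge partial overrides into a config list
merge_config <- function(cfg, overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(cfg)
  utils::modifyList(cfg, overrides)
}
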