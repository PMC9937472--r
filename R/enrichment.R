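#' Loss-of-function impact classification
#'
#' Frameshift, stop-gained and splice-region changes are treated as
#' loss-of-function; missense is protein-altering but not LoF. The set is
#' configurable (`config$lof_classes`).
#'
#' @param impact Character vector of impact classes.
#' @param lof_classes The LoF set.
#' @return Logical vector.
#' @export
lof_of <- function(impact, lof_classes = default_config()$lof_classes) {
  !is.na(impact) & impact %in% lof_classes
}

#' De novo loss-of-function burden test
#'
#' Compares the total number of de novo LoF calls observed across the
#' loss samples with the expectation under a per-sample background rate:
#' a one-sided Poisson test, `p = P(X >= observed_total)` with
#' `X ~ Poisson(expected_rate * n_samples)` - the simplest model
#' consistent with asking whether the observed mean exceeds the expected
#' mean. `method = "permutation"` replaces the analytic tail with a
#' Monte-Carlo draw from the same null (add-one convention), useful as a
#' robustness check since the analytic form is exact only if the null
#' really is Poisson.
#'
#' @param observed_total Total de novo LoF calls across loss samples.
#' @param n_samples Number of loss samples (>= 1).
#' @param expected_rate Expected de novo LoF calls per sample (> 0);
#'   default 0.2.
#' @param method `"poisson"` (analytic) or `"permutation"`.
#' @param n_permutations Monte-Carlo draws for the permutation method.
#' @param seed Seed for the permutation method.
#' @return List of class `"dn_burden"`: `n_samples`, `observed_total`,
#'   `observed_mean`, `expected_rate`, `p_value`, `method`.
#' @export
#' @examples
#' de_novo_burden(12, 6, 0.2)
de_novo_burden <- function(observed_total, n_samples,
                           expected_rate = 0.2,
                           method = c("poisson", "permutation"),
                           n_permutations = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (!is.numeric(expected_rate) || expected_rate <= 0)
    stop("expected_rate must be > 0")
  if (n_samples < 1L) stop("n_samples must be >= 1")
  observed_total <- as.integer(observed_total)
  lambda <- expected_rate * n_samples
  if (method == "poisson") {
    # P(X >= observed_total); equals 1 when observed_total == 0
    p <- stats::ppois(observed_total - 1L, lambda, lower.tail = FALSE)
  } else {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    draws <- stats::rpois(n_permutations, lambda)
    p <- (1 + sum(draws >= observed_total)) / (1 + n_permutations)
  }
  structure(list(
    n_samples = as.integer(n_samples),
    observed_total = observed_total,
    observed_mean = observed_total / n_samples,
    expected_rate = expected_rate,
    p_value = p,
    method = method
  ), class = "dn_burden")
}

#' @export
print.dn_burden <- function(x, ...) {
  cat(sprintf(
    "De novo LoF burden: %d calls in %d samples (mean %.2f vs expected %.2f); one-sided %s p = %.4g\n",
    x$observed_total, x$n_samples, x$observed_mean, x$expected_rate,
    x$method, x$p_value))
  invisible(x)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Gene-recurrence permutation test for de novo calls
#'
#' Observed statistic: the number of genes hit by more than one de novo
#' protein-altering call. Null: each call lands on a gene drawn from a
#' universe of `gene_universe_size` genes, uniformly or with supplied
#' weights (e.g. coding length or mutability); the permutation p-value
#' uses the add-one convention, so its minimum attainable value is
#' `1 / (1 + n_permutations)` and it is never 0.
#'
#' @param genes Character vector, the gene of each observed call.
#' @param gene_universe_size Number of genes calls could have hit.
#' @param n_permutations Number of permutations (>= 1000).
#' @param seed Seed; fixed seed gives bit-reproducible p-values.
#' @param weights Optional per-gene sampling weights (length
#'   `gene_universe_size`).
#' @return List: `observed_recurrent` (genes with > 1 call), `p_value`,
#'   `n_permutations`.
#' @export
gene_recurrence_test <- function(genes, gene_universe_size,
                                 n_permutations = 10000L, seed = 1L,
                                 weights = NULL) {
  genes <- genes[!is.na(genes)]
  n_calls <- length(genes)
  if (n_permutations < 1000L) stop("n_permutations must be >= 1000")
  if (gene_universe_size < length(unique(genes)))
    stop("gene_universe_size (", gene_universe_size,
         ") smaller than the number of distinct observed genes (",
         length(unique(genes)), ")")
  if (!is.null(weights) && length(weights) != gene_universe_size)
    stop("weights must have length gene_universe_size")
  observed <- sum(table(genes) > 1L)
  if (n_calls == 0L) {
    return(list(observed_recurrent = 0L, p_value = 1,
                n_permutations = as.integer(n_permutations)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_permutations)) {
    hit <- sample.int(gene_universe_size, n_calls, replace = TRUE,
                      prob = weights)
    stat <- length(unique(hit[duplicated(hit)]))  # genes with > 1 call
    if (stat >= observed) exceed <- exceed + 1L
  }
  list(observed_recurrent = as.integer(observed),
       p_value = (1 + exceed) / (1 + n_permutations),
       n_permutations = as.integer(n_permutations))
}

#' Two-sided 1-df chi-squared proportion test
#'
#' Pearson chi-squared on a 2x2 table (group x category), by default
#' without continuity correction, as used to compare the proportions of
#' SNVs between losses and live births.
#'
#' @param counts 2x2 numeric matrix of non-negative counts; both row and
#'   column margins must be positive.
#' @param correct Apply the Yates continuity correction (default FALSE).
#' @return List of class `"proportion_test"`: `counts`, `chi2`, `df` (1),
#'   `p_value`.
#' @export
#' @examples
#' proportion_chi2(matrix(c(20, 5, 5, 20), 2))
proportion_chi2 <- function(counts, correct = FALSE) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2L, 2L))) stop("counts must be a 2x2 matrix")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("both margins of the 2x2 table must be positive")
  if (all(counts == 0)) stop("empty table")
  ht <- suppressWarnings(stats::chisq.test(counts, correct = correct))
  structure(list(counts = counts,
                 chi2 = unname(ht$statistic),
                 df = 1L,
                 p_value = unname(ht$p.value)),
            class = "proportion_test")
}

#' @export
print.proportion_test <- function(x, ...) {
  cat(sprintf("2x2 proportion test: chi2 = %.4g (df = 1), p = %.4g\n",
              x$chi2, x$p_value))
  invisible(x)
}

#' Enrichment statistics for a prioritized candidate table
#'
#' Convenience wrapper running the three statistical layers on pipeline
#' output: (1) de novo LoF burden in loss samples against
#' `config$expected_dn_rate`; (2) gene recurrence among de novo
#' protein-altering calls in losses; (3) per-mode 2x2 proportion tests
#' comparing, between losses and live births, the share of candidate
#' calls in each mode against all other modes.
#'
#' @param candidates Candidate table from [prioritize()].
#' @param pedigree Pedigree table.
#' @param config Pipeline configuration.
#' @param gene_universe_size Gene universe for the recurrence test.
#' @param n_permutations,seed Passed to [gene_recurrence_test()].
#' @return List: `burden` (`dn_burden`), `recurrence`, `proportions`
#'   (data.table: mode, loss/live-birth counts, chi2, p_value).
#' @export
stats_report <- function(candidates, pedigree, config = default_config(),
                         gene_universe_size = 20000L,
                         n_permutations = 10000L, seed = 1L) {
  cand <- as.data.table(candidates)
  ped <- as.data.table(pedigree)
  n_loss <- ped[outcome == "loss" & has_sample == TRUE, .N]
  dn_loss <- cand[mode == "de_novo" & quality_pass == TRUE & outcome == "loss"]
  burden <- de_novo_burden(
    observed_total = sum(lof_of(dn_loss$impact, config$lof_classes)),
    n_samples = n_loss, expected_rate = config$expected_dn_rate)
  recurrence <- gene_recurrence_test(
    dn_loss$gene, gene_universe_size = gene_universe_size,
    n_permutations = n_permutations, seed = seed)
  props <- rbindlist(lapply(unique(cand$mode), function(m) {
    tab <- rbind(
      loss = c(sum(cand$outcome == "loss" & cand$mode == m),
               sum(cand$outcome == "loss" & cand$mode != m)),
      live_birth = c(sum(cand$outcome == "live_birth" & cand$mode == m),
                     sum(cand$outcome == "live_birth" & cand$mode != m)))
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
      return(data.table(mode = m, loss_in_mode = tab[1, 1],
                        livebirth_in_mode = tab[2, 1],
                        chi2 = NA_real_, p_value = NA_real_))
    pt <- proportion_chi2(tab)
    data.table(mode = m, loss_in_mode = tab[1, 1],
               livebirth_in_mode = tab[2, 1],
               chi2 = pt$chi2, p_value = pt$p_value)
  }))
  list(burden = burden, recurrence = recurrence, proportions = props)
}
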