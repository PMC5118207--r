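#' Captured alleles per variant
#'
#' The capture-rate adjustment denominator: at each site, twice the number of
#' samples with a QC-passing genotype call (diploid samples). Samples whose
#' call is missing (capture failure) or below the GQ threshold do not count.
#'
#' @param cohort A `"cohort_genotypes"` object.
#' @param keys Variant keys to report; default all cohort variants.
#' @param samples Optional logical vector or sample-id character vector
#'   restricting the cohort (e.g. cases only); default all samples.
#' @param config A [run_config()].
#' @return Tibble with columns `key` and `captured_alleles`.
#' @export
captured_alleles <- function(cohort, keys = NULL, samples = NULL,
                             config = run_config()) {
  idx <- sample_index(cohort, samples)
  counts <- qc_counts_matrix(cohort, idx, config$gq_threshold)
  keys <- keys %||% cohort$variants$key
  rows <- match(keys, cohort$variants$key)
  if (anyNA(rows)) {
    abort(paste0("Unknown variant key: ", keys[is.na(rows)][1]))
  }
  tibble(key = keys,
         captured_alleles = unname(2L * counts$called_samples[rows]))
}

#' Carrier rate
#'
#' Fraction of samples carrying at least one qualifying alternate allele.
#'
#' @param carriers Integer vector of carrier counts.
#' @param n_samples Cohort sizes (recycled).
#' @return Numeric vector of rates.
#' @examples
#' carrier_rate(8, 187)   # 0.0428
#' carrier_rate(3, 1096)  # 0.0027
#' @export
carrier_rate <- function(carriers, n_samples) {
  stopifnot(all(n_samples > 0))
  carriers / n_samples
}

sample_index <- function(cohort, samples) {
  if (is.null(samples)) return(seq_len(nrow(cohort$samples)))
  if (is.character(samples)) {
    idx <- match(samples, cohort$samples$sample_id)
    if (anyNA(idx)) abort("Unknown sample id in `samples`.")
    return(idx)
  }
  stopifnot(is.logical(samples), length(samples) == nrow(cohort$samples))
  which(samples)
}

# core per-gene burden on precomputed QC counts
burden_one <- function(counts, rows, n_samples) {
  if (length(rows) == 0) {
    return(tibble(allele_count = 0L, mean_captured = NA_real_,
                  load = 0, carriers = 0L, n_samples = n_samples))
  }
  ac <- sum(counts$alt_alleles[rows])
  # a variant with zero passing calls still enters the average with N_v = 0:
  # dropping it would mask capture failure
  mean_cap <- mean(2 * counts$called_samples[rows])
  load <- if (mean_cap > 0) ac / mean_cap else NA_real_
  carr <- sum(colSums(counts$carrier[rows, , drop = FALSE]) > 0)
  tibble(allele_count = as.integer(ac), mean_captured = mean_cap,
         load = load, carriers = as.integer(carr),
         n_samples = n_samples)
}

#' Capture-adjusted mutational load of one gene in one cohort
#'
#' The per-gene mutational load is the sum of QC-passing alternate-allele
#' counts over the gene's qualifying variants, divided by the unweighted mean
#' of the per-variant captured-allele counts (2 x passing calls). Dividing by
#' the *average* captured alleles rather than a fixed 2n adjusts for
#' platform-specific capture differences between cohorts. Carriers are
#' counted at the sample level: a sample with a passing alternate call at any
#' qualifying variant of the gene counts once.
#'
#' @param cohort A `"cohort_genotypes"` object.
#' @param qualifying_keys Character vector of qualifying variant keys for the
#'   gene (may be empty: load 0, carriers 0, `mean_captured` `NA`).
#' @param samples Optional sample restriction (see [captured_alleles()]).
#' @param config A [run_config()].
#' @return One-row tibble: `allele_count`, `mean_captured`, `load`,
#'   `carriers`, `n_samples`, `carrier_rate`.
#' @examples
#' # 8 alt alleles, every variant called in all 187 diploid cases:
#' # load = 8 / 374 = 2.14%
#' @export
gene_burden <- function(cohort, qualifying_keys, samples = NULL,
                        config = run_config()) {
  idx <- sample_index(cohort, samples)
  counts <- qc_counts_matrix(cohort, idx, config$gq_threshold)
  rows <- match(qualifying_keys, cohort$variants$key)
  if (anyNA(rows)) {
    abort(paste0("Unknown variant key: ", qualifying_keys[is.na(rows)][1]))
  }
  b <- burden_one(counts, rows, length(idx))
  mutate(b, carrier_rate = carrier_rate(.data$carriers, .data$n_samples))
}

#' Per-gene burdens across cohorts
#'
#' Computes [gene_burden()] for every gene of a qualifying-variant map in
#' each sample group (by default case vs control status).
#'
#' @param cohort A `"cohort_genotypes"` object.
#' @param qualifying Long tibble `gene`/`key` from [select_qualifying()].
#' @param by Name of a `samples` column to group by (`"status"` or
#'   `"cohort"`), default `"status"`.
#' @param genes Genes to report; defaults to the full gene list recorded by
#'   [select_qualifying()] (genes with empty sets get load 0).
#' @param config A [run_config()].
#' @return Tibble, one row per gene x group: `gene`, `cohort`,
#'   `allele_count`, `mean_captured`, `load`, `carriers`, `n_samples`,
#'   `carrier_rate`.
#' @export
burden_by_gene <- function(cohort, qualifying, by = "status", genes = NULL,
                           config = run_config()) {
  genes <- genes %||% attr(qualifying, "genes") %||% unique(qualifying$gene)
  if (!by %in% names(cohort$samples)) {
    abort(paste0("No sample column called `", by, "`."))
  }
  groups <- cohort$samples[[by]]
  key_rows <- match(qualifying$key, cohort$variants$key)
  purrr::map_dfr(unique(groups), function(g) {
    idx <- which(groups == g)
    counts <- qc_counts_matrix(cohort, idx, config$gq_threshold)
    purrr::map_dfr(genes, function(gn) {
      rows <- key_rows[qualifying$gene == gn]
      bind_cols(tibble(gene = gn, cohort = g),
                burden_one(counts, rows, length(idx)))
    })
  }) |>
    mutate(carrier_rate = carrier_rate(.data$carriers, .data$n_samples))
}

#' Aggregate carrier burden over a gene set
#'
#' Counts, per sample group, the samples carrying at least one qualifying
#' alternate allele in *any* gene of the set — a sample carrying variants in
#' several genes counts once. Used for panel-wide enrichment summaries.
#'
#' @inheritParams burden_by_gene
#' @param genes Genes forming the set; default the full recorded gene list.
#' @return Tibble, one row per group: `cohort`, `n_genes`, `allele_count`,
#'   `carriers`, `n_samples`, `carrier_rate`.
#' @export
geneset_burden <- function(cohort, qualifying, by = "status", genes = NULL,
                           config = run_config()) {
  genes <- genes %||% attr(qualifying, "genes") %||% unique(qualifying$gene)
  keys <- qualifying$key[qualifying$gene %in% genes]
  rows <- match(keys, cohort$variants$key)
  groups <- cohort$samples[[by]]
  purrr::map_dfr(unique(groups), function(g) {
    idx <- which(groups == g)
    counts <- qc_counts_matrix(cohort, idx, config$gq_threshold)
    carr <- if (length(rows) == 0) 0L else
      sum(colSums(counts$carrier[rows, , drop = FALSE]) > 0)
    tibble(
      cohort = g, n_genes = length(genes),
      allele_count = as.integer(sum(counts$alt_alleles[rows])),
      carriers = as.integer(carr), n_samples = length(idx),
      carrier_rate = carrier_rate(carr, length(idx))
    )
  })
}
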