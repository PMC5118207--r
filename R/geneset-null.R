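#' Draw random control gene sets
#'
#' Samples `n_sets` mutually disjoint gene sets of `set_size` without
#' replacement from a universe, excluding the target panel so no true signal
#' can leak into the empirical null. Fully reproducible from `seed` (the
#' global RNG state is left untouched).
#'
#' @param universe Character vector of candidate gene symbols.
#' @param exclude Genes to remove from the universe first (typically the
#'   GWAS target panel).
#' @param set_size Genes per set (>= 1).
#' @param n_sets Number of disjoint sets.
#' @param seed Integer seed, recorded in the output.
#' @return Tibble with columns `set_id` (`"set1"`, ...) and `gene`;
#'   attribute `"seed"`.
#' @export
draw_control_sets <- function(universe, exclude = character(), set_size,
                              n_sets = 5, seed = 1L) {
  if (set_size < 1) abort("`set_size` must be >= 1.")
  if (n_sets < 1) abort("`n_sets` must be >= 1.")
  avail <- setdiff(unique(universe), exclude)
  need <- set_size * n_sets
  if (length(avail) < need) {
    abort(sprintf(
      "Universe too small: need %d genes for %d disjoint set(s) of %d, have %d.",
      need, n_sets, set_size, length(avail)
    ))
  }
  picked <- withr::with_seed(seed, sample(avail, need, replace = FALSE))
  out <- tibble(
    set_id = rep(paste0("set", seq_len(n_sets)), each = set_size),
    gene = picked
  )
  attr(out, "seed") <- as.integer(seed)
  out
}

#' Evaluate random control gene sets under the association pipeline
#'
#' Re-runs the per-gene case/control association for each drawn control set
#' and applies the Bonferroni correction within each set, with the
#' denominator fixed at the set size. A healthy pipeline on null data should
#' almost never declare a gene significant in these sets.
#'
#' @param draws Tibble from [draw_control_sets()].
#' @param cohort A `"cohort_genotypes"` object.
#' @param qualifying Long `gene`/`key` tibble from [select_qualifying()]
#'   computed over the drawn genes (its gene list must cover `draws$gene`).
#' @param config A [run_config()].
#' @return Per-gene tibble: `set_id`, `gene`, `p_raw`, `p_bonferroni`,
#'   `significant`; summarise per set with
#'   `dplyr::count(result, set_id, wt = significant)`.
#' @export
evaluate_control_sets <- function(draws, cohort, qualifying,
                                  config = run_config()) {
  all_genes <- unique(draws$gene)
  # one association pass over the union of genes; per-set correction after
  base_cfg <- config
  base_cfg$n_genes_tested <- NULL
  res <- associate_genes(cohort, qualifying, genes = all_genes,
                         config = base_cfg)
  draws |>
    left_join(as_tibble(res)[, c("gene", "p_raw")], by = "gene") |>
    group_by(.data$set_id) |>
    mutate(
      p_bonferroni = if_else(
        is.na(.data$p_raw), NA_real_,
        bonferroni_correct(dplyr::coalesce(.data$p_raw, 1), n())
      ),
      significant = !is.na(.data$p_bonferroni) &
        .data$p_bonferroni < config$alpha
    ) |>
    ungroup()
}
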