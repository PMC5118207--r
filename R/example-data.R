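#' Worked-example dataset: rare CARD10 variants in a glaucoma cohort
#'
#' Builds, in code, a compact case/control dataset for the README worked
#' example: six rare candidate variants in the gene *CARD10* across 187
#' primary open-angle glaucoma cases and 1096 controls (103 screened local
#' plus 993 external), every genotype called with high quality. Five
#' missense variants carry SIFT / PolyPhen-2 HVAR scores such that each is
#' predicted damaging by at least one score, and one frameshift carries no
#' scores; eight case samples and three control samples are heterozygous
#' carriers. An external summary control of 33370 samples (AN = 66740) with
#' allele counts matching the variants' reference-population frequencies is
#' included.
#'
#' @return A list: `cohort` (a `"cohort_genotypes"`), `annotations`,
#'   `summary_control`, `gene_list` (`"CARD10"`), and `config` (a
#'   [run_config()] with the Bonferroni denominator fixed at the 86-gene
#'   panel size this example is imagined as part of).
#' @examples
#' ex <- example_card10_study()
#' qual <- select_qualifying(ex$cohort, ex$annotations, ex$gene_list,
#'                           ex$config)
#' gene_burden(ex$cohort, qual$key,
#'             samples = ex$cohort$samples$status == "case",
#'             config = ex$config)
#' @export
example_card10_study <- function() {
  n_case <- 187L
  n_ctrl <- 1096L
  annotations <- tibble(
    chrom = "22",
    pos = c(37494000L, 37494350L, 37494391L, 37494577L, 37495852L, 37496448L),
    ref = c("C", "G", "C", "G", "G", "TG"),
    alt = c("T", "A", "T", "A", "A", "T"),
    gene = "CARD10",
    consequence = c("missense", "missense", "missense", "missense",
                    "missense", "frameshift"),
    sift = c(0.10, 0.02, 0.04, 0.01, 0.02, NA),
    polyphen_hvar = c(0.987, 0.944, 0.025, 0.764, 0.01, NA),
    maf_1kg = NA_real_, maf_esp = NA_real_,
    maf_exac = c(0, 3.6e-3, 2e-4, 1.5e-5, 4.0e-4, 0),
    maf_dbsnp = NA_real_
  ) |>
    mutate(key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)) |>
    select("key", dplyr::everything())

  samples <- tibble(
    sample_id = c(sprintf("CASE%04d", seq_len(n_case)),
                  sprintf("CTRL%04d", seq_len(n_ctrl))),
    status = rep(c("case", "control"), c(n_case, n_ctrl)),
    subtype = "unknown",
    cohort = rep(c("local", "local", "AOGC"), c(n_case, 103L, 993L)),
    age_dx = NA_real_, max_iop = NA_real_
  )
  gt <- matrix(0L, 6L, n_case + n_ctrl)
  # heterozygous singleton carriers: case allele counts (1, 3, 1, 1, 2, 0)
  # across distinct samples, control counts (0, 2, 0, 0, 0, 1)
  case_carriers <- list(1L, 2:4, 5L, 6L, 7:8, integer())
  ctrl_carriers <- list(integer(), 1:2, integer(), integer(), integer(), 3L)
  for (v in 1:6) {
    gt[v, case_carriers[[v]]] <- 1L
    gt[v, n_case + ctrl_carriers[[v]]] <- 1L
  }
  gq <- matrix(99, 6L, n_case + n_ctrl)
  cohort <- cohort_genotypes(annotations[, c("chrom", "pos", "ref", "alt",
                                             "key")],
                             samples, gt, gq)
  an <- 66740L
  summary_control <- annotations |>
    select("key", "chrom", "pos", "ref", "alt") |>
    mutate(ac = as.integer(round(c(0, 3.6e-3, 2e-4, 1.5e-5, 4.0e-4, 0) * an)),
           an = an)
  list(
    cohort = cohort,
    annotations = annotations,
    summary_control = summary_control,
    gene_list = "CARD10",
    config = run_config(n_genes_tested = 86)
  )
}
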