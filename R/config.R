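#' Analysis run configuration
#'
#' Bundles the tunable thresholds of the burden pipeline. Defaults follow the
#' conventional rare-variant collapsing design: genotype calls require a
#' Genotype Quality (GQ) of at least 20, variants with a known minor allele
#' frequency above 1% in any population database are excluded, and
#' family-wise significance is declared at `alpha` after Bonferroni
#' correction over the genes actually tested.
#'
#' @param maf_threshold Population MAF above which a variant is considered
#'   common and excluded. Strictly between 0 and 1; default `0.01`.
#' @param gq_threshold Minimum genotype quality for a call to contribute to
#'   allele and capture counts (inclusive). Default `20`.
#' @param alpha Family-wise significance level applied to
#'   Bonferroni-corrected p-values. Default `0.05`.
#' @param n_genes_tested Optional fixed Bonferroni denominator. When `NULL`
#'   (default) the denominator is the number of genes with a testable
#'   contingency table.
#' @param seed Integer seed recorded with the configuration and used by
#'   operations that draw random numbers.
#' @param paths Optional named list of input/output file paths, carried along
#'   for provenance (used by [read_run_config()] round-trips).
#'
#' @return A list with class `"run_config"`.
#' @examples
#' run_config()
#' run_config(maf_threshold = 0.005, alpha = 0.01)
#' @export
run_config <- function(maf_threshold = 0.01,
                       gq_threshold = 20,
                       alpha = 0.05,
                       n_genes_tested = NULL,
                       seed = 1L,
                       paths = list()) {
  stopifnot(is.numeric(maf_threshold), length(maf_threshold) == 1)
  if (!(maf_threshold > 0 && maf_threshold < 1)) {
    abort("`maf_threshold` must lie strictly between 0 and 1.")
  }
  if (!(alpha > 0 && alpha < 1)) {
    abort("`alpha` must lie strictly between 0 and 1.")
  }
  if (gq_threshold < 0) abort("`gq_threshold` must be non-negative.")
  if (!is.null(n_genes_tested)) {
    n_genes_tested <- as.integer(n_genes_tested)
    if (n_genes_tested < 1) abort("`n_genes_tested` must be >= 1.")
  }
  structure(
    list(
      maf_threshold = maf_threshold,
      gq_threshold = gq_threshold,
      alpha = alpha,
      n_genes_tested = n_genes_tested,
      seed = as.integer(seed),
      paths = paths
    ),
    class = "run_config"
  )
}

#' Read a YAML run configuration
#'
#' Reads a YAML file whose top-level keys mirror the arguments of
#' [run_config()]; unknown keys are rejected so typos do not silently fall
#' back to defaults.
#'
#' @param path Path to a YAML file.
#' @return A `"run_config"` object.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0) {
    abort(paste0("Unknown configuration keys: ", paste(extra, collapse = ", ")))
  }
  do.call(run_config, raw)
}

#' @export
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  cat(sprintf("  MAF threshold:  %g\n", x$maf_threshold))
  cat(sprintf("  GQ threshold:   %g\n", x$gq_threshold))
  cat(sprintf("  alpha:          %g\n", x$alpha))
  cat(sprintf(
    "  Bonferroni n:   %s\n",
    if (is.null(x$n_genes_tested)) "genes tested" else x$n_genes_tested
  ))
  cat(sprintf("  seed:           %d\n", x$seed))
  invisible(x)
}
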