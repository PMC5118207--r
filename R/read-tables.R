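consequence_levels <- c(
  "synonymous", "missense", "stopgain", "stoploss", "frameshift",
  "nonframeshift_indel", "splicing", "other"
)

# ANNOVAR-style function strings -> the consequence vocabulary used here
normalise_consequence <- function(x) {
  lut <- c(
    "synonymous" = "synonymous", "synonymous_snv" = "synonymous",
    "missense" = "missense", "nonsynonymous" = "missense",
    "nonsynonymous_snv" = "missense",
    "stopgain" = "stopgain", "stopgain_snv" = "stopgain",
    "stoploss" = "stoploss", "stoploss_snv" = "stoploss",
    "frameshift" = "frameshift",
    "frameshift_insertion" = "frameshift",
    "frameshift_deletion" = "frameshift",
    "frameshift_substitution" = "frameshift",
    "nonframeshift_indel" = "nonframeshift_indel",
    "nonframeshift_insertion" = "nonframeshift_indel",
    "nonframeshift_deletion" = "nonframeshift_indel",
    "nonframeshift_substitution" = "nonframeshift_indel",
    "splicing" = "splicing", "splice" = "splicing"
  )
  out <- unname(lut[tolower(x)])
  out[is.na(out)] <- "other"
  out
}

#' Read a per-variant annotation table
#'
#' Reads the ANNOVAR-style TSV the pipeline consumes: one row per biallelic
#' variant with gene symbol, functional consequence, SIFT and PolyPhen-2 HVAR
#' scores and per-database population allele frequencies. `"."` (or empty)
#' denotes a missing value. Consequence strings not in the known vocabulary
#' map to `"other"` (treated as non-coding downstream).
#'
#' @param path TSV with columns `CHROM POS REF ALT GENE FUNC SIFT PPH2_HVAR
#'   MAF_1KG MAF_ESP MAF_EXAC MAF_DBSNP` (case-insensitive).
#' @return A tibble keyed by `key = chrom:pos:ref:alt` with columns `gene`,
#'   `consequence`, `sift`, `polyphen_hvar` and `maf_1kg`, `maf_esp`,
#'   `maf_exac`, `maf_dbsnp`.
#' @export
read_annotations <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE,
                         na = c("", "NA", "."),
                         col_types = readr::cols(.default = readr::col_character()))
  names(raw) <- tolower(names(raw))
  need <- c("chrom", "pos", "ref", "alt", "gene", "func", "sift", "pph2_hvar",
            "maf_1kg", "maf_esp", "maf_exac", "maf_dbsnp")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0) {
    abort(paste0("Annotation table lacks column(s): ",
                 paste(toupper(miss), collapse = ", ")))
  }
  ann <- raw |>
    mutate(
      pos = as.integer(.data$pos),
      key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt),
      consequence = normalise_consequence(.data$func),
      sift = as.numeric(.data$sift),
      polyphen_hvar = as.numeric(.data$pph2_hvar),
      across(dplyr::starts_with("maf_"), as.numeric)
    ) |>
    select("key", "chrom", "pos", "ref", "alt", "gene", "consequence",
           "sift", "polyphen_hvar",
           "maf_1kg", "maf_esp", "maf_exac", "maf_dbsnp")
  if (nrow(ann) == 0) return(ann)
  if (anyDuplicated(ann$key)) {
    abort(paste0("Duplicate variant key in annotation table: ",
                 ann$key[duplicated(ann$key)][1]))
  }
  if (any(ann$pos < 1, na.rm = TRUE)) abort("Annotation POS must be >= 1.")
  score_bad <- function(x) any(!is.na(x) & (x < 0 | x > 1))
  if (score_bad(ann$sift)) abort("SIFT scores must lie in [0, 1].")
  if (score_bad(ann$polyphen_hvar)) {
    abort("PolyPhen-2 HVAR scores must lie in [0, 1].")
  }
  maf_cols <- c("maf_1kg", "maf_esp", "maf_exac", "maf_dbsnp")
  for (cc in maf_cols) {
    if (score_bad(ann[[cc]])) {
      abort(paste0("Allele frequencies in ", toupper(cc), " must lie in [0, 1]."))
    }
  }
  ann
}

#' Read an ordered gene list
#'
#' One gene symbol per line; `#` starts a comment; blank lines are ignored.
#' Order is preserved; duplicates are removed with a warning; an effectively
#' empty file is an error.
#'
#' @param path Path to the gene list.
#' @return Character vector of unique gene symbols in file order.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  genes <- trimws(lines)
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0) abort("Gene list is empty.")
  if (anyDuplicated(genes)) {
    dups <- unique(genes[duplicated(genes)])
    warn(paste0("Duplicate gene symbol(s) removed from list: ",
                paste(head(dups, 5), collapse = ", ")))
    genes <- genes[!duplicated(genes)]
  }
  genes
}

#' Read an external summary-statistic control table
#'
#' A summary control is a reference cohort available only as per-variant
#' allele counts (AC) over total called alleles (AN), such as a public exome
#' aggregation subpopulation. Used by [associate_vs_summary()].
#'
#' @param path TSV with columns `CHROM POS REF ALT AC AN` (case-insensitive).
#' @return A tibble with columns `key`, `chrom`, `pos`, `ref`, `alt`, `ac`,
#'   `an`.
#' @export
read_summary_control <- function(path) {
  raw <- readr::read_tsv(path, show_col_types = FALSE, na = c("", "NA", "."))
  names(raw) <- tolower(names(raw))
  miss <- setdiff(c("chrom", "pos", "ref", "alt", "ac", "an"), names(raw))
  if (length(miss) > 0) {
    abort(paste0("Summary-control table lacks column(s): ",
                 paste(toupper(miss), collapse = ", ")))
  }
  out <- raw |>
    mutate(
      pos = as.integer(.data$pos),
      ac = as.integer(.data$ac),
      an = as.integer(.data$an),
      key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)
    ) |>
    select("key", "chrom", "pos", "ref", "alt", "ac", "an")
  if (any(out$ac < 0) || any(out$an <= 0)) {
    abort("Summary control requires AC >= 0 and AN > 0.")
  }
  bad <- out$ac > out$an
  if (any(bad)) {
    abort(paste0("AC exceeds AN at ", out$key[bad][1], "."))
  }
  if (anyDuplicated(out$key)) {
    abort("Duplicate variant key in summary-control table.")
  }
  out
}

#' Write per-gene association results to TSV
#'
#' Serialises an association result table with floats at 6 significant
#' digits and a deterministic row order: ascending raw p, ties broken
#' alphabetically by gene.
#'
#' @param results A tibble as returned by [associate_genes()].
#' @param path Output TSV path.
#' @return Invisibly, the tibble as written (ordered, formatted).
#' @export
write_gene_results <- function(results, path) {
  cols <- c("gene", "case_load", "control_load", "case_carriers",
            "control_carriers", "odds_ratio", "ci_low", "ci_high",
            "p_raw", "p_bonferroni", "significant")
  miss <- setdiff(cols, names(results))
  if (length(miss) > 0) {
    abort(paste0("Result table lacks column(s): ", paste(miss, collapse = ", ")))
  }
  out <- results |>
    select(dplyr::all_of(cols)) |>
    arrange(.data$p_raw, .data$gene) |>
    mutate(across(dplyr::where(is.numeric), ~ signif(.x, 6)))
  readr::write_tsv(out, path)
  invisible(out)
}
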