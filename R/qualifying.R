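coding_consequences <- c(
  "synonymous", "missense", "stopgain", "stoploss", "frameshift",
  "nonframeshift_indel", "splicing"
)

# SIFT below 0.05 (strict) or PolyPhen-2 HVAR above 0.909 (strict) is
# predicted damaging; damaging by at least one score retains a missense
sift_damaging_cutoff <- 0.05
polyphen_damaging_cutoff <- 0.909

#' Is a variant protein-coding or splice-site?
#'
#' The analysis is restricted to protein-coding exonic and splice-site
#' variants; everything else (intronic, UTR, intergenic, mapped to
#' `"other"`) is excluded before any further filtering.
#'
#' @param consequence Character vector of consequence classes.
#' @return Logical vector.
#' @export
is_coding_or_splicing <- function(consequence) {
  consequence %in% coding_consequences
}

#' Rare-in-all-databases frequency filter
#'
#' A variant fails if any *populated* population database reports an allele
#' frequency strictly above `maf_threshold`. Variants unknown to every
#' database pass: only a *known* MAF above the threshold is evidence the
#' variant is common.
#'
#' @param annotations Annotation tibble (see [read_annotations()]).
#' @param maf_threshold Frequency threshold in (0, 1); default 0.01.
#' @return Logical vector, one element per annotation row.
#' @export
passes_frequency_filter <- function(annotations, maf_threshold = 0.01) {
  stopifnot(maf_threshold > 0, maf_threshold < 1)
  maf <- as.matrix(annotations[, c("maf_1kg", "maf_esp", "maf_exac",
                                   "maf_dbsnp")])
  !apply(maf > maf_threshold, 1, any, na.rm = TRUE)
}

#' Pathogenicity call for each variant
#'
#' Retains stop-gain/stop-loss and frameshift variants as loss-of-function,
#' splice-site variants, and missense variants predicted damaging by SIFT
#' (score < 0.05) *or* PolyPhen-2 HVAR (score > 0.909) — damaging by one
#' score suffices. Synonymous variants, in-frame indels, and missense
#' variants tolerated by both scores (or with both scores missing) never
#' qualify.
#'
#' @param annotations Annotation tibble.
#' @return Tibble with columns `key`, `qualifies` (logical) and `reason`, one
#'   of `lof`, `splicing`, `deleterious_missense`, `excluded_synonymous`,
#'   `excluded_nonframeshift`, `excluded_tolerated_missense`,
#'   `excluded_noncoding`.
#' @export
is_predicted_pathogenic <- function(annotations) {
  cons <- annotations$consequence
  sift <- annotations$sift
  pph <- annotations$polyphen_hvar
  sift_dmg <- !is.na(sift) & sift < sift_damaging_cutoff
  pph_dmg <- !is.na(pph) & pph > polyphen_damaging_cutoff
  reason <- dplyr::case_when(
    cons %in% c("stopgain", "stoploss", "frameshift") ~ "lof",
    cons == "splicing" ~ "splicing",
    cons == "missense" & (sift_dmg | pph_dmg) ~ "deleterious_missense",
    cons == "missense" ~ "excluded_tolerated_missense",
    cons == "synonymous" ~ "excluded_synonymous",
    cons == "nonframeshift_indel" ~ "excluded_nonframeshift",
    .default = "excluded_noncoding"
  )
  tibble(
    key = annotations$key,
    qualifies = reason %in% c("lof", "splicing", "deleterious_missense"),
    reason = reason
  )
}

#' Classify every variant through the full qualifying cascade
#'
#' Applies, in order: coding/splicing restriction, rarity in all population
#' databases, and predicted pathogenicity. Each variant receives exactly one
#' status: a qualifying reason (`lof`, `splicing`, `deleterious_missense`) or
#' the first exclusion reason that applies (`excluded_noncoding`,
#' `excluded_common`, then the pathogenicity exclusions).
#'
#' @param annotations Annotation tibble.
#' @param config A [run_config()] (supplies `maf_threshold`).
#' @return Audit tibble: `key`, `gene`, `qualifies`, `reason`.
#' @export
classify_variants <- function(annotations, config = run_config()) {
  coding <- is_coding_or_splicing(annotations$consequence)
  rare <- passes_frequency_filter(annotations, config$maf_threshold)
  path <- is_predicted_pathogenic(annotations)
  reason <- dplyr::case_when(
    !coding ~ "excluded_noncoding",
    !rare ~ "excluded_common",
    .default = path$reason
  )
  tibble(
    key = annotations$key,
    gene = annotations$gene,
    qualifies = coding & rare & path$qualifies,
    reason = reason
  )
}

#' Write the qualifying-filter audit table
#'
#' @param classified Output of [classify_variants()].
#' @param path Output TSV path.
#' @return Invisibly, `classified`.
#' @export
write_qualifying_audit <- function(classified, path) {
  readr::write_tsv(classified, path)
  invisible(classified)
}

#' QC-filtered allele count at one site
#'
#' A genotype contributes only when it is called and its genotype quality
#' meets the threshold (inclusive: GQ equal to the threshold passes). Returns
#' the summed alternate-allele dosage and the number of contributing samples.
#'
#' @param gt Integer dosages at one site (NA = uncalled).
#' @param gq Genotype qualities, same length (NA fails QC).
#' @param gq_threshold Minimum genotype quality; default 20.
#' @return A list with `alt_alleles` and `called_samples`.
#' @export
allele_count_with_qc <- function(gt, gq, gq_threshold = 20) {
  stopifnot(length(gt) == length(gq))
  ok <- !is.na(gt) & !is.na(gq) & gq >= gq_threshold
  list(alt_alleles = sum(gt[ok]), called_samples = sum(ok))
}

# matrix version used throughout: per-variant alt-allele and called-sample
# counts over a sample subset, with per-genotype GQ filtering
qc_counts_matrix <- function(cohort, sample_idx, gq_threshold) {
  gt <- cohort$gt[, sample_idx, drop = FALSE]
  gq <- cohort$gq[, sample_idx, drop = FALSE]
  ok <- !is.na(gt) & !is.na(gq) & gq >= gq_threshold
  gt0 <- gt
  gt0[!ok] <- 0L
  list(
    alt_alleles = rowSums(gt0),
    called_samples = rowSums(ok),
    carrier = ok & gt > 0L
  )
}

#' Select qualifying variants per gene
#'
#' A variant is *qualifying* when it is coding or splice-site, rare in all
#' population databases where known, and predicted pathogenic — and it is
#' observed (at least one QC-passing alternate allele in any sample of the
#' joint cohort). The result is restricted to the supplied gene list; a
#' listed gene with no annotated variant is retained with an empty set and a
#' warning. VCF variants without an annotation row are excluded with a
#' logged warning (only annotated coding variants are analysed).
#'
#' @param cohort A `"cohort_genotypes"` object (cases and controls together).
#' @param annotations Annotation tibble.
#' @param gene_list Character vector of gene symbols to analyse.
#' @param config A [run_config()].
#' @return Tibble mapping `gene` to qualifying variant `key`s (long format),
#'   with `reason` for audit. Genes with an empty set are absent from the
#'   rows but recorded in the `"genes"` attribute, which preserves the full
#'   gene list order.
#' @export
select_qualifying <- function(cohort, annotations, gene_list,
                              config = run_config()) {
  unannotated <- setdiff(cohort$variants$key, annotations$key)
  if (length(unannotated) > 0) {
    gb_log("WARN", length(unannotated),
           " VCF variant(s) without annotation were excluded.")
  }
  no_ann_gene <- setdiff(gene_list, annotations$gene)
  if (length(no_ann_gene) > 0) {
    warn(paste0(
      "Gene(s) in the list with no annotated variant (kept, empty set): ",
      paste(head(no_ann_gene, 5), collapse = ", ")
    ))
  }
  cls <- classify_variants(annotations, config)
  counts <- qc_counts_matrix(cohort, seq_len(nrow(cohort$samples)),
                             config$gq_threshold)
  observed <- tibble(key = cohort$variants$key,
                     alt_alleles = counts$alt_alleles)
  out <- cls |>
    filter(.data$qualifies, .data$gene %in% gene_list) |>
    inner_join(observed, by = "key") |>
    filter(.data$alt_alleles > 0) |>
    select("gene", "key", "reason") |>
    arrange(match(.data$gene, gene_list), .data$key)
  attr(out, "genes") <- gene_list
  out
}
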