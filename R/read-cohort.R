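#' Cohort genotype container
#'
#' Holds a joint-called case/control cohort: a variant table, a sample
#' phenotype table, and variant-by-sample matrices of alternate-allele dosage
#' and genotype quality. Construct one from files with [read_cohort()] or
#' simulate one with [simulate_cohort()].
#'
#' @param variants Tibble with columns `chrom`, `pos`, `ref`, `alt` (and a
#'   derived `key`), one row per biallelic variant.
#' @param samples Tibble with columns `sample_id`, `status` (`"case"` or
#'   `"control"`), `subtype` (`"HTG"`, `"NTG"` or `"unknown"`), `cohort`
#'   (free label, e.g. `"local"` or `"AOGC"`), `age_dx` (years, may be `NA`)
#'   and `max_iop` (mmHg, may be `NA`).
#' @param gt Integer matrix, variants x samples, of alternate-allele dosages
#'   in `{0, 1, 2}`; `NA` means uncalled.
#' @param gq Numeric matrix, variants x samples, of genotype qualities;
#'   `NA` where the genotype is uncalled or no quality was emitted.
#'
#' @return An object of class `"cohort_genotypes"`.
#' @export
cohort_genotypes <- function(variants, samples, gt, gq) {
  variants <- as_tibble(variants)
  samples <- as_tibble(samples)
  if (!"key" %in% names(variants)) {
    variants$key <- variant_key(variants$chrom, variants$pos,
                                variants$ref, variants$alt)
  }
  if (anyDuplicated(variants$key)) {
    abort("Duplicate variant keys (chrom:pos:ref:alt) in the cohort.")
  }
  stopifnot(
    nrow(gt) == nrow(variants), ncol(gt) == nrow(samples),
    all(dim(gq) == dim(gt))
  )
  if (any(gt < 0 | gt > 2, na.rm = TRUE)) {
    abort("Genotype dosages must be 0, 1 or 2.")
  }
  if (any(gq < 0, na.rm = TRUE)) abort("Genotype qualities must be >= 0.")
  bad_status <- setdiff(unique(samples$status), c("case", "control"))
  if (length(bad_status) > 0) {
    abort(paste0("Unknown sample status: ", paste(bad_status, collapse = ", ")))
  }
  dimnames(gt) <- list(variants$key, samples$sample_id)
  dimnames(gq) <- list(variants$key, samples$sample_id)
  structure(
    list(variants = variants, samples = samples, gt = gt, gq = gq),
    class = "cohort_genotypes"
  )
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  ns <- table(factor(x$samples$status, levels = c("case", "control")))
  cat(sprintf(
    "<cohort_genotypes> %d variants x %d samples (%d cases, %d controls)\n",
    nrow(x$variants), nrow(x$samples), ns[["case"]], ns[["control"]]
  ))
  cat(sprintf("  missing genotype rate: %.3f\n", mean(is.na(x$gt))))
  invisible(x)
}

#' Subset a cohort to selected samples
#'
#' @param cohort A `"cohort_genotypes"` object.
#' @param keep Logical vector over samples, or character vector of sample ids.
#' @return A `"cohort_genotypes"` with the selected samples only.
#' @export
subset_samples <- function(cohort, keep) {
  if (is.character(keep)) keep <- cohort$samples$sample_id %in% keep
  stopifnot(is.logical(keep), length(keep) == nrow(cohort$samples))
  cohort_genotypes(
    cohort$variants, cohort$samples[keep, , drop = FALSE],
    cohort$gt[, keep, drop = FALSE], cohort$gq[, keep, drop = FALSE]
  )
}

parse_gt_dosage <- function(gt_strings) {
  # "0/1", "0|1", "./.", "." -> alt dosage or NA; any allele beyond 0/1 means
  # an unsplit multiallelic slipped through and is an error upstream.
  # GT strings take only a handful of distinct values, so parse unique ones.
  ux <- unique(gt_strings)
  parse_one <- function(s) {
    if (is.na(s)) return(NA_integer_)
    a <- strsplit(s, "[/|]")[[1]]
    if (any(a == ".")) return(NA_integer_)
    ai <- suppressWarnings(as.integer(a))
    if (anyNA(ai) || any(ai > 1)) return(-1L)
    sum(ai)
  }
  dosage_u <- vapply(ux, parse_one, integer(1), USE.NAMES = FALSE)
  if (any(dosage_u == -1L, na.rm = TRUE)) {
    abort("Genotype with allele index > 1 found; split multiallelic records upstream.")
  }
  dosage_u[match(gt_strings, ux)]
}

#' Read a joint-called multi-sample VCF with phenotypes
#'
#' Loads a VCF v4.2 whose FORMAT includes `GT` and `GQ`, together with a
#' tab-separated phenotype table covering every VCF sample. Records must be
#' biallelic: multiallelic sites are rejected with an error (split them
#' upstream, e.g. with `bcftools norm -m-`), because allele counting is only
#' unambiguous on biallelic records. Genotypes are encoded as alternate-allele
#' dosage; missing calls (`./.`) are encoded `NA`.
#'
#' The phenotype file needs columns `sample_id` and `status`
#' (`case`/`control`); optional columns `subtype` (`HTG`/`NTG`/`unknown`),
#' `cohort`, `age_dx`, `max_iop`. When `subtype` is absent or `unknown` and
#' `max_iop` is recorded, the subtype is derived: maximum IOP above 21 mmHg
#' is high-tension glaucoma (HTG), otherwise NTG. An explicit subtype always
#' wins over the derived one.
#'
#' @param vcf_path Path to the VCF (plain text or bgzipped).
#' @param phenotype_path Path to the phenotype TSV.
#' @return A `"cohort_genotypes"` object with samples in VCF column order.
#' @export
read_cohort <- function(vcf_path, phenotype_path) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record VCF
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0) abort("VCF contains no variant records.")
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    abort(paste0(
      "Multiallelic record(s) at ",
      paste(head(paste0(fix$CHROM[multi], ":", fix$POS[multi]), 5), collapse = ", "),
      "; split to biallelic records upstream (e.g. `bcftools norm -m-`)."
    ))
  }
  variants <- tibble(
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT
  )
  if (any(variants$pos < 1)) abort("VCF positions must be >= 1.")

  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  gq_raw <- vcfR::extract.gt(vcf, element = "GQ")
  if (is.null(gt_raw)) abort("VCF FORMAT lacks a GT field.")
  gq_chr <- as.character(gq_raw)
  gq_num <- suppressWarnings(as.numeric(gq_chr))
  malformed <- !is.na(gq_chr) & gq_chr != "." & is.na(gq_num)
  if (any(malformed)) {
    abort(paste0("Malformed GQ value(s), e.g. \"", gq_chr[malformed][1], "\"."))
  }
  gq <- matrix(gq_num, nrow = nrow(gt_raw), ncol = ncol(gt_raw))
  gt <- matrix(parse_gt_dosage(as.character(gt_raw)),
               nrow = nrow(gt_raw), ncol = ncol(gt_raw))

  pheno <- read_phenotypes(phenotype_path)
  vcf_samples <- colnames(gt_raw)
  missing_pheno <- setdiff(vcf_samples, pheno$sample_id)
  if (length(missing_pheno) > 0) {
    abort(paste0(
      "VCF sample(s) absent from the phenotype file: ",
      paste(head(missing_pheno, 5), collapse = ", ")
    ))
  }
  extra <- setdiff(pheno$sample_id, vcf_samples)
  if (length(extra) > 0) {
    gb_log("WARN", length(extra),
           " phenotype row(s) without a VCF sample were dropped.")
  }
  samples <- pheno[match(vcf_samples, pheno$sample_id), , drop = FALSE]
  cohort_genotypes(variants, samples, gt, gq)
}

read_phenotypes <- function(path) {
  pheno <- readr::read_tsv(path, show_col_types = FALSE,
                           na = c("", "NA", "."))
  need <- c("sample_id", "status")
  miss <- setdiff(need, names(pheno))
  if (length(miss) > 0) {
    abort(paste0("Phenotype file lacks column(s): ", paste(miss, collapse = ", ")))
  }
  if (anyDuplicated(pheno$sample_id)) {
    abort("Duplicate sample_id in the phenotype file.")
  }
  if (!"subtype" %in% names(pheno)) pheno$subtype <- NA_character_
  if (!"cohort" %in% names(pheno)) pheno$cohort <- "local"
  if (!"age_dx" %in% names(pheno)) pheno$age_dx <- NA_real_
  if (!"max_iop" %in% names(pheno)) pheno$max_iop <- NA_real_
  pheno |>
    mutate(
      subtype = if_else(is.na(.data$subtype), "unknown", .data$subtype),
      # derive HTG/NTG from maximum recorded IOP (> 21 mmHg => HTG) only
      # where no explicit subtype was given: explicit wins on conflict
      subtype = if_else(
        .data$subtype == "unknown" & !is.na(.data$max_iop),
        if_else(.data$max_iop > 21, "HTG", "NTG"),
        .data$subtype
      ),
      age_dx = as.numeric(.data$age_dx),
      max_iop = as.numeric(.data$max_iop)
    ) |>
    select("sample_id", "status", "subtype", "cohort", "age_dx", "max_iop")
}

#' Write a cohort back to VCF + phenotype TSV
#'
#' Emits a minimal VCF v4.2 with FORMAT `GT:GQ` (dosage 1 written as `0/1`,
#' dosage 2 as `1/1`, `NA` as `./.`) and the matching phenotype table. Used
#' by the synthetic-cohort generator and for round-trip testing.
#'
#' @param cohort A `"cohort_genotypes"` object.
#' @param vcf_path,phenotype_path Output paths.
#' @return Invisibly, `cohort`.
#' @export
write_cohort <- function(cohort, vcf_path, phenotype_path = NULL) {
  v <- cohort$variants
  gt_str <- matrix(c("0/0", "0/1", "1/1")[cohort$gt + 1L],
                   nrow = nrow(v))
  gt_str[is.na(cohort$gt)] <- "./."
  gq_str <- ifelse(is.na(cohort$gq), ".",
                   format(cohort$gq, trim = TRUE, scientific = FALSE))
  body <- matrix(paste(gt_str, gq_str, sep = ":"), nrow = nrow(v))
  body[is.na(cohort$gt)] <- "./.:."
  header <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype Quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples$sample_id), collapse = "\t")
  )
  lines <- paste(
    v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".", "GT:GQ",
    apply(body, 1, paste, collapse = "\t"),
    sep = "\t"
  )
  writeLines(c(header, lines), vcf_path)
  if (!is.null(phenotype_path)) {
    readr::write_tsv(cohort$samples, phenotype_path)
  }
  invisible(cohort)
}
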