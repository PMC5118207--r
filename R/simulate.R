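#' Parameters for the synthetic study-shaped cohort
#'
#' Describes the simulated study design: an exome case/control cohort of 187
#' cases and 103 screened local controls sequenced on one capture platform,
#' joint-called with 993 external controls from a second platform with a
#' markedly lower per-site call rate (emulating ~75% 10x coverage), a target
#' panel of 86 GWAS-locus genes plus a background gene universe, and one
#' target gene carrying a planted carrier-level enrichment.
#'
#' Carriers are heterozygous, singleton-style: each carrier of a gene
#' receives exactly one of the gene's qualifying variants, chosen by fixed
#' per-variant weights. For the planted gene the case carrier probability
#' `p` solves `p/(1-p) = planted_or * q/(1-q)` with `q` the per-gene control
#' carrier rate; all other genes use `q` in both arms.
#'
#' @param n_cases,n_local_controls,n_external_controls Cohort sizes
#'   (defaults 187 / 103 / 993; total controls 1096).
#' @param n_target_genes Genes in the analysed panel (default 86).
#' @param n_background_genes Extra genes forming the universe random control
#'   sets are drawn from (default 600).
#' @param variants_per_gene Poisson mean variant count per gene (default 20).
#' @param consequence_mix Named probabilities over `synonymous`, `missense`,
#'   `lof`, `splicing`, `nonframeshift_indel`; must sum to 1.
#' @param damaging_missense_prob Probability a missense variant is given
#'   damaging scores (SIFT < 0.05 and/or PolyPhen-2 HVAR > 0.909).
#' @param maf_spectrum List: `p_common` (mass above the 1% rarity threshold),
#'   `common_range`, `rare_meanlog`/`rare_sdlog` (log-normal for rare
#'   frequencies), `p_db_present` (probability each database reports the
#'   variant).
#' @param control_carrier_rate Per-gene carrier probability `q` in controls
#'   (default 0.003, i.e. ~3 carriers per 1000).
#' @param planted_gene Symbol of the enriched gene (default `"TG001"`).
#' @param planted_or Carrier-level odds ratio planted in cases
#'   (default 13.2; must be >= 1).
#' @param capture_rate_case,capture_rate_external Per-site per-sample call
#'   probabilities for the case/local platform (0.98) and the external
#'   platform (0.75).
#' @param gq_mean,gq_sd Normal genotype-quality distribution, clipped to
#'   0-99; defaults 60/25 put ~5% of calls below the GQ-20 QC threshold.
#' @param htg_fraction Fraction of cases labelled high-tension (default
#'   122/187).
#' @param age_case_mean,age_case_sd Age at diagnosis for cases (44.4 / 10.4
#'   years).
#' @param carrier_age_shift Years added to the age at diagnosis of
#'   planted-gene carriers (default 0; negative emulates earlier onset).
#' @param iop_htg_mean,iop_htg_sd,iop_ntg_mean,iop_ntg_sd Maximum-IOP
#'   distributions; HTG values are truncated above 21 mmHg, NTG at or below.
#' @param summary_n Sample count of the simulated external summary control
#'   (default 33370, so AN = 66740).
#' @param summary_freq_scale Multiplier on qualifying-variant control
#'   frequencies in the summary cohort (default 1).
#' @param seed Integer seed; [simulate_cohort()] is fully deterministic
#'   given it.
#' @return A list with class `"sim_params"`.
#' @export
sim_params <- function(n_cases = 187,
                       n_local_controls = 103,
                       n_external_controls = 993,
                       n_target_genes = 86,
                       n_background_genes = 600,
                       variants_per_gene = 20,
                       consequence_mix = c(synonymous = 0.35, missense = 0.45,
                                           lof = 0.06, splicing = 0.04,
                                           nonframeshift_indel = 0.10),
                       damaging_missense_prob = 0.5,
                       maf_spectrum = list(p_common = 0.15,
                                           common_range = c(0.011, 0.30),
                                           rare_meanlog = log(1e-3),
                                           rare_sdlog = 1,
                                           p_db_present = 0.7),
                       control_carrier_rate = 0.003,
                       planted_gene = "TG001",
                       planted_or = 13.2,
                       capture_rate_case = 0.98,
                       capture_rate_external = 0.75,
                       gq_mean = 60, gq_sd = 25,
                       htg_fraction = 122 / 187,
                       age_case_mean = 44.4, age_case_sd = 10.4,
                       carrier_age_shift = 0,
                       iop_htg_mean = 28, iop_htg_sd = 4,
                       iop_ntg_mean = 16, iop_ntg_sd = 3,
                       summary_n = 33370,
                       summary_freq_scale = 1,
                       seed = 1L) {
  mix_names <- c("synonymous", "missense", "lof", "splicing",
                 "nonframeshift_indel")
  if (!setequal(names(consequence_mix), mix_names)) {
    abort("`consequence_mix` must name exactly: synonymous, missense, lof, splicing, nonframeshift_indel.")
  }
  if (any(consequence_mix < 0) || abs(sum(consequence_mix) - 1) > 1e-8) {
    abort("`consequence_mix` must be non-negative and sum to 1.")
  }
  stopifnot(
    damaging_missense_prob >= 0, damaging_missense_prob <= 1,
    control_carrier_rate >= 0, control_carrier_rate < 1,
    capture_rate_case >= 0, capture_rate_case <= 1,
    capture_rate_external >= 0, capture_rate_external <= 1,
    htg_fraction >= 0, htg_fraction <= 1,
    n_cases >= 1, n_local_controls >= 0, n_external_controls >= 0,
    n_target_genes >= 1, variants_per_gene > 0, summary_n >= 1
  )
  if (planted_or < 1) abort("`planted_or` must be >= 1.")
  structure(
    list(
      n_cases = as.integer(n_cases),
      n_local_controls = as.integer(n_local_controls),
      n_external_controls = as.integer(n_external_controls),
      n_target_genes = as.integer(n_target_genes),
      n_background_genes = as.integer(n_background_genes),
      variants_per_gene = variants_per_gene,
      consequence_mix = consequence_mix[mix_names],
      damaging_missense_prob = damaging_missense_prob,
      maf_spectrum = maf_spectrum,
      control_carrier_rate = control_carrier_rate,
      planted_gene = planted_gene,
      planted_or = planted_or,
      capture_rate_case = capture_rate_case,
      capture_rate_external = capture_rate_external,
      gq_mean = gq_mean, gq_sd = gq_sd,
      htg_fraction = htg_fraction,
      age_case_mean = age_case_mean, age_case_sd = age_case_sd,
      carrier_age_shift = carrier_age_shift,
      iop_htg_mean = iop_htg_mean, iop_htg_sd = iop_htg_sd,
      iop_ntg_mean = iop_ntg_mean, iop_ntg_sd = iop_ntg_sd,
      summary_n = as.integer(summary_n),
      summary_freq_scale = summary_freq_scale,
      seed = as.integer(seed)
    ),
    class = "sim_params"
  )
}

sim_gene_table <- function(params) {
  n <- params$n_target_genes + params$n_background_genes
  tibble(
    gene = c(sprintf("TG%03d", seq_len(params$n_target_genes)),
             if (params$n_background_genes > 0)
               sprintf("BG%03d", seq_len(params$n_background_genes))),
    target = rep(c(TRUE, FALSE),
                 c(params$n_target_genes, params$n_background_genes)),
    chrom = as.character(rep_len(1:22, n)),
    start = 1e6 + (seq_len(n) - 1) * 5e4
  )
}

#' Simulate a variant annotation table with known truth
#'
#' Draws a study-shaped annotation table: per gene, a Poisson number of
#' variants with consequence classes from `consequence_mix`, SIFT/PolyPhen-2
#' HVAR scores generated so that the damaging/tolerated status of every
#' missense variant is known, and per-database population frequencies from
#' `maf_spectrum` (a variant may be absent from any database). The returned
#' truth table records, per variant, the class flags and the exact
#' qualifying status implied by the emitted annotation values — the label
#' the filtering cascade must recover.
#'
#' @param params A [sim_params()] object.
#' @param seed Optional seed; when `NULL` the current RNG state is used
#'   (as done inside [simulate_cohort()]).
#' @return List with `annotations` (tibble in [read_annotations()] layout)
#'   and `truth` (tibble with `key`, `gene`, `target`, `consequence`,
#'   `true_maf`, `rare`, `pathogenic`, `qualifies`, `weight`,
#'   `control_freq`).
#' @export
simulate_variant_annotations <- function(params, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed, simulate_variant_annotations(params)))
  }
  genes <- sim_gene_table(params)
  n_var_per_gene <- pmax(1L, rpois(nrow(genes), params$variants_per_gene))
  gidx <- rep(seq_len(nrow(genes)), n_var_per_gene)
  nv <- length(gidx)
  offset <- sequence(n_var_per_gene)

  mix <- params$consequence_mix
  class_draw <- sample(names(mix), nv, replace = TRUE, prob = mix)
  consequence <- class_draw
  lof_kinds <- c("stopgain", "frameshift", "stoploss")
  consequence[class_draw == "lof"] <-
    sample(lof_kinds, sum(class_draw == "lof"), replace = TRUE,
           prob = c(0.5, 0.4, 0.1))

  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, nv, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  is_indel <- consequence %in% c("frameshift", "nonframeshift_indel")
  ins <- is_indel & (runif(nv) < 0.5)
  del <- is_indel & !ins
  tail_len <- ifelse(consequence == "nonframeshift_indel", 3L, 1L)
  tail_seq <- vapply(tail_len, function(k)
    paste(sample(bases, k, replace = TRUE), collapse = ""), character(1))
  alt[ins] <- paste0(ref[ins], tail_seq[ins])
  alt[del] <- ref[del]
  ref[del] <- paste0(ref[del], tail_seq[del])

  sp <- params$maf_spectrum
  common <- runif(nv) < sp$p_common
  true_maf <- ifelse(
    common,
    runif(nv, sp$common_range[1], sp$common_range[2]),
    pmin(0.5, stats::rlnorm(nv, sp$rare_meanlog, sp$rare_sdlog))
  )
  db_cols <- c("maf_1kg", "maf_esp", "maf_exac", "maf_dbsnp")
  mafs <- matrix(NA_real_, nv, 4, dimnames = list(NULL, db_cols))
  for (j in 1:4) {
    present <- runif(nv) < sp$p_db_present
    mafs[present, j] <- pmin(1, true_maf[present] * runif(sum(present), 0.9, 1.1))
  }
  # a common variant is always known to at least one database, so the
  # frequency filter sees it
  force_known <- common & rowSums(!is.na(mafs)) == 0
  mafs[force_known, "maf_exac"] <- true_maf[force_known]

  is_missense <- consequence == "missense"
  damaging <- is_missense & (runif(nv) < params$damaging_missense_prob)
  sift <- rep(NA_real_, nv)
  pph <- rep(NA_real_, nv)
  channel <- sample(c("sift", "pph", "both"), nv, replace = TRUE)
  d_sift <- damaging & channel %in% c("sift", "both")
  d_pph <- damaging & channel %in% c("pph", "both")
  sift[d_sift] <- runif(sum(d_sift), 0, 0.0499)
  pph[d_pph] <- runif(sum(d_pph), 0.9095, 1)
  # the non-damaging score of a one-channel damaging missense, and both
  # scores of a tolerated missense, fall in the tolerated range or go missing
  tol_sift <- is_missense & !d_sift & (runif(nv) < 0.85)
  tol_pph <- is_missense & !d_pph & (runif(nv) < 0.85)
  sift[tol_sift] <- runif(sum(tol_sift), 0.05, 1)
  pph[tol_pph] <- runif(sum(tol_pph), 0, 0.909)

  ann <- tibble(
    chrom = genes$chrom[gidx],
    pos = as.integer(genes$start[gidx] + offset * 7L),
    ref = ref, alt = alt,
    gene = genes$gene[gidx],
    consequence = consequence,
    sift = sift, polyphen_hvar = pph,
    maf_1kg = mafs[, 1], maf_esp = mafs[, 2],
    maf_exac = mafs[, 3], maf_dbsnp = mafs[, 4]
  ) |>
    mutate(key = variant_key(.data$chrom, .data$pos, .data$ref, .data$alt)) |>
    select("key", dplyr::everything())

  rare <- !apply(mafs > 0.01, 1, any, na.rm = TRUE)
  pathogenic <- consequence %in% c("stopgain", "stoploss", "frameshift",
                                   "splicing") |
    (is_missense & (d_sift | d_pph))
  qualifies <- rare & pathogenic
  weight <- rep(NA_real_, nv)
  w_raw <- rexp(nv)
  for (g in unique(gidx[qualifies])) {
    idx <- which(qualifies & gidx == g)
    weight[idx] <- w_raw[idx] / sum(w_raw[idx])
  }
  q <- params$control_carrier_rate
  truth <- tibble(
    key = ann$key, gene = ann$gene, target = genes$target[gidx],
    consequence = consequence, true_maf = true_maf,
    rare = rare, pathogenic = pathogenic, qualifies = qualifies,
    weight = weight,
    # per-allele control frequency: a carrier is heterozygous at one variant
    control_freq = ifelse(qualifies, q * weight / 2, pmin(true_maf, 0.5))
  )
  list(annotations = ann, truth = truth)
}

#' Simulate joint-called genotypes and phenotypes
#'
#' Plants carriers gene by gene (Bernoulli per sample at the gene's carrier
#' probability; each carrier heterozygous at one qualifying variant chosen
#' by the truth weights), draws non-qualifying genotypes binomially at their
#' population frequency, then applies the two missingness channels the
#' pipeline must distinguish: capture failure (platform-specific per-site
#' call probability, genotype absent) and low genotype quality (call present
#' but below the QC threshold).
#'
#' @param params A [sim_params()] object.
#' @param annotations,truth Output of [simulate_variant_annotations()].
#' @param seed Optional seed (see [simulate_variant_annotations()]).
#' @return List with `cohort` (a `"cohort_genotypes"`) and `gene_truth`
#'   (per-gene case/control carrier probabilities).
#' @export
simulate_genotypes <- function(params, annotations, truth, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
                            simulate_genotypes(params, annotations, truth)))
  }
  q <- params$control_carrier_rate
  if (q == 0 && params$planted_or > 1) {
    abort("Cannot plant an odds ratio > 1 on a control carrier rate of 0.")
  }
  odds <- params$planted_or * q / (1 - q)
  p_planted <- odds / (1 + odds)

  n_case <- params$n_cases
  n_loc <- params$n_local_controls
  n_ext <- params$n_external_controls
  ns <- n_case + n_loc + n_ext
  status <- rep(c("case", "control"), c(n_case, n_loc + n_ext))
  cohort_lbl <- rep(c("local", "local", "AOGC"), c(n_case, n_loc, n_ext))
  sample_id <- c(sprintf("CASE%04d", seq_len(n_case)),
                 sprintf("LC%04d", seq_len(n_loc)),
                 if (n_ext > 0) sprintf("EXT%04d", seq_len(n_ext)))

  nv <- nrow(annotations)
  gt <- matrix(0L, nv, ns)

  # carriers: one heterozygous qualifying variant per carrier per gene
  qual <- which(truth$qualifies)
  for (g in unique(truth$gene[qual])) {
    vrows <- qual[truth$gene[qual] == g]
    p_case <- if (g == params$planted_gene) p_planted else q
    p_vec <- ifelse(status == "case", p_case, q)
    carriers <- which(runif(ns) < p_vec)
    if (length(carriers) == 0) next
    vpick <- vrows[sample.int(length(vrows), length(carriers), replace = TRUE,
                              prob = truth$weight[vrows])]
    gt[cbind(vpick, carriers)] <- 1L
  }

  nq <- which(!truth$qualifies)
  if (length(nq) > 0) {
    f <- pmin(truth$true_maf[nq], 0.5)
    gt[nq, ] <- matrix(
      rbinom(length(nq) * ns, 2L, rep(f, times = ns)),
      nrow = length(nq)
    )
  }

  # capture failure by platform, then per-call genotype quality
  rate <- ifelse(cohort_lbl == "AOGC", params$capture_rate_external,
                 params$capture_rate_case)
  missing <- matrix(runif(nv * ns), nv, ns) >
    matrix(rep(rate, each = nv), nv, ns)
  gt[missing] <- NA_integer_
  gq <- matrix(pmin(99, pmax(0, round(rnorm(nv * ns, params$gq_mean,
                                            params$gq_sd)))), nv, ns)
  gq[missing] <- NA_real_

  subtype <- rep("unknown", ns)
  is_case <- status == "case"
  subtype[is_case] <- ifelse(runif(n_case) < params$htg_fraction,
                             "HTG", "NTG")
  planted_rows <- qual[truth$gene[qual] == params$planted_gene]
  planted_carrier <- if (length(planted_rows) > 0) {
    colSums(!is.na(gt[planted_rows, , drop = FALSE]) &
              gt[planted_rows, , drop = FALSE] > 0) > 0
  } else rep(FALSE, ns)
  age_dx <- rep(NA_real_, ns)
  age_dx[is_case] <- rnorm(n_case, params$age_case_mean, params$age_case_sd) +
    ifelse(planted_carrier[is_case], params$carrier_age_shift, 0)
  max_iop <- rep(NA_real_, ns)
  htg <- is_case & subtype == "HTG"
  ntg <- is_case & subtype == "NTG"
  max_iop[htg] <- pmax(21.5, rnorm(sum(htg), params$iop_htg_mean,
                                   params$iop_htg_sd))
  max_iop[ntg] <- pmin(21, pmax(8, rnorm(sum(ntg), params$iop_ntg_mean,
                                         params$iop_ntg_sd)))

  samples <- tibble(
    sample_id = sample_id, status = status, subtype = subtype,
    cohort = cohort_lbl, age_dx = round(age_dx, 1),
    max_iop = round(max_iop, 1)
  )
  variants <- annotations |>
    select("chrom", "pos", "ref", "alt", "key")
  cohort <- cohort_genotypes(variants, samples, gt, gq)

  gene_truth <- truth |>
    filter(.data$qualifies) |>
    distinct(.data$gene) |>
    mutate(
      control_carrier_prob = q,
      case_carrier_prob = if_else(.data$gene == params$planted_gene,
                                  p_planted, q)
    )
  list(cohort = cohort, gene_truth = gene_truth)
}

#' Simulate an external summary-statistic control
#'
#' Draws per-variant allele counts for a reference cohort of `summary_n`
#' diploid samples: `AC ~ Binomial(AN, f)` with `AN = 2 * summary_n` and `f`
#' the variant's control allele frequency (scaled by `summary_freq_scale`
#' for qualifying variants).
#'
#' @param params A [sim_params()] object.
#' @param truth Truth tibble from [simulate_variant_annotations()].
#' @param annotations Matching annotation tibble.
#' @param seed Optional seed.
#' @return Tibble in [read_summary_control()] layout.
#' @export
simulate_summary_control <- function(params, annotations, truth,
                                     seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(
      seed, simulate_summary_control(params, annotations, truth)))
  }
  an <- 2L * params$summary_n
  f <- truth$control_freq *
    ifelse(truth$qualifies, params$summary_freq_scale, 1)
  tibble(
    key = annotations$key, chrom = annotations$chrom,
    pos = annotations$pos, ref = annotations$ref, alt = annotations$alt,
    ac = rbinom(nrow(annotations), an, pmin(1, f)),
    an = an
  )
}

#' Simulate a complete study-shaped dataset
#'
#' Runs the three generator stages under one seed: annotations with truth,
#' joint-called genotypes with phenotypes, and the external summary control.
#' Deterministic given `params$seed` — repeated calls yield identical
#' objects and, through [write_simulation()], byte-identical files.
#'
#' @param params A [sim_params()] object.
#' @return A list with class `"burden_sim"`: `params`, `annotations`,
#'   `truth` (per variant), `gene_truth`, `cohort`, `summary_control`, and
#'   `gene_list` (the target panel symbols).
#' @export
simulate_cohort <- function(params = sim_params()) {
  withr::with_seed(params$seed, {
    ann <- simulate_variant_annotations(params)
    gen <- simulate_genotypes(params, ann$annotations, ann$truth)
    summ <- simulate_summary_control(params, ann$annotations, ann$truth)
    structure(
      list(
        params = params,
        annotations = ann$annotations,
        truth = ann$truth,
        gene_truth = gen$gene_truth,
        cohort = gen$cohort,
        summary_control = summ,
        gene_list = sprintf("TG%03d", seq_len(params$n_target_genes))
      ),
      class = "burden_sim"
    )
  })
}

#' @export
print.burden_sim <- function(x, ...) {
  cat(sprintf(
    "<burden_sim> %d variants in %d genes; %d cases / %d controls; planted %s (OR %.1f); seed %d\n",
    nrow(x$annotations), length(unique(x$annotations$gene)),
    sum(x$cohort$samples$status == "case"),
    sum(x$cohort$samples$status == "control"),
    x$params$planted_gene, x$params$planted_or, x$params$seed
  ))
  invisible(x)
}

#' Write a simulated dataset to files
#'
#' Emits the file set the pipeline reads: `cohort.vcf`, `phenotypes.tsv`,
#' `annotations.tsv`, `summary_control.tsv`, `gene_list.txt`, and
#' `truth.json`.
#'
#' @param sim A `"burden_sim"` object from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named list of the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    vcf = file.path(dir, "cohort.vcf"),
    phenotypes = file.path(dir, "phenotypes.tsv"),
    annotations = file.path(dir, "annotations.tsv"),
    summary_control = file.path(dir, "summary_control.tsv"),
    gene_list = file.path(dir, "gene_list.txt"),
    truth = file.path(dir, "truth.json")
  )
  write_cohort(sim$cohort, paths$vcf, paths$phenotypes)
  ann_out <- sim$annotations |>
    select(CHROM = "chrom", POS = "pos", REF = "ref", ALT = "alt",
           GENE = "gene", FUNC = "consequence", SIFT = "sift",
           PPH2_HVAR = "polyphen_hvar", MAF_1KG = "maf_1kg",
           MAF_ESP = "maf_esp", MAF_EXAC = "maf_exac",
           MAF_DBSNP = "maf_dbsnp")
  readr::write_tsv(ann_out, paths$annotations, na = ".")
  readr::write_tsv(
    sim$summary_control |>
      select(CHROM = "chrom", POS = "pos", REF = "ref", ALT = "alt",
             AC = "ac", AN = "an"),
    paths$summary_control
  )
  writeLines(sim$gene_list, paths$gene_list)
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(params = sim$params[setdiff(names(sim$params), "consequence_mix")],
           consequence_mix = as.list(sim$params$consequence_mix),
           gene_truth = sim$gene_truth, variant_truth = sim$truth),
      paths$truth, auto_unbox = TRUE, digits = NA, na = "null"
    )
  } else {
    paths$truth <- NULL
  }
  invisible(paths)
}
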