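#' Allele-level contingency table from two burdens
#'
#' Builds the 2x2 table driving the enrichment test: alternate vs reference
#' alleles in cases and controls, with the reference-allele cells derived
#' from the capture-adjusted denominators. `mean_captured` is rounded
#' half-up to an integer because the exact test needs integer cells; the
#' reference cell is clamped at zero (with a warning) in the pathological
#' case where the allele count exceeds the rounded capture.
#'
#' @param case_burden,control_burden One-row burden tibbles from
#'   [gene_burden()] (need `allele_count` and `mean_captured`).
#' @return One-row tibble with cells `a` (case alt), `b` (case ref),
#'   `c` (control alt), `d` (control ref).
#' @export
contingency_table <- function(case_burden, control_burden) {
  if (is.na(case_burden$mean_captured) || is.na(control_burden$mean_captured)) {
    abort("Undefined mean_captured: gene has no qualifying variant in a cohort.")
  }
  cell <- function(burden) {
    x <- burden$allele_count
    n <- round_half_up(burden$mean_captured)
    if (x > n) {
      warn("Allele count exceeds rounded captured alleles; reference cell clamped to 0.")
    }
    c(x, max(n - x, 0))
  }
  ca <- cell(case_burden)
  co <- cell(control_burden)
  tibble(a = as.integer(ca[1]), b = as.integer(ca[2]),
         c = as.integer(co[1]), d = as.integer(co[2]))
}

#' Two-sided Fisher exact p-value
#'
#' Point-probability (conventional) two-sided exact test on a 2x2 table:
#' conditioning on the margins, the p-value sums the hypergeometric point
#' probabilities of every table as or less probable than the observed one. A
#' relative tolerance of 1e-7 guards the comparison of point probabilities
#' against floating-point tie misclassification. Degenerate margins (an
#' all-zero row or column) give p = 1.
#'
#' @param a,b,c,d Non-negative integer cells (vectorised).
#' @return Numeric vector of p-values in (0, 1].
#' @examples
#' fisher_exact_two_sided(1, 9, 1, 9)  # identical proportions: 1
#' fisher_exact_two_sided(5, 0, 0, 5)  # 2/252
#' @export
fisher_exact_two_sided <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("Contingency cells must be non-negative.")
  one <- function(a, b, c, d) {
    m <- a + c
    nn <- b + d
    k <- a + b
    if (m + nn == 0) abort("Empty table.")
    support <- max(0, k - nn):min(k, m)
    probs <- dhyper(support, m, nn, k)
    p_obs <- dhyper(a, m, nn, k)
    min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
  }
  mapply(one, a, b, c, d)
}

#' Odds ratio with Wald confidence interval
#'
#' Sample odds ratio `a*d / (b*c)`. When any cell is zero the
#' Haldane–Anscombe correction (0.5 added to every cell) is applied first,
#' keeping the estimate and interval finite. The 95% interval is Wald on the
#' log-odds-ratio scale: `exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`
#' over the (possibly corrected) cells.
#'
#' @param a,b,c,d Non-negative cells (vectorised).
#' @return Tibble with `odds_ratio`, `ci_low`, `ci_high`.
#' @export
odds_ratio <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("Contingency cells must be non-negative.")
  zero <- (a == 0) | (b == 0) | (c == 0) | (d == 0)
  shift <- ifelse(zero, 0.5, 0)
  a <- a + shift; b <- b + shift; c <- c + shift; d <- d + shift
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  tibble(
    odds_ratio = or,
    ci_low = exp(log(or) - 1.96 * se),
    ci_high = exp(log(or) + 1.96 * se)
  )
}

#' Bonferroni correction
#'
#' Multiplies each raw p-value by the number of tests, capped at 1.
#'
#' @param p Raw p-values.
#' @param n_tests Number of tests in the family (>= 1).
#' @return Corrected p-values.
#' @examples
#' bonferroni_correct(6.94e-5, 86)  # 5.97e-3
#' @export
bonferroni_correct <- function(p, n_tests) {
  stopifnot(n_tests >= 1)
  vapply(p, function(pp) p.adjust(pp, method = "bonferroni", n = n_tests),
         numeric(1))
}

new_burden_assoc <- function(x, alpha, n_tests, subgroup = NULL) {
  structure(
    x,
    alpha = alpha, n_tests = n_tests, subgroup = subgroup,
    class = c("burden_assoc", class(tibble())))
}

#' Per-gene case/control association
#'
#' For every gene of the qualifying map, builds the capture-adjusted
#' allele-level 2x2 table of cases (optionally restricted to the HTG or NTG
#' subgroup) versus all controls, and computes the odds ratio, Wald CI,
#' two-sided Fisher exact p and Bonferroni-corrected p. Genes with no
#' qualifying variant, or with an undefined capture denominator on either
#' side, are reported with `NA` statistics and excluded from the Bonferroni
#' denominator (unless `config$n_genes_tested` fixes it).
#'
#' @param cohort A `"cohort_genotypes"` object (cases and controls).
#' @param qualifying Long `gene`/`key` tibble from [select_qualifying()].
#' @param subgroup Optional `"HTG"` or `"NTG"`: restrict cases to that
#'   subtype (controls are never restricted).
#' @param genes Genes to test; default the recorded gene list.
#' @param config A [run_config()]; supplies `alpha` and optionally a fixed
#'   Bonferroni denominator.
#' @return A `"burden_assoc"` tibble: one row per gene with cells `a`-`d`,
#'   loads, carrier counts, `odds_ratio`, `ci_low`, `ci_high`, `p_raw`,
#'   `p_bonferroni`, `significant`. Attributes `alpha` and `n_tests` record
#'   the testing family; see [glance.burden_assoc()].
#' @export
associate_genes <- function(cohort, qualifying, subgroup = NULL,
                            genes = NULL, config = run_config()) {
  genes <- genes %||% attr(qualifying, "genes") %||% unique(qualifying$gene)
  is_case <- cohort$samples$status == "case"
  if (!is.null(subgroup)) {
    subgroup <- match.arg(subgroup, c("HTG", "NTG"))
    is_case <- is_case & cohort$samples$subtype == subgroup
  }
  is_control <- cohort$samples$status == "control"
  if (!any(is_case) || !any(is_control)) {
    abort("Need at least one case and one control sample.")
  }
  key_rows <- match(qualifying$key, cohort$variants$key)
  counts_case <- qc_counts_matrix(cohort, which(is_case), config$gq_threshold)
  counts_ctrl <- qc_counts_matrix(cohort, which(is_control), config$gq_threshold)

  rows <- purrr::map_dfr(genes, function(gn) {
    vrows <- key_rows[qualifying$gene == gn]
    bc <- burden_one(counts_case, vrows, sum(is_case))
    bt <- burden_one(counts_ctrl, vrows, sum(is_control))
    base <- tibble(
      gene = gn, n_variants = length(vrows),
      case_load = bc$load, control_load = bt$load,
      case_carriers = bc$carriers, control_carriers = bt$carriers,
      case_n = bc$n_samples, control_n = bt$n_samples
    )
    testable <- length(vrows) > 0 &&
      !is.na(bc$mean_captured) && bc$mean_captured > 0 &&
      !is.na(bt$mean_captured) && bt$mean_captured > 0
    if (!testable) {
      return(bind_cols(base, tibble(a = NA_integer_, b = NA_integer_,
                                    c = NA_integer_, d = NA_integer_)))
    }
    bind_cols(base, contingency_table(bc, bt))
  })

  tested <- !is.na(rows$a)
  n_tests <- config$n_genes_tested %||% sum(tested)
  rows$odds_ratio <- rows$ci_low <- rows$ci_high <- NA_real_
  rows$p_raw <- rows$p_bonferroni <- NA_real_
  if (any(tested)) {
    or <- odds_ratio(rows$a[tested], rows$b[tested],
                     rows$c[tested], rows$d[tested])
    rows$odds_ratio[tested] <- or$odds_ratio
    rows$ci_low[tested] <- or$ci_low
    rows$ci_high[tested] <- or$ci_high
    rows$p_raw[tested] <- fisher_exact_two_sided(
      rows$a[tested], rows$b[tested], rows$c[tested], rows$d[tested])
    rows$p_bonferroni[tested] <- bonferroni_correct(rows$p_raw[tested],
                                                    max(n_tests, 1))
  }
  rows$significant <- !is.na(rows$p_bonferroni) &
    rows$p_bonferroni < config$alpha
  rows <- select(
    rows, "gene", "n_variants", "a", "b", "c", "d",
    "case_load", "control_load", "case_carriers", "control_carriers",
    "case_n", "control_n", "odds_ratio", "ci_low", "ci_high",
    "p_raw", "p_bonferroni", "significant"
  )
  new_burden_assoc(rows, alpha = config$alpha, n_tests = n_tests,
                   subgroup = subgroup)
}

#' Association against a summary-statistic external control
#'
#' Compares a gene's case burden against an external reference cohort known
#' only through per-variant allele counts (AC) and called-allele numbers
#' (AN). Qualifying variants absent from the summary table contribute AC = 0
#' with AN imputed as the median AN of the present variants (an absent
#' variant in a large reference is an unobserved, not an uncaptured, site).
#' The control cells are `c = sum(AC)` and `d = round(mean(AN)) - c`; the OR
#' and Fisher machinery is identical to the internal comparison.
#'
#' @param case_burden One-row burden tibble from [gene_burden()] on the case
#'   samples.
#' @param summary_control Tibble from [read_summary_control()].
#' @param qualifying_keys The gene's qualifying variant keys.
#' @param gene Gene symbol (for labelling).
#' @param config A [run_config()]; `n_genes_tested` (default 1) is the
#'   Bonferroni denominator.
#' @return One-row `"burden_assoc"` tibble.
#' @export
associate_vs_summary <- function(case_burden, summary_control,
                                 qualifying_keys, gene = NA_character_,
                                 config = run_config()) {
  if (length(qualifying_keys) == 0) abort("Empty qualifying set.")
  hit <- match(qualifying_keys, summary_control$key)
  if (all(is.na(hit))) {
    abort("No qualifying variant present in the summary control; AN cannot be imputed.")
  }
  an_present <- summary_control$an[hit[!is.na(hit)]]
  ac <- ifelse(is.na(hit), 0L, summary_control$ac[hit])
  an <- ifelse(is.na(hit), median(an_present), summary_control$an[hit])
  ctrl <- tibble(allele_count = sum(ac), mean_captured = mean(an))
  tab <- contingency_table(case_burden, ctrl)
  or <- odds_ratio(tab$a, tab$b, tab$c, tab$d)
  p <- fisher_exact_two_sided(tab$a, tab$b, tab$c, tab$d)
  n_tests <- config$n_genes_tested %||% 1L
  out <- bind_cols(
    tibble(gene = gene, n_variants = length(qualifying_keys),
           case_load = case_burden$load,
           control_load = ctrl$allele_count / ctrl$mean_captured,
           case_carriers = case_burden$carriers,
           control_carriers = NA_integer_,
           case_n = case_burden$n_samples,
           control_n = round_half_up(ctrl$mean_captured / 2)),
    tab, or,
    tibble(p_raw = p,
           p_bonferroni = bonferroni_correct(p, n_tests))
  )
  out$significant <- out$p_bonferroni < config$alpha
  new_burden_assoc(out, alpha = config$alpha, n_tests = n_tests)
}

#' Carrier-level gene-set enrichment
#'
#' Panel-wide analogue of the per-gene test at the carrier level: the 2x2
#' table counts carriers vs non-carriers of any qualifying variant in the
#' gene set, cases against controls.
#'
#' @inheritParams geneset_burden
#' @return One-row tibble: carrier counts and rates per arm, `odds_ratio`,
#'   `ci_low`, `ci_high`, `p_raw`.
#' @export
test_geneset_carriers <- function(cohort, qualifying, genes = NULL,
                                  config = run_config()) {
  gs <- geneset_burden(cohort, qualifying, by = "status", genes = genes,
                       config = config)
  ca <- gs[gs$cohort == "case", ]
  co <- gs[gs$cohort == "control", ]
  if (nrow(ca) != 1 || nrow(co) != 1) {
    abort("Need both case and control samples.")
  }
  a <- ca$carriers; b <- ca$n_samples - ca$carriers
  c <- co$carriers; d <- co$n_samples - co$carriers
  bind_cols(
    tibble(n_genes = ca$n_genes,
           case_carriers = a, case_n = ca$n_samples,
           case_rate = ca$carrier_rate,
           control_carriers = c, control_n = co$n_samples,
           control_rate = co$carrier_rate),
    odds_ratio(a, b, c, d),
    tibble(p_raw = fisher_exact_two_sided(a, b, c, d))
  )
}

#' Compare a quantitative trait between carriers and non-carriers
#'
#' Welch two-sample t-test (two-sided) of a trait such as age at diagnosis
#' or maximum IOP between carriers and non-carriers. When a group has fewer
#' than two non-missing values, or the trait is essentially constant (Welch
#' is undefined), the test falls back to an exact (or, for large designs,
#' Monte-Carlo) permutation test on the absolute mean difference; two
#' identical constant groups give p = 1.
#'
#' @param carrier Logical vector: does each sample carry a qualifying
#'   variant?
#' @param trait Numeric trait values (NA dropped pairwise).
#' @param n_perm Monte-Carlo permutation count used only when exact
#'   enumeration exceeds `max_exact` assignments.
#' @param max_exact Enumeration budget for the exact permutation fallback.
#' @return One-row tibble: `mean_carrier`, `mean_noncarrier`, `n_carrier`,
#'   `n_noncarrier`, `p`, `method`.
#' @export
carrier_trait_test <- function(carrier, trait, n_perm = 10000,
                               max_exact = 50000) {
  stopifnot(length(carrier) == length(trait))
  keep <- !is.na(trait) & !is.na(carrier)
  carrier <- carrier[keep]
  trait <- trait[keep]
  n1 <- sum(carrier)
  n0 <- sum(!carrier)
  if (n1 < 1 || n0 < 1) {
    abort("Need at least one carrier and one non-carrier with a trait value.")
  }
  m1 <- mean(trait[carrier])
  m0 <- mean(trait[!carrier])
  res <- tibble(mean_carrier = m1, mean_noncarrier = m0,
                n_carrier = n1, n_noncarrier = n0)
  welch_ok <- n1 >= 2 && n0 >= 2 &&
    (stats::sd(trait[carrier]) > 0 || stats::sd(trait[!carrier]) > 0)
  if (welch_ok) {
    p <- t.test(trait[carrier], trait[!carrier])$p.value
    return(mutate(res, p = p, method = "welch"))
  }
  if (isTRUE(all.equal(stats::var(trait), 0)) || length(unique(trait)) == 1) {
    return(mutate(res, p = 1, method = "degenerate"))
  }
  obs <- abs(m1 - m0)
  stat_for <- function(idx) {
    abs(mean(trait[idx]) - mean(trait[-idx]))
  }
  n <- length(trait)
  if (choose(n, n1) <= max_exact) {
    stats_all <- utils::combn(n, n1, stat_for)
    p <- mean(stats_all >= obs * (1 - 1e-12))
    method <- "permutation_exact"
  } else {
    stats_all <- replicate(n_perm, stat_for(sample.int(n, n1)))
    p <- (sum(stats_all >= obs * (1 - 1e-12)) + 1) / (n_perm + 1)
    method <- "permutation_mc"
  }
  mutate(res, p = p, method = method)
}
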