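burden_row <- function(ac, n) {
  tibble::tibble(allele_count = ac, mean_captured = n,
                 load = ifelse(n > 0, ac / n, NA), carriers = ac,
                 n_samples = round(n / 2))
}

test_that("contingency tables derive reference cells from rounded capture", {
  tab <- contingency_table(burden_row(8, 374), burden_row(3, 2142))
  expect_equal(unlist(tab), c(a = 8L, b = 366L, c = 3L, d = 2139L))
  tab0 <- contingency_table(burden_row(0, 374), burden_row(0, 2192))
  expect_equal(unlist(tab0), c(a = 0L, b = 374L, c = 0L, d = 2192L))
  # fractional capture rounds half-up
  expect_equal(contingency_table(burden_row(1, 373.5), burden_row(0, 10))$b,
               373L)
  expect_warning(
    tabc <- contingency_table(burden_row(5, 3.6), burden_row(0, 10)),
    "clamped")
  expect_equal(tabc$b, 0L)
  expect_error(contingency_table(burden_row(0, NA), burden_row(1, 10)),
               "mean_captured")
})

test_that("two-sided Fisher p matches closed forms and the reference test", {
  expect_equal(fisher_exact_two_sided(1, 9, 1, 9), 1.0)
  # margins (5,5)/(5,5): 6 tables, the two extremes each 1/252
  expect_equal(fisher_exact_two_sided(5, 0, 0, 5), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_two_sided(8, 366, 3, 2139),
               fisher_oracle(8, 366, 3, 2139), tolerance = 1e-12)
  # degenerate margin: only one table possible
  expect_equal(fisher_exact_two_sided(0, 10, 0, 20), 1.0)
  expect_error(fisher_exact_two_sided(-1, 1, 1, 1), "non-negative")

  withr::local_seed(8)
  for (i in 1:50) {
    cells <- as.integer(rpois(4, lambda = sample(c(2, 10, 40), 1)))
    if (sum(cells[1:2]) == 0 || sum(cells[3:4]) == 0) next
    mine <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))$p.value
    expect_equal(mine, ref, tolerance = 1e-9)
  }
})

test_that("odds ratios use ad/bc with Haldane correction on zero cells", {
  expect_equal(odds_ratio(1, 1, 1, 1)$odds_ratio, 1)
  expect_equal(odds_ratio(8, 366, 3, 2140)$odds_ratio, 17120 / 1098)
  hz <- odds_ratio(0, 10, 5, 5)
  expect_equal(hz$odds_ratio, (0.5 * 5.5) / (10.5 * 5.5))
  expect_true(is.finite(hz$ci_low) && is.finite(hz$ci_high))
  or <- odds_ratio(8, 366, 3, 2140)
  expect_true(or$ci_low < or$odds_ratio && or$odds_ratio < or$ci_high)
  se <- sqrt(1 / 8 + 1 / 366 + 1 / 3 + 1 / 2140)
  expect_equal(or$ci_low, exp(log(17120 / 1098) - 1.96 * se))
})

test_that("Bonferroni correction multiplies and caps", {
  expect_equal(bonferroni_correct(6.94e-5, 86), 6.94e-5 * 86)
  expect_equal(signif(bonferroni_correct(6.94e-5, 86), 3), 5.97e-3)
  expect_equal(bonferroni_correct(0.5, 86), 1)
  expect_equal(bonferroni_correct(0.123, 1), 0.123)
})

test_that("swapping case and control inverts the OR and keeps p", {
  withr::local_seed(21)
  for (i in 1:25) {
    cells <- as.integer(rpois(4, 8) + 1)
    or1 <- odds_ratio(cells[1], cells[2], cells[3], cells[4])$odds_ratio
    or2 <- odds_ratio(cells[3], cells[4], cells[1], cells[2])$odds_ratio
    expect_equal(or1, 1 / or2)
    p1 <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
    p2 <- fisher_exact_two_sided(cells[3], cells[4], cells[1], cells[2])
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})

test_that("p decreases as the case-alt cell grows past its expectation", {
  # margins fixed: row1 = 20, row2 = 2000, col totals shift with a
  n1 <- 20; n2 <- 2000
  as <- 8:14
  ps <- vapply(as, function(a) {
    fisher_exact_two_sided(a, n1 - a, 10, n2 - 10)
  }, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("associate_genes flags a strongly planted gene and respects subgroups", {
  p <- small_sim_params(planted_or = 40, n_cases = 187,
                        n_local_controls = 103, n_external_controls = 993)
  sim <- simulate_cohort(p)
  cfg <- run_config()
  qual <- select_qualifying(sim$cohort, sim$annotations, sim$gene_list, cfg)
  res <- associate_genes(sim$cohort, qual, config = cfg)
  expect_s3_class(res, "burden_assoc")
  top <- tidy(res)[1, ]
  expect_equal(top$gene, p$planted_gene)
  expect_true(top$significant)
  expect_gt(top$odds_ratio, 1)

  g <- glance(res)
  expect_equal(g$n_tests, sum(!is.na(res$p_raw)))
  expect_equal(g$p_threshold, cfg$alpha / g$n_tests)

  htg <- associate_genes(sim$cohort, qual, subgroup = "HTG", config = cfg)
  n_htg <- sum(sim$cohort$samples$subtype == "HTG")
  expect_equal(unique(htg$case_n), n_htg)
  expect_equal(unique(htg$control_n), 1096L)
})

test_that("genes without qualifying variants are excluded from the family", {
  co <- tiny_cohort()
  ann <- tiny_annotations()
  cfg <- run_config()
  suppressWarnings(
    qual <- select_qualifying(co, ann, c("GENEA", "GENEB", "GENED"), cfg))
  res <- associate_genes(co, qual, config = cfg)
  expect_equal(nrow(res), 3)
  expect_equal(attr(res, "n_tests"), 1)
  expect_true(is.na(res$p_raw[res$gene == "GENED"]))
  # fixed denominator override
  cfg86 <- run_config(n_genes_tested = 86)
  res86 <- associate_genes(co, qual, config = cfg86)
  expect_equal(res86$p_bonferroni[res86$gene == "GENEA"],
               min(1, res86$p_raw[res86$gene == "GENEA"] * 86))
})

test_that("summary-control comparison builds AC/AN cells and imputes AN", {
  summ <- tibble::tibble(
    key = c("k1", "k2", "k3"),
    ac = c(10L, 5L, 5L), an = c(66740L, 66740L, 66740L)
  )
  res <- associate_vs_summary(burden_row(8, 374), summ,
                              c("k1", "k2", "k3"), "G")
  expect_equal(unlist(res[, c("a", "b", "c", "d")]),
               c(a = 8L, b = 366L, c = 20L, d = 66720L))
  # absent variant contributes AC 0 with AN imputed at the median
  res2 <- associate_vs_summary(burden_row(8, 374), summ,
                               c("k1", "k2", "k3", "k4"), "G")
  expect_equal(res2$c, 20L)
  expect_equal(res2$d, 66720L)
  # all-zero AC: Haldane-corrected finite OR
  summ0 <- dplyr::mutate(summ, ac = 0L)
  res3 <- associate_vs_summary(burden_row(8, 374), summ0, summ0$key, "G")
  expect_true(is.finite(res3$odds_ratio) && res3$odds_ratio > 1)
  expect_error(
    associate_vs_summary(burden_row(8, 374), summ, c("kX", "kY"), "G"),
    "AN cannot be imputed")
})

test_that("summary-control ORs recover a planted frequency ratio", {
  # summary cohort with 3x lower qualifying frequency than internal controls
  p <- small_sim_params(planted_or = 1, summary_freq_scale = 1 / 3,
                        control_carrier_rate = 0.01, n_target_genes = 6)
  cfg <- run_config()
  ors <- vapply(1:20, function(s) {
    pp <- p; pp$seed <- 1000L + s
    sim <- simulate_cohort(pp)
    qual <- select_qualifying(sim$cohort, sim$annotations, sim$gene_list, cfg)
    keys <- qual$key[qual$gene == "TG001"]
    if (length(keys) == 0) return(NA_real_)
    cb <- gene_burden(sim$cohort, keys,
                      samples = sim$cohort$samples$status == "control",
                      config = cfg)
    associate_vs_summary(cb, sim$summary_control, keys, "TG001",
                         cfg)$odds_ratio
  }, numeric(1))
  med <- median(ors, na.rm = TRUE)
  expect_gt(med, 3 / 2)   # within a factor 2 of the planted ratio 3
  expect_lt(med, 3 * 2)
})

test_that("carrier trait contrasts: Welch, degenerate and permutation paths", {
  withr::local_seed(9)
  # same distribution in both groups: p well above any signal level
  x <- rnorm(200, 44.8, 10)
  carrier <- rep(c(TRUE, FALSE), each = 100)
  res <- carrier_trait_test(carrier, x)
  expect_equal(res$method, "welch")
  expect_gt(res$p, 0.05)

  # generator-recovery of the printed means
  tr <- c(rnorm(2000, 34.9, 8), rnorm(2000, 44.8, 10))
  cf <- rep(c(TRUE, FALSE), each = 2000)
  res2 <- carrier_trait_test(cf, tr)
  expect_equal(res2$mean_carrier, 34.9, tolerance = 0.02)
  expect_equal(res2$mean_noncarrier, 44.8, tolerance = 0.02)
  expect_lt(res2$p, 1e-6)

  # constant trait: degenerate p = 1
  res3 <- carrier_trait_test(c(TRUE, TRUE, FALSE, FALSE), rep(5, 4))
  expect_equal(res3$p, 1)
  expect_equal(res3$method, "degenerate")

  # single carrier: exact permutation fallback still defined
  res4 <- carrier_trait_test(c(TRUE, rep(FALSE, 9)), c(10, rnorm(9)))
  expect_equal(res4$method, "permutation_exact")
  expect_true(res4$p > 0 && res4$p <= 1)
  expect_error(carrier_trait_test(rep(FALSE, 4), rnorm(4)), "at least one")
})

test_that("gene-set carrier test compares panel-wide carrier rates", {
  sim <- simulate_cohort(small_sim_params(planted_or = 1))
  cfg <- run_config()
  qual <- select_qualifying(sim$cohort, sim$annotations, sim$gene_list, cfg)
  gs <- test_geneset_carriers(sim$cohort, qual, config = cfg)
  expect_equal(gs$case_carriers + round(gs$case_n * (1 - gs$case_rate)),
               gs$case_n)
  expect_true(gs$p_raw > 0 && gs$p_raw <= 1)
})
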