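test_that("simulation is fully deterministic given the seed", {
  p <- small_sim_params()
  s1 <- simulate_cohort(p)
  s2 <- simulate_cohort(p)
  expect_identical(s1$annotations, s2$annotations)
  expect_identical(s1$cohort$gt, s2$cohort$gt)
  expect_identical(s1$summary_control, s2$summary_control)

  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_simulation(s1, d1)
  write_simulation(s2, d2)
  for (f in c("cohort.vcf", "annotations.tsv", "phenotypes.tsv",
              "summary_control.tsv", "gene_list.txt")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  }
  p2 <- small_sim_params(seed = 43)
  expect_false(identical(simulate_cohort(p2)$cohort$gt, s1$cohort$gt))
})

test_that("consequence mix controls the qualifying truth", {
  p_syn <- small_sim_params(consequence_mix = c(
    synonymous = 1, missense = 0, lof = 0, splicing = 0,
    nonframeshift_indel = 0))
  ann <- simulate_variant_annotations(p_syn, seed = 5)
  expect_equal(sum(ann$truth$qualifies), 0)

  p_mis <- small_sim_params(
    consequence_mix = c(synonymous = 0, missense = 1, lof = 0, splicing = 0,
                        nonframeshift_indel = 0),
    damaging_missense_prob = 1)
  ann2 <- simulate_variant_annotations(p_mis, seed = 5)
  expect_true(all(ann2$truth$qualifies[ann2$truth$rare]))
})

test_that("given rarity, the qualifying fraction follows the mix arithmetic", {
  p <- small_sim_params(n_target_genes = 40, n_background_genes = 20,
                        variants_per_gene = 20)
  ann <- simulate_variant_annotations(p, seed = 17)
  mix <- p$consequence_mix
  p_path <- mix[["lof"]] + mix[["splicing"]] +
    mix[["missense"]] * p$damaging_missense_prob
  rare <- ann$truth$rare
  expect_within_binom99(sum(ann$truth$qualifies[rare]), sum(rare), p_path)
  # and the common mass matches its parameter
  expect_within_binom99(sum(!rare), nrow(ann$truth),
                        p$maf_spectrum$p_common)
})

test_that("scores encode the planted damaging status exactly", {
  ann <- simulate_variant_annotations(small_sim_params(), seed = 23)
  mis <- ann$annotations$consequence == "missense"
  sift_dmg <- !is.na(ann$annotations$sift) & ann$annotations$sift < 0.05
  pph_dmg <- !is.na(ann$annotations$polyphen_hvar) &
    ann$annotations$polyphen_hvar > 0.909
  expect_equal(ann$truth$pathogenic[mis], (sift_dmg | pph_dmg)[mis])
})

test_that("planted carrier probability matches the odds identity", {
  p <- small_sim_params(control_carrier_rate = 0.003, planted_or = 13.2)
  sim <- simulate_cohort(p)
  # p = OR*q/(1-q) / (1 + OR*q/(1-q)) evaluated independently
  odds <- 13.2 * 0.003 / 0.997
  expect_equal(
    sim$gene_truth$case_carrier_prob[sim$gene_truth$gene == "TG001"],
    odds / (1 + odds))
  expect_equal(sim$gene_truth$case_carrier_prob[
    sim$gene_truth$gene != "TG001"],
    rep(0.003, sum(sim$gene_truth$gene != "TG001")))
  expect_error(
    simulate_cohort(small_sim_params(control_carrier_rate = 0,
                                     planted_or = 13.2)),
    "carrier rate of 0")
})

test_that("null planting gives equal carrier rates in expectation", {
  p <- small_sim_params(planted_or = 1, n_cases = 500,
                        n_local_controls = 0, n_external_controls = 500,
                        control_carrier_rate = 0.05, n_target_genes = 5)
  sim <- simulate_cohort(p)
  gt <- sim$gene_truth
  expect_equal(gt$case_carrier_prob, gt$control_carrier_prob)
  qkeys <- sim$truth$key[sim$truth$qualifies & sim$truth$gene == "TG001"]
  rows <- match(qkeys, sim$cohort$variants$key)
  carrier <- colSums(sim$cohort$gt[rows, , drop = FALSE] > 0,
                     na.rm = TRUE) > 0
  is_case <- sim$cohort$samples$status == "case"
  expect_within_binom99(sum(carrier[is_case]), sum(is_case), 0.05)
  expect_within_binom99(sum(carrier[!is_case]), sum(!is_case), 0.05)
})

test_that("capture and GQ are distinct missingness channels", {
  p <- small_sim_params(capture_rate_case = 1, capture_rate_external = 1)
  sim <- simulate_cohort(p)
  expect_equal(sum(is.na(sim$cohort$gt)), 0)

  p2 <- small_sim_params(capture_rate_case = 0.9,
                         capture_rate_external = 0.6)
  sim2 <- simulate_cohort(p2)
  ext <- sim2$cohort$samples$cohort == "AOGC"
  miss_ext <- mean(is.na(sim2$cohort$gt[, ext]))
  miss_loc <- mean(is.na(sim2$cohort$gt[, !ext]))
  expect_within_binom99(sum(is.na(sim2$cohort$gt[, ext])),
                        length(sim2$cohort$gt[, ext]), 0.4)
  expect_within_binom99(sum(is.na(sim2$cohort$gt[, !ext])),
                        length(sim2$cohort$gt[, !ext]), 0.1)
  # GQ failures happen on called genotypes (present but filtered)
  called_low_gq <- !is.na(sim2$cohort$gt) & sim2$cohort$gq < 20
  expect_gt(sum(called_low_gq), 0)
})

test_that("phenotypes reflect the HTG/NTG design", {
  sim <- simulate_cohort(small_sim_params(n_cases = 187))
  s <- sim$cohort$samples
  cases <- s$status == "case"
  expect_within_binom99(sum(s$subtype[cases] == "HTG"), 187, 122 / 187)
  expect_true(all(s$max_iop[cases & s$subtype == "HTG"] > 21))
  expect_true(all(s$max_iop[cases & s$subtype == "NTG"] <= 21))
  expect_true(all(s$subtype[!cases] == "unknown"))
  expect_true(all(is.na(s$age_dx[!cases])))
})

test_that("summary control allele counts are binomial at the control frequency", {
  p <- small_sim_params(summary_n = 50000)
  sim <- simulate_cohort(p)
  an <- 2 * 50000
  expect_true(all(sim$summary_control$an == an))
  expect_equal(nrow(sim$summary_control), nrow(sim$annotations))
  f0 <- sim$truth$control_freq == 0
  expect_true(all(sim$summary_control$ac[f0] == 0))
  checked <- which(sim$truth$control_freq > 1e-3)[1:10]
  for (i in checked) {
    expect_within_binom99(sim$summary_control$ac[i], an,
                          sim$truth$control_freq[i])
  }
})

test_that("reading back the written VCF reproduces the generator's counts", {
  sim <- simulate_cohort(small_sim_params())
  d <- withr::local_tempdir()
  paths <- write_simulation(sim, d)
  back <- read_cohort(paths$vcf, paths$phenotypes)
  expect_equal(unname(back$gt), unname(sim$cohort$gt))
  expect_equal(rowSums(back$gt, na.rm = TRUE),
               rowSums(sim$cohort$gt, na.rm = TRUE),
               ignore_attr = TRUE)
  ann_back <- read_annotations(paths$annotations)
  expect_equal(ann_back$sift, sim$annotations$sift)
  expect_equal(ann_back$maf_exac, sim$annotations$maf_exac)
  expect_equal(ann_back$consequence, sim$annotations$consequence)
})

test_that("the planted gene wins the panel in most seeds end to end", {
  cfg <- run_config()
  hits <- vapply(1:20, function(s) {
    p <- small_sim_params(
      n_cases = 187, n_local_controls = 103, n_external_controls = 993,
      n_target_genes = 20, n_background_genes = 0,
      variants_per_gene = 10, planted_or = 13, seed = 2000 + s)
    sim <- simulate_cohort(p)
    qual <- suppressWarnings(
      select_qualifying(sim$cohort, sim$annotations, sim$gene_list, cfg))
    res <- tidy(associate_genes(sim$cohort, qual, config = cfg))
    res$gene[which.min(res$p_raw)] == "TG001"
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})
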