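# shared fixtures and independent oracles

# 4 variants x 6 samples (3 cases, 3 controls) with hand-readable dosages
tiny_cohort <- function() {
  variants <- tibble::tibble(
    chrom = "1", pos = c(100L, 200L, 300L, 400L),
    ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C")
  )
  samples <- tibble::tibble(
    sample_id = sprintf("S%d", 1:6),
    status = rep(c("case", "control"), each = 3),
    subtype = c("HTG", "NTG", "HTG", rep("unknown", 3)),
    cohort = c(rep("local", 4), "AOGC", "AOGC"),
    age_dx = c(35, 44, 51, NA, NA, NA),
    max_iop = c(28, 17, 30, NA, NA, NA)
  )
  gt <- matrix(c(
    1L, 0L, NA, 0L, 1L, 0L,
    0L, 2L, 0L, 0L, 0L, 0L,
    0L, 0L, 1L, 1L, 0L, 0L,
    0L, 0L, 0L, 0L, 0L, 2L
  ), nrow = 4, byrow = TRUE)
  gq <- matrix(c(
    99, 45, NA, 60, 19, 80,
    30, 20, 99, 99, 99, 99,
    99, 99, 25, 18, 99, 99,
    99, 99, 99, 99, 99, 35
  ), nrow = 4, byrow = TRUE)
  geneburden::cohort_genotypes(variants, samples, gt, gq)
}

tiny_annotations <- function() {
  tibble::tibble(
    chrom = "1", pos = c(100L, 200L, 300L, 400L),
    ref = c("A", "C", "G", "T"), alt = c("G", "T", "A", "C"),
    gene = c("GENEA", "GENEA", "GENEB", "GENEC"),
    consequence = c("missense", "stopgain", "missense", "synonymous"),
    sift = c(0.01, NA, 0.4, NA),
    polyphen_hvar = c(0.2, NA, 0.5, NA),
    maf_1kg = NA_real_, maf_esp = NA_real_,
    maf_exac = c(1e-4, NA, 2e-4, 1e-4), maf_dbsnp = NA_real_,
    key = paste("1", c(100, 200, 300, 400),
                c("A", "C", "G", "T"), c("G", "T", "A", "C"), sep = ":")
  )[, c("key", "chrom", "pos", "ref", "alt", "gene", "consequence",
        "sift", "polyphen_hvar", "maf_1kg", "maf_esp", "maf_exac",
        "maf_dbsnp")]
}

# independent two-sided Fisher oracle: exhaustive enumeration with
# binomial-coefficient arithmetic (lchoose), no dhyper
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lp <- function(x) {
    lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)
  }
  support <- max(0, c1 - (n - r1)):min(r1, c1)
  probs <- exp(vapply(support, lp, numeric(1)))
  p_obs <- exp(lp(a))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# small fast simulation parameters for property tests
small_sim_params <- function(...) {
  defaults <- list(
    n_cases = 60, n_local_controls = 30, n_external_controls = 110,
    n_target_genes = 12, n_background_genes = 8,
    variants_per_gene = 8, seed = 42
  )
  do.call(geneburden::sim_params, utils::modifyList(defaults, list(...)))
}

# two-sided 99% binomial interval for an observed count
binom99 <- function(n, p) {
  c(stats::qbinom(0.005, n, p), stats::qbinom(0.995, n, p))
}
expect_within_binom99 <- function(x, n, p) {
  bounds <- binom99(n, p)
  expect_gte(x, bounds[1])
  expect_lte(x, bounds[2])
}
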