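#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a per-gene association result
#'
#' Returns the per-gene rows as a plain tibble, one row per tested gene by
#' default, ordered by raw p-value (ties alphabetical).
#'
#' @param x A `"burden_assoc"` object from [associate_genes()].
#' @param tested_only Drop genes without a testable table (default `TRUE`).
#' @param ... Unused.
#' @return A tibble.
#' @method tidy burden_assoc
#' @export
tidy.burden_assoc <- function(x, tested_only = TRUE, ...) {
  out <- as_tibble(x)
  if (tested_only) out <- filter(out, !is.na(.data$p_raw))
  arrange(out, .data$p_raw, .data$gene)
}

#' One-row summary of an association run
#'
#' @param x A `"burden_assoc"` object.
#' @param ... Unused.
#' @return Tibble with the testing-family size, the significance level, the
#'   Bonferroni-equivalent raw-p threshold (`alpha / n_tests`), significant
#'   gene count and smallest raw p.
#' @method glance burden_assoc
#' @export
glance.burden_assoc <- function(x, ...) {
  alpha <- attr(x, "alpha")
  n_tests <- attr(x, "n_tests")
  tibble(
    n_genes = nrow(x),
    n_tested = sum(!is.na(x$p_raw)),
    n_tests = n_tests,
    alpha = alpha,
    p_threshold = alpha / max(n_tests, 1),
    n_significant = sum(x$significant, na.rm = TRUE),
    min_p_raw = if (any(!is.na(x$p_raw))) min(x$p_raw, na.rm = TRUE)
                else NA_real_,
    subgroup = attr(x, "subgroup") %||% NA_character_
  )
}
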