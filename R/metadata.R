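#' Contingency table for two metadata factors
#'
#' Cross-tabulates two categorical factors over samples. Categories are
#' ordered lexicographically for deterministic output.
#'
#' @param metadata A data frame with one row per sample (a `sample_id`
#'   column is ignored for counting).
#' @param factor_a,factor_b Column names of the two factors.
#' @return An integer counts matrix (categories of `factor_a` in rows).
#' @export
contingency_table <- function(metadata, factor_a, factor_b) {
  for (f in c(factor_a, factor_b)) {
    if (!f %in% names(metadata)) abort(sprintf("unknown factor '%s'", f))
  }
  a <- as.character(metadata[[factor_a]])
  b <- as.character(metadata[[factor_b]])
  if (anyNA(a) || anyNA(b)) abort("factors must be present for all samples")
  tab <- table(factor(a, levels = sort(unique(a))),
               factor(b, levels = sort(unique(b))))
  unclass(tab)
}

#' Pearson's chi-squared test of independence
#'
#' Classic Pearson statistic sum((O - E)^2 / E) on a counts table, no
#' continuity correction, degrees of freedom (rows - 1)(cols - 1), p-value
#' from the asymptotic chi-squared distribution. Empty rows/columns (zero
#' marginals) are dropped with a warning; expected counts below 5 trigger a
#' warning but not an exact test.
#'
#' @param table A counts matrix.
#' @return A list with `chi2_stat`, `dof`, `p_value`.
#' @export
#' @examples
#' chi2_test(matrix(c(10, 0, 0, 10), 2))  # chi2 = 20, dof = 1
chi2_test <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("`table` must contain non-negative counts")
  }
  empty_r <- rowSums(tab) == 0
  empty_c <- colSums(tab) == 0
  if (any(empty_r) || any(empty_c)) {
    warn("dropping empty row/column categories from contingency table")
    tab <- tab[!empty_r, !empty_c, drop = FALSE]
  }
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    abort("contingency table needs >= 2 non-empty categories per factor")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5)) {
    warn("expected count(s) < 5; asymptotic chi-squared p-value is approximate")
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(chi2_stat = unname(ht$statistic), dof = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Bonferroni screen over factor-pair p-values
#'
#' Flags factor pairs whose uncorrected chi-squared p-value stays significant
#' after Bonferroni adjustment: the per-test level is `overall_alpha /
#' n_pairs` and comparison is strict. With the study design of 7 factors
#' there are choose(7, 2) = 21 pairs and the adjusted level is 0.05 / 21
#' (0.0024 to 2 significant figures).
#'
#' @param p_values Numeric vector of per-pair p-values.
#' @param overall_alpha Family-wise error rate to maintain (default 0.05).
#' @param n_pairs Number of comparisons in the family (default
#'   `length(p_values)`).
#' @return A tibble with `p_value`, `alpha_adjusted`,
#'   `significant_bonferroni`; `n_pairs` and `alpha_adjusted` as attributes.
#' @export
bonferroni_screen <- function(p_values, overall_alpha = 0.05,
                              n_pairs = length(p_values)) {
  if (n_pairs < 1) abort("`n_pairs` must be >= 1")
  alpha_adj <- overall_alpha / n_pairs
  out <- tibble(p_value = p_values, alpha_adjusted = alpha_adj,
                significant_bonferroni = p_values < alpha_adj)
  attr(out, "n_pairs") <- n_pairs
  attr(out, "alpha_adjusted") <- alpha_adj
  out
}

#' Screen all metadata factor pairs for association
#'
#' Runs Pearson's chi-squared test on every pair of categorical metadata
#' factors and applies the Bonferroni screen across the full family of
#' choose(k, 2) pairs. Strong pairwise associations (e.g. gender with sexual
#' status, or breed with weight) warn that a discriminant model for one
#' factor may be confounded by the other.
#'
#' @param metadata A data frame, one row per sample; all columns except
#'   `sample_id` are treated as factors unless `factors` is given.
#' @param factors Character vector of factor columns to screen.
#' @param overall_alpha Family-wise error rate (default 0.05).
#' @return An `association_screen` tibble: `factor_a`, `factor_b`,
#'   `chi2_stat`, `dof`, `p_value`, `alpha_adjusted`,
#'   `significant_bonferroni`.
#' @export
#' @examples
#' md <- generate_metadata(60, list(gender = c("m", "f"),
#'                                  status = c("entire", "neutered")),
#'                         association = list(pair = c("gender", "status"),
#'                                            strength = 1), seed = 3)
#' screen_metadata(md)
screen_metadata <- function(metadata, factors = NULL, overall_alpha = 0.05) {
  factors <- factors %||% setdiff(names(metadata), "sample_id")
  if (length(factors) < 2) abort("need >= 2 factors to screen")
  pairs <- utils::combn(sort(factors), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    ht <- chi2_test(contingency_table(metadata, a, b))
    tibble(factor_a = a, factor_b = b, chi2_stat = ht$chi2_stat,
           dof = ht$dof, p_value = ht$p_value)
  })
  scr <- bonferroni_screen(res$p_value, overall_alpha, ncol(pairs))
  res$alpha_adjusted <- scr$alpha_adjusted
  res$significant_bonferroni <- scr$significant_bonferroni
  attr(res, "n_pairs") <- ncol(pairs)
  attr(res, "alpha_adjusted") <- attr(scr, "alpha_adjusted")
  class(res) <- c("association_screen", class(res))
  res
}

#' @exportS3Method
autoplot.association_screen <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$factor_a, .data$factor_b,
                               fill = -log10(.data$p_value))) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$significant_bonferroni, "*", "")), size = 6) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = expression(-log[10](p))) +
    ggplot2::theme_minimal()
}
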