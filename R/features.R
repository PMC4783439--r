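#' Random-forest permutation importance per bin
#'
#' Importance Score of a feature: the mean decrease in classification
#' accuracy when the feature's information is withheld, estimated by the
#' standard out-of-bag permutation procedure of a random forest (unscaled
#' mean decrease in accuracy). Constant features get importance 0.
#'
#' @inheritParams bootstrap_classify
#' @return A tibble with columns `bin` and `importance`.
#' @export
rf_importance <- function(x, labels, n_trees = 1000, seed = 1) {
  m <- unclass(as.matrix(x))
  labels <- factor(as.character(labels))
  if (nlevels(labels) < 2) abort("at least 2 classes required")
  if (n_trees < 1) abort("`n_trees` must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  rf <- randomForest::randomForest(m, labels, ntree = n_trees,
                                   importance = TRUE)
  imp <- randomForest::importance(rf, type = 1, scale = FALSE)[, 1]
  tibble(bin = bin_ids(m), importance = unname(imp))
}

#' Per-feature discriminatory AUC
#'
#' Rank-based AUC of a single feature's values against a binary class label,
#' folded to `max(auc, 1 - auc)` so the score is direction-free (a feature
#' that is consistently *lower* in the positive class ranks as highly as one
#' that is consistently higher).
#'
#' @param values Numeric feature values, one per sample.
#' @param labels Binary class labels.
#' @param fold Fold to the direction-free value (default `TRUE`).
#' @param positive Positive class; defaults to first sorted label.
#' @return AUC in \[0.5, 1\] when folded.
#' @export
#' @examples
#' feature_auc(c(1, 3, 2, 4), c("a", "a", "b", "b"))  # 0.75
feature_auc <- function(values, labels, fold = TRUE, positive = NULL) {
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2) abort("exactly 2 classes required")
  positive <- positive %||% classes[1]
  a <- rank_auc(values, labels == positive)
  if (fold) max(a, 1 - a) else a
}

#' Student's t-test for one feature
#'
#' Two-sided pooled-variance (Student) t-test between two groups, used for
#' p-value ranking and the p < 0.05 selection gate. When both groups are
#' constant: equal means give (t = 0, p = 1); unequal means give
#' (t = +/-Inf, p = 0). `var_equal = FALSE` switches to the Welch form.
#'
#' @param values_a,values_b Numeric vectors, each of length >= 2.
#' @param var_equal Pooled-variance Student form (default) or Welch.
#' @return A list with `t_stat` and `p_value`.
#' @export
feature_t_test <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    abort("each group needs >= 2 values")
  }
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    if (mean(values_a) == mean(values_b)) {
      return(list(t_stat = 0, p_value = 1))
    }
    return(list(t_stat = sign(mean(values_a) - mean(values_b)) * Inf,
                p_value = 0))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  list(t_stat = unname(ht$statistic), p_value = ht$p.value)
}

#' Ensemble feature ranking
#'
#' Ranks every bin of a two-class fingerprint matrix by three independent
#' criteria -- random-forest Importance Score, direction-free per-feature AUC,
#' and Student's t-test p-value -- and fuses them into a combined rank (mean
#' of the three rank columns). A bin is flagged `selected` when it clears
#' both selection gates: p-value below `p_threshold` and Importance Score
#' above `importance_threshold`.
#'
#' @inheritParams bootstrap_classify
#' @param p_threshold t-test selection gate (default 0.05).
#' @param importance_threshold Importance Score gate (default 0.002). The
#'   scale of permutation importance depends on forest configuration, so the
#'   gate is a tunable, not a portable constant.
#' @param var_equal Passed to [feature_t_test()].
#' @return A `feature_rank_table` tibble: `bin`, `importance`, `feature_auc`,
#'   `t_stat`, `p_value`, `rank_importance`, `rank_auc`, `rank_p`,
#'   `rank_combined`, `selected`.
#' @export
rank_features <- function(x, labels, n_trees = 1000, seed = 1,
                          p_threshold = 0.05, importance_threshold = 0.002,
                          var_equal = TRUE) {
  m <- unclass(as.matrix(x))
  labels <- factor(as.character(labels))
  classes <- sort(levels(labels))
  if (length(classes) != 2) abort("rank_features is a pairwise operation")
  imp <- rf_importance(m, labels, n_trees = n_trees, seed = seed)
  a_idx <- labels == classes[1]
  per_bin <- purrr::map_dfr(seq_len(ncol(m)), function(j) {
    tt <- feature_t_test(m[a_idx, j], m[!a_idx, j], var_equal = var_equal)
    tibble(feature_auc = feature_auc(m[, j], labels),
           t_stat = tt$t_stat, p_value = tt$p_value)
  })
  out <- dplyr::bind_cols(imp, per_bin)
  out <- dplyr::mutate(
    out,
    rank_importance = rank(-.data$importance, ties.method = "first"),
    rank_auc = rank(-.data$feature_auc, ties.method = "first"),
    rank_p = rank(.data$p_value, ties.method = "first"),
    rank_combined = (.data$rank_importance + .data$rank_auc + .data$rank_p) / 3,
    selected = .data$p_value < p_threshold &
      .data$importance > importance_threshold
  )
  out <- dplyr::arrange(out, .data$rank_combined)
  class(out) <- c("feature_rank_table", class(out))
  out
}

#' @exportS3Method
autoplot.feature_rank_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$importance, -log10(.data$p_value),
                               colour = .data$selected)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "Importance Score (mean decrease in accuracy)",
                  y = expression(-log[10](p)), colour = "selected") +
    ggplot2::theme_minimal()
}

#' Correlation clusters of selected signals
#'
#' Groups bins whose intensity profiles are strongly correlated across
#' samples: an edge joins two bins when their Pearson |r| exceeds
#' `threshold`, and clusters are the connected components of the resulting
#' graph. Within a fingerprint, such clusters typically collect different
#' ionization products (Na+/K+ adducts, 13C isotopologues, in-source
#' fragments) of a single metabolite. Components are reported largest first,
#' ties broken by smallest member bin. Constant bins correlate with nothing
#' (r undefined) and end up as singletons, with a warning.
#'
#' @param x A [fingerprint_matrix()] or numeric matrix.
#' @param bins Integer vector of bins to cluster (e.g. the `selected` bins of
#'   [rank_features()]); default all columns.
#' @param threshold Absolute Pearson correlation above which two bins are
#'   linked (default 0.7, strict inequality).
#' @return A list of `feature_cluster` objects, each with `member_bins`
#'   (sorted integer vector) and `pairwise_r` (correlation matrix).
#' @export
correlation_clusters <- function(x, bins = NULL, threshold = 0.7) {
  m <- unclass(as.matrix(x))
  ids <- bin_ids(m)
  if (!is.null(bins)) {
    miss <- setdiff(bins, ids)
    if (length(miss)) {
      abort(sprintf("bin(s) not in matrix: %s", paste(miss, collapse = ", ")))
    }
    m <- m[, match(bins, ids), drop = FALSE]
    ids <- bin_ids(m)
  }
  if (!ncol(m)) abort("no bins to cluster")
  if (threshold <= 0 || threshold >= 1) abort("`threshold` must be in (0, 1)")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warn(sprintf("constant bin(s) have undefined correlations: %s",
                 paste(ids[sds == 0], collapse = ", ")))
  }
  r <- suppressWarnings(stats::cor(m))
  adj <- !is.na(r) & abs(r) > threshold
  diag(adj) <- FALSE
  gr <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(gr)$membership
  groups <- split(seq_along(ids), comp)
  ord <- order(-lengths(groups),
               vapply(groups, function(g) min(ids[g]), numeric(1)))
  lapply(groups[ord], function(g) {
    structure(
      list(member_bins = sort(ids[g]),
           pairwise_r = r[g, g, drop = FALSE]),
      class = "feature_cluster"
    )
  })
}

#' @export
print.feature_cluster <- function(x, ...) {
  cat(sprintf("<feature_cluster> %d bin(s): %s\n", length(x$member_bins),
              paste(x$member_bins, collapse = ", ")))
  invisible(x)
}

# column identifiers as integers when they are nominal masses, else indices
bin_ids <- function(m) {
  cn <- colnames(m)
  if (is.null(cn)) return(seq_len(ncol(m)))
  v <- suppressWarnings(as.numeric(cn))
  if (any(is.na(v))) seq_len(ncol(m)) else v
}
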