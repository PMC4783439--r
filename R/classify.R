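#' Per-sample classification margin from vote fractions
#'
#' The random-forest margin of a test sample is the vote fraction its true
#' class received minus the largest vote fraction any other class received;
#' it ranges from -1 (confidently wrong) to 1 (confidently right).
#'
#' @param votes Numeric matrix of vote fractions, test samples in rows, one
#'   column per class (named).
#' @param true_class Character/factor vector of true class labels, one per
#'   row of `votes`.
#' @return Numeric vector of per-sample margins.
#' @export
#' @examples
#' vote_margin(matrix(c(0.8, 0.2), 1, dimnames = list(NULL, c("A", "B"))), "A")
vote_margin <- function(votes, true_class) {
  votes <- as.matrix(votes)
  true_class <- as.character(true_class)
  if (length(true_class) != nrow(votes)) {
    abort("one true class per row of `votes` is required")
  }
  if (is.null(colnames(votes))) abort("`votes` needs class column names")
  vapply(seq_len(nrow(votes)), function(i) {
    j <- match(true_class[i], colnames(votes))
    if (is.na(j)) abort(sprintf("unknown class '%s'", true_class[i]))
    votes[i, j] - max(votes[i, -j])
  }, numeric(1))
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed from ranks: the probability that a
#' randomly chosen positive-class score exceeds a randomly chosen
#' negative-class score, with ties counted one half.
#'
#' @param scores Numeric scores (higher = more positive-like).
#' @param positive Logical vector, `TRUE` for positive-class observations.
#' @return AUC in \[0, 1\].
#' @export
rank_auc <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) abort("both classes must be present")
  r <- rank(scores)                       # midranks handle ties as 0.5
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# stratified 2/3-1/3 split; test size = ceiling(n_c / 3) per class
split_train_test <- function(labels) {
  test <- unlist(lapply(split(seq_along(labels), labels), function(idx) {
    sample(idx, ceiling(length(idx) / 3))
  }), use.names = FALSE)
  list(train = setdiff(seq_along(labels), test), test = sort(test))
}

#' Bootstrap random-forest classification
#'
#' Assesses pairwise class separation by repeated random-forest modelling:
#' each bootstrap draws a stratified 2/3 training / 1/3 test split, grows a
#' forest of `n_trees` trees on the training set and scores the held-out
#' third. Three robustness statistics are recorded per bootstrap: accuracy
#' (ACC), rank-based AUC of the positive-class vote fractions, and the mean
#' test-sample margin. A model is deemed adequate overall when the aggregate
#' margin exceeds 0.2 and aggregate AUC and/or ACC exceeds 0.8 (see
#' [adequacy()]).
#'
#' A single master seed spawns one sub-seed per bootstrap, so increasing
#' `n_bootstraps` extends the report without reshuffling earlier splits.
#'
#' @param x A [fingerprint_matrix()] or numeric matrix (samples x bins).
#' @param labels Two-class label vector, each class with >= 3 samples.
#' @param n_bootstraps Number of bootstrap rounds (default 100).
#' @param n_trees Trees per forest (default 1000).
#' @param seed Master seed (integer).
#' @param aggregate `"mean"` (default) or `"median"` over bootstraps.
#' @param positive Class treated as positive for AUC; defaults to the first
#'   class in sorted label order.
#' @return A `classification_report`: `comparison`, `n_bootstraps`,
#'   `per_bootstrap` tibble (`bootstrap`, `margin`, `auc`, `acc`),
#'   `aggregate` named vector, `adequate` flag, `seed`.
#' @export
#' @examples
#' sim <- generate_fingerprints(synthetic_design(
#'   n_bins = 40, samples_per_class = 8,
#'   discriminatory_bins = data.frame(bin = 110:114, class = "class2",
#'                                    shift = 1.5),
#'   seed = 7))
#' rep <- bootstrap_classify(preprocess_fingerprints(sim$fingerprints),
#'                           sim$labels, n_bootstraps = 5, n_trees = 50,
#'                           seed = 7)
#' glance(rep)
bootstrap_classify <- function(x, labels, n_bootstraps = 100, n_trees = 1000,
                               seed = 1, aggregate = c("mean", "median"),
                               positive = NULL) {
  aggregate <- match.arg(aggregate)
  m <- unclass(as.matrix(x))
  labels <- factor(as.character(labels))
  counts <- table(labels)
  if (length(counts) != 2) abort("bootstrap_classify is a pairwise comparison: exactly 2 classes required")
  if (any(counts < 3)) {
    abort(sprintf("every class needs >= 3 samples (got %s)",
                  paste(sprintf("%s=%d", names(counts), counts),
                        collapse = ", ")))
  }
  if (n_bootstraps < 1 || n_trees < 1) {
    abort("`n_bootstraps` and `n_trees` must be >= 1")
  }
  classes <- sort(levels(labels))
  positive <- positive %||% classes[1]
  if (!positive %in% classes) abort("`positive` is not one of the class labels")

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, n_bootstraps)

  one <- function(b) {
    set.seed(sub_seeds[b])
    sp <- split_train_test(labels)
    rf <- randomForest::randomForest(
      m[sp$train, , drop = FALSE], labels[sp$train], ntree = n_trees)
    votes <- stats::predict(rf, m[sp$test, , drop = FALSE], type = "vote",
                            norm.votes = TRUE)
    truth <- as.character(labels[sp$test])
    # predicted class = top vote; ties resolved toward the smaller label
    pred <- apply(votes, 1, function(v) {
      top <- colnames(votes)[v == max(v)]
      sort(top)[1]
    })
    c(margin = mean(vote_margin(votes, truth)),
      auc = rank_auc(votes[, positive], truth == positive),
      acc = mean(pred == truth))
  }
  per <- t(vapply(seq_len(n_bootstraps), one, numeric(3)))
  per_bootstrap <- tibble(bootstrap = seq_len(n_bootstraps),
                          margin = per[, "margin"], auc = per[, "auc"],
                          acc = per[, "acc"])
  aggfun <- if (aggregate == "mean") mean else stats::median
  agg <- c(margin = aggfun(per_bootstrap$margin),
           auc = aggfun(per_bootstrap$auc),
           acc = aggfun(per_bootstrap$acc))
  structure(
    list(comparison = classes, n_bootstraps = n_bootstraps,
         per_bootstrap = per_bootstrap, aggregate = agg,
         aggregate_fun = aggregate,
         adequate = adequacy(agg[["margin"]], agg[["auc"]], agg[["acc"]]),
         n_trees = n_trees, positive = positive, seed = seed),
    class = "classification_report"
  )
}

#' Classification adequacy rule
#'
#' A pairwise model is adequate overall when its aggregate random-forest
#' margin exceeds 0.2 and its aggregate AUC and/or ACC exceeds 0.8 (all
#' inequalities strict).
#'
#' @param margin Aggregate margin, or a `classification_report`.
#' @param auc,acc Aggregate AUC and accuracy (ignored when `margin` is a
#'   report).
#' @return Logical.
#' @export
#' @examples
#' adequacy(0.49, auc = 0.98, acc = 0.89)  # TRUE
#' adequacy(0.13, auc = 0.90, acc = 0.69)  # FALSE
adequacy <- function(margin, auc = NULL, acc = NULL) {
  if (inherits(margin, "classification_report")) {
    a <- margin$aggregate
    return(adequacy(a[["margin"]], a[["auc"]], a[["acc"]]))
  }
  stopifnot(is.numeric(margin), is.numeric(auc), is.numeric(acc))
  unname(margin > 0.2 & (auc > 0.8 | acc > 0.8))
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> %s vs %s, %d bootstraps x %d trees\n",
              x$comparison[1], x$comparison[2], x$n_bootstraps, x$n_trees))
  cat(sprintf("  %s margin %.3f, AUC %.3f, ACC %.3f -> %s\n",
              x$aggregate_fun, x$aggregate["margin"], x$aggregate["auc"],
              x$aggregate["acc"],
              if (x$adequate) "adequate" else "not adequate"))
  invisible(x)
}

#' @exportS3Method
tidy.classification_report <- function(x, ...) x$per_bootstrap

#' @exportS3Method
glance.classification_report <- function(x, ...) {
  tibble(
    comparison = paste(x$comparison, collapse = " vs "),
    n_bootstraps = x$n_bootstraps,
    n_trees = x$n_trees,
    margin = x$aggregate[["margin"]],
    auc = x$aggregate[["auc"]],
    acc = x$aggregate[["acc"]],
    adequate = x$adequate
  )
}

#' @exportS3Method
autoplot.classification_report <- function(object, ...) {
  d <- tidyr::pivot_longer(object$per_bootstrap, c("margin", "auc", "acc"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$metric, .data$value)) +
    ggplot2::geom_boxplot(outlier.size = 0.7) +
    ggplot2::geom_hline(yintercept = c(0.2, 0.8), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(
      title = paste(object$comparison, collapse = " vs "),
      y = "per-bootstrap value", x = NULL
    ) +
    ggplot2::theme_minimal()
}

# save/restore the global RNG state so seeded fits don't perturb callers
.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
}
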