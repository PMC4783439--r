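#' Principal component reduction of a fingerprint matrix
#'
#' Column-centres the matrix and projects onto its principal components,
#' retaining the smallest number of components whose cumulative explained
#' variance reaches `variance_target`. Each component is oriented so that its
#' largest-magnitude loading is positive, making scores reproducible across
#' platforms.
#'
#' @param x A [fingerprint_matrix()] or numeric matrix (samples in rows).
#' @param variance_target Cumulative explained-variance fraction to retain,
#'   in (0, 1]; default 0.95.
#' @param max_pcs Optional hard cap on the number of retained components.
#' @return A list with `scores` (samples x PCs), `explained` (variance
#'   fraction per retained PC), `rotation`, and `center`.
#' @export
pca_reduce <- function(x, variance_target = 0.95, max_pcs = NULL) {
  m <- unclass(as.matrix(x))
  if (nrow(m) < 2) abort("PCA needs at least 2 samples")
  if (!is.numeric(variance_target) || variance_target <= 0 ||
      variance_target > 1) {
    abort("`variance_target` must lie in (0, 1]")
  }
  p <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2
  keep <- ev > max(ev) * 1e-12            # drop numerically null components
  ev <- ev[keep]
  frac <- ev / sum(ev)
  k <- which(cumsum(frac) >= variance_target - 1e-12)[1]
  if (is.na(k)) k <- length(frac)
  if (!is.null(max_pcs)) k <- min(k, max_pcs)
  k <- max(k, 1L)
  rot <- p$rotation[, seq_len(k), drop = FALSE]
  scores <- p$x[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(scores = scores, explained = frac[seq_len(k)], rotation = rot,
       center = p$center)
}

#' PC-LDA: linear discriminant analysis on principal-component scores
#'
#' Fits linear discriminant axes to PCA-reduced fingerprint data, the standard
#' route for p >> n spectral matrices. Discriminant functions (DFs) are the
#' generalized eigenvectors of the between-class scatter against the
#' within-class scatter of the retained PC scores; each DF's eigenvalue (Tw)
#' is its between-to-within scatter ratio and is the model-adequacy metric:
#' models are called adequate at Tw > 2 and poor at Tw < 1 (see
#' [tw_adequacy()]).
#'
#' The number of retained PCs is capped at (n samples - n classes) so the
#' within-class scatter stays invertible; a tiny ridge (1e-8 x trace) is added
#' when it is singular anyway, with a warning.
#'
#' @inheritParams pca_reduce
#' @param labels Per-sample class labels (factor or character), length
#'   `nrow(x)`. Every class needs at least 2 samples.
#' @return An object of class `pc_lda`: list with `df_scores` (samples x DFs),
#'   `tw` (eigenvalue per DF, non-increasing), `n_pcs_retained`,
#'   `explained_variance`, `class_labels`, and `scaling` (PC-space DF
#'   loadings).
#' @export
#' @examples
#' sim <- generate_fingerprints(synthetic_design(seed = 1))
#' fit <- pc_lda(preprocess_fingerprints(sim$fingerprints), sim$labels)
#' glance(fit)
pc_lda <- function(x, labels, variance_target = 0.95) {
  m <- unclass(as.matrix(x))
  labels <- factor(labels)
  if (length(labels) != nrow(m)) abort("one label per sample is required")
  counts <- table(labels)
  if (length(counts) < 2) abort("PC-LDA needs at least 2 classes")
  if (any(counts < 2)) {
    abort(sprintf(
      "class(es) with a single sample give singular within-class scatter: %s",
      paste(names(counts)[counts < 2], collapse = ", ")))
  }
  g <- length(counts)
  red <- pca_reduce(m, variance_target, max_pcs = nrow(m) - g)
  S <- red$scores
  k <- ncol(S)

  grand <- colMeans(S)
  W <- matrix(0, k, k)
  B <- matrix(0, k, k)
  for (cl in names(counts)) {
    Sc <- S[labels == cl, , drop = FALSE]
    mu <- colMeans(Sc)
    Wc <- crossprod(sweep(Sc, 2, mu))
    W <- W + Wc
    B <- B + nrow(Sc) * tcrossprod(mu - grand)
  }

  # solve B v = tw W v via W^{-1/2}; ridge only if W is singular
  eW <- eigen(W, symmetric = TRUE)
  if (min(eW$values) <= sum(diag(W)) * 1e-12) {
    warn("within-class scatter is singular; adding ridge 1e-8 x trace")
    W <- W + diag(1e-8 * sum(diag(W)), k)
    eW <- eigen(W, symmetric = TRUE)
  }
  Wihalf <- eW$vectors %*% (t(eW$vectors) / sqrt(eW$values))
  M <- t(Wihalf) %*% B %*% Wihalf
  eM <- eigen((M + t(M)) / 2, symmetric = TRUE)
  n_df <- min(g - 1L, k)
  tw <- pmax(eM$values[seq_len(n_df)], 0)
  V <- Wihalf %*% eM$vectors[, seq_len(n_df), drop = FALSE]
  for (j in seq_len(n_df)) {            # reproducible axis orientation
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  scores <- S %*% V
  colnames(scores) <- paste0("DF", seq_len(n_df))
  rownames(scores) <- rownames(m)

  structure(
    list(df_scores = scores, tw = tw, n_pcs_retained = k,
         explained_variance = red$explained, class_labels = labels,
         scaling = V),
    class = "pc_lda"
  )
}

#' Eigenvalue adequacy call
#'
#' Classifies a discriminant-function eigenvalue (Tw, the between- to
#' within-class scatter ratio): discrimination is adequate above 2.0, poor
#' below 1.0, intermediate otherwise (boundaries excluded on both sides).
#'
#' @param tw Non-negative eigenvalue(s).
#' @return Character vector: `"adequate"`, `"intermediate"` or `"poor"`.
#' @export
#' @examples
#' tw_adequacy(c(2.79, 2.0, 0.5))
tw_adequacy <- function(tw) {
  if (!is.numeric(tw) || any(is.na(tw)) || any(tw < 0)) {
    abort("`tw` must be non-negative")
  }
  out <- rep("intermediate", length(tw))
  out[tw > 2] <- "adequate"
  out[tw < 1] <- "poor"
  out
}

#' @export
print.pc_lda <- function(x, ...) {
  cat(sprintf("<pc_lda> %d samples, %d classes, %d PCs retained\n",
              nrow(x$df_scores), nlevels(x$class_labels), x$n_pcs_retained))
  cat(sprintf("  Tw: %s\n",
              paste(sprintf("%.3g (%s)", x$tw, tw_adequacy(x$tw)),
                    collapse = ", ")))
  invisible(x)
}

#' @exportS3Method
tidy.pc_lda <- function(x, ...) {
  dplyr::bind_cols(
    tibble(sample_id = rownames(x$df_scores),
           class = as.character(x$class_labels)),
    as_tibble(x$df_scores)
  )
}

#' @exportS3Method
glance.pc_lda <- function(x, ...) {
  tibble(
    n_samples = nrow(x$df_scores),
    n_classes = nlevels(x$class_labels),
    n_pcs_retained = x$n_pcs_retained,
    tw1 = x$tw[1],
    tw2 = if (length(x$tw) >= 2) x$tw[2] else NA_real_,
    adequacy = tw_adequacy(x$tw[1])
  )
}

#' @exportS3Method
autoplot.pc_lda <- function(object, ...) {
  d <- tidy(object)
  if (!"DF2" %in% names(d)) d$DF2 <- 0
  ggplot2::ggplot(d, ggplot2::aes(.data$DF1, .data$DF2,
                                  colour = .data$class)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("DF1 (Tw %.2f)", object$tw[1]),
      y = if (length(object$tw) >= 2)
        sprintf("DF2 (Tw %.2f)", object$tw[2]) else "DF2",
      colour = "class"
    ) +
    ggplot2::theme_minimal()
}
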