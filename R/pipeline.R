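#' Analysis run configuration
#'
#' Bundles every stage parameter of the end-to-end workflow with its standard
#' default: 0.1 Da binning tolerance, 5th-percentile baseline, log10-then-TIC
#' transform order, 95% PCA variance target, 100 bootstraps of 1000-tree
#' forests, |r| > 0.7 correlation clustering, overall alpha 0.05, 5 ppm
#' annotation tolerance, and the p < 0.05 / Importance Score > 0.002
#' selection gates. Configs round-trip losslessly through YAML via
#' [read_run_config()] / [write_run_config()].
#'
#' @param ... Named overrides of the defaults listed above.
#' @return A `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(
    tolerance = 0.1,
    baseline_quantile = 0.05,
    transform_order = "log-tic",
    variance_target = 0.95,
    n_bootstraps = 100,
    n_trees = 1000,
    r_threshold = 0.7,
    alpha = 0.05,
    tol_ppm = 5,
    p_threshold = 0.05,
    importance_threshold = 0.002,
    label_factor = "breed",
    classes = NULL,
    seed = 1
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown config field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config[!vapply(config, is.null, logical(1))], path)
  invisible(path)
}

#' Run the end-to-end breed analysis
#'
#' Orchestrates the full workflow on a fingerprint matrix and its sample
#' metadata: pre-processing (baseline, log10, TIC), chi-squared metadata
#' association screening, a PC-LDA model per metadata factor (factors with
#' any single-sample class are skipped with a warning), bootstrap
#' random-forest classification of every pairwise class comparison of the
#' designated label factor, ensemble feature ranking for the best-separated
#' (or requested) pair, correlation clustering of the selected bins, and
#' nominal-mass cluster interpretation. All stage randomness derives from
#' `config$seed`, so reruns with the same inputs are identical.
#'
#' @param fingerprints A binned or pre-processed [fingerprint_matrix()].
#' @param metadata A data frame with `sample_id` plus factor columns, rows
#'   matching the fingerprint samples.
#' @param config A [run_config()].
#' @return A `run_report` list: `config`, `provenance`, `metadata_screen`,
#'   `lda` (per-factor glance rows), `classification` (one glance row per
#'   pairwise comparison), `feature_ranks`, `clusters`,
#'   `cluster_interpretation`.
#' @export
run_breed_analysis <- function(fingerprints, metadata, config = run_config()) {
  stopifnot(inherits(fingerprints, "fingerprint_matrix"),
            inherits(config, "run_config"))
  metadata <- as_tibble(metadata)
  if (!"sample_id" %in% names(metadata)) abort("metadata needs a sample_id column")
  idx <- match(fp_samples(fingerprints), metadata$sample_id)
  if (anyNA(idx)) {
    abort(sprintf("stage metadata: no metadata for sample(s) %s",
                  paste(fp_samples(fingerprints)[is.na(idx)], collapse = ", ")))
  }
  metadata <- metadata[idx, ]
  factors <- setdiff(names(metadata), "sample_id")
  if (!config$label_factor %in% factors) {
    abort(sprintf("stage classify: label factor '%s' not in metadata",
                  config$label_factor))
  }

  if (!"tic_normalized" %in% fp_state(fingerprints)) {
    fingerprints <- preprocess_fingerprints(
      fingerprints, baseline_quantile = config$baseline_quantile,
      order = config$transform_order)
  }

  screen <- if (length(factors) >= 2) {
    screen_metadata(metadata, factors, config$alpha)
  } else NULL

  lda_rows <- purrr::map_dfr(factors, function(f) {
    labs <- metadata[[f]]
    if (any(table(labs) < 2) || length(unique(labs)) < 2) {
      warn(sprintf("skipping PC-LDA for factor '%s' (singleton or single class)", f))
      return(tibble())
    }
    dplyr::bind_cols(tibble(factor = f),
                     glance(pc_lda(fingerprints, labs,
                                   config$variance_target)))
  })

  labs <- as.character(metadata[[config$label_factor]])
  classes <- sort(unique(labs))
  usable <- classes[table(factor(labs, classes)) >= 3]
  pairs <- utils::combn(usable, 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  pair_seeds <- sample.int(.Machine$integer.max, ncol(pairs) + 1)
  cls_rows <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    sel <- labs %in% pairs[, i]
    rep <- bootstrap_classify(
      unclass(fingerprints)[sel, , drop = FALSE], labs[sel],
      n_bootstraps = config$n_bootstraps, n_trees = config$n_trees,
      seed = pair_seeds[i])
    glance(rep)
  })

  target <- config$classes %||%
    pairs[, which.max(cls_rows$margin)]
  sel <- labs %in% target
  ranks <- rank_features(
    unclass(fingerprints)[sel, , drop = FALSE], labs[sel],
    n_trees = config$n_trees, seed = pair_seeds[length(pair_seeds)],
    p_threshold = config$p_threshold,
    importance_threshold = config$importance_threshold)

  sel_bins <- ranks$bin[ranks$selected]
  clusters <- if (length(sel_bins) >= 1) {
    correlation_clusters(fingerprints, bins = sel_bins,
                         threshold = config$r_threshold)
  } else list()
  interp <- purrr::imap_dfr(clusters, function(cl, i) {
    rel <- interpret_cluster(cl)
    if (nrow(rel)) dplyr::bind_cols(tibble(cluster = i), rel) else tibble()
  })

  report <- list(
    config = unclass(config),
    provenance = list(
      package_version = as.character(utils::packageVersion("fiefin")),
      config_hash = rlang::hash(unclass(config)),
      seed = config$seed
    ),
    metadata_screen = screen,
    lda = lda_rows,
    classification = cls_rows,
    ranked_comparison = target,
    feature_ranks = ranks,
    clusters = lapply(clusters, `[[`, "member_bins"),
    cluster_interpretation = interp
  )
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  %d pairwise comparison(s), %d adequate\n",
              nrow(x$classification), sum(x$classification$adequate)))
  cat(sprintf("  %d selected bin(s) in %d cluster(s)\n",
              sum(x$feature_ranks$selected), length(x$clusters)))
  invisible(x)
}

#' Serialize a run report to JSON
#'
#' Timestamp-free JSON so identical configs and seeds rerun byte-identically.
#'
#' @param report A `run_report`.
#' @param path Output file.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
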