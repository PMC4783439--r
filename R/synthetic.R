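#' Synthetic fingerprint experiment design
#'
#' Describes a simulated multi-class FIE-MS fingerprint experiment with the
#' statistical structure the analysis assumes: per-bin log-normal baseline
#' intensities, class-specific log10 shifts on designated discriminatory
#' bins, correlated adduct/isotopologue bin clusters tied to an anchor bin,
#' per-sample total-ion-current scale factors, and multiplicative (log-normal)
#' measurement noise. Optional replicate structure reuses an individual-level
#' latent profile plus within-individual noise, emulating repeat sampling of
#' the same dog.
#'
#' Defaults mirror a two-breed controlled comparison: 2 classes of 12 samples
#' on a 250-bin fingerprint with moderate biological noise (0.2 on the log10
#' scale) and up to four-fold TIC variation between samples.
#'
#' @param n_classes Number of classes (default 2).
#' @param samples_per_class Individuals per class (default 12).
#' @param n_bins Approximate number of nominal-mass bins, spread over
#'   15-1200 m/z (planted bins are always included; default 250).
#' @param discriminatory_bins Data frame with columns `bin`, `class`
#'   (`"class1"`, `"class2"`, ...) and `shift` (log10-scale intensity shift
#'   added to that class), or `NULL` for a null design.
#' @param adduct_clusters List of `list(anchor =, offsets =, scales =)`
#'   entries; each offset bin (anchor + offset, offsets drawn from +1 / +16)
#'   is generated as `scale` times the anchor intensity plus tiny log-normal
#'   noise, so pre-noise pairwise correlations exceed 0.9.
#' @param tic_scale_range Multiplicative per-sample scale interval (uniform
#'   on the log scale; default 0.5-2).
#' @param noise_sd Between-individual SD on the log10 scale (default 0.2).
#' @param replicate_sd Within-individual SD on the log10 scale for replicate
#'   designs (default 0).
#' @param n_replicates Repeated samples per individual (default 1).
#' @param seed Integer seed; generators are pure functions of
#'   (design, seed).
#' @return A `synthetic_design` list.
#' @export
synthetic_design <- function(n_classes = 2, samples_per_class = 12,
                             n_bins = 250, discriminatory_bins = NULL,
                             adduct_clusters = list(),
                             tic_scale_range = c(0.5, 2), noise_sd = 0.2,
                             replicate_sd = 0, n_replicates = 1, seed = 1) {
  if (n_classes < 1 || samples_per_class < 1 || n_bins < 1) {
    abort("counts must be positive")
  }
  if (noise_sd < 0 || replicate_sd < 0) abort("noise SDs must be >= 0")
  if (any(tic_scale_range <= 0) || tic_scale_range[1] > tic_scale_range[2]) {
    abort("`tic_scale_range` must be a positive increasing interval")
  }
  if (!is.null(discriminatory_bins)) {
    discriminatory_bins <- as_tibble(discriminatory_bins)
    stopifnot(all(c("bin", "class", "shift") %in% names(discriminatory_bins)))
    bad <- !discriminatory_bins$class %in% paste0("class", seq_len(n_classes))
    if (any(bad)) abort("discriminatory_bins$class must name class1..classK")
  }
  cluster_bins <- unlist(lapply(adduct_clusters, function(cl) {
    stopifnot(all(c("anchor", "offsets", "scales") %in% names(cl)),
              length(cl$offsets) == length(cl$scales))
    c(cl$anchor, cl$anchor + cl$offsets)
  }))
  planted <- c(discriminatory_bins$bin, cluster_bins)
  if (anyDuplicated(planted)) {
    abort("planted bins overlap across discriminatory/cluster roles")
  }
  if (length(planted) && (any(planted < 15) || any(planted > 1200))) {
    abort("planted bins must lie within 15..1200")
  }
  structure(
    list(n_classes = n_classes, samples_per_class = samples_per_class,
         n_bins = n_bins, discriminatory_bins = discriminatory_bins,
         adduct_clusters = adduct_clusters,
         tic_scale_range = tic_scale_range, noise_sd = noise_sd,
         replicate_sd = replicate_sd, n_replicates = n_replicates,
         seed = seed),
    class = "synthetic_design"
  )
}

#' Generate a synthetic fingerprint matrix
#'
#' Draws a raw (binned, pre-normalization) fingerprint matrix from a
#' [synthetic_design()], together with true class labels and a truth record
#' of every planted structure, so downstream recovery can be verified.
#'
#' @param design A [synthetic_design()].
#' @param seed Overrides `design$seed` when given.
#' @return A list: `fingerprints` (binned [fingerprint_matrix()]), `labels`
#'   (factor, one per row, replicates share their individual's class),
#'   `individual` (factor of individual ids), `truth` (planted bins,
#'   clusters, design).
#' @export
#' @examples
#' sim <- generate_fingerprints(synthetic_design(seed = 42))
#' dim(sim$fingerprints)
generate_fingerprints <- function(design, seed = NULL) {
  stopifnot(inherits(design, "synthetic_design"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed %||% design$seed)

  planted <- c(design$discriminatory_bins$bin,
               unlist(lapply(design$adduct_clusters, function(cl) {
                 c(cl$anchor, cl$anchor + cl$offsets)
               })))
  bins <- sort(unique(c(round(seq(15, 1200, length.out = design$n_bins)),
                        planted)))
  p <- length(bins)
  n_ind <- design$n_classes * design$samples_per_class
  cls <- factor(rep(paste0("class", seq_len(design$n_classes)),
                    each = design$samples_per_class))

  mu <- runif(p, min = 3, max = 5)          # log10 baseline abundance per bin
  # cluster anchors emulate abundant metabolites so their lower-intensity
  # adduct/isotope satellites stay above the baseline correction
  for (cl in design$adduct_clusters) {
    mu[match(cl$anchor, bins)] <- runif(1, 4.5, 5)
  }
  shift <- matrix(0, n_ind, p)
  if (!is.null(design$discriminatory_bins)) {
    for (i in seq_len(nrow(design$discriminatory_bins))) {
      db <- design$discriminatory_bins[i, ]
      shift[cls == db$class, match(db$bin, bins)] <- db$shift
    }
  }

  # individual-level latent profiles (log10 scale)
  latent <- sweep(shift, 2, mu, `+`) +
    matrix(rnorm(n_ind * p, sd = design$noise_sd), n_ind, p)

  # replicate expansion
  r <- design$n_replicates
  L <- latent[rep(seq_len(n_ind), each = r), , drop = FALSE] +
    matrix(rnorm(n_ind * r * p, sd = design$replicate_sd), n_ind * r, p)
  labels <- cls[rep(seq_len(n_ind), each = r)]
  individual <- factor(rep(sprintf("ind%03d", seq_len(n_ind)), each = r))

  # adduct/isotopologue clusters: members are fixed multiples of the anchor
  for (cl in design$adduct_clusters) {
    ai <- match(cl$anchor, bins)
    for (k in seq_along(cl$offsets)) {
      mi <- match(cl$anchor + cl$offsets[k], bins)
      L[, mi] <- L[, ai] + log10(cl$scales[k]) +
        rnorm(nrow(L), sd = 0.01)
    }
  }

  X <- 10^L
  tic <- 10^runif(nrow(X), log10(design$tic_scale_range[1]),
                  log10(design$tic_scale_range[2]))
  X <- X * tic
  rownames(X) <- if (r > 1) {
    sprintf("%s_r%d", individual, rep(seq_len(r), times = n_ind))
  } else sprintf("s%03d", seq_len(n_ind))
  colnames(X) <- bins

  truth <- list(
    discriminatory_bins = design$discriminatory_bins,
    clusters = lapply(design$adduct_clusters, function(cl) {
      sort(c(cl$anchor, cl$anchor + cl$offsets))
    }),
    tic_factors = tic, design = design
  )
  list(fingerprints = fingerprint_matrix(X, "positive", "binned"),
       labels = labels, individual = individual, truth = truth)
}

#' Emit synthetic peak lists from a fingerprint matrix
#'
#' Converts each sample row into a centroided peak list: every nonzero bin
#' becomes one peak at the integer m/z plus Gaussian jitter truncated to
#' +/-0.1 Da, so [bin_peaks()] at the default tolerance recovers the matrix
#' exactly (intensity-conserving round trip).
#'
#' @param fingerprints A binned [fingerprint_matrix()].
#' @param jitter_sd SD of the m/z jitter in Daltons; must be < 0.1.
#' @param seed Integer seed.
#' @return A list of [peak_spectrum()] objects, one per sample.
#' @export
generate_peaklists <- function(fingerprints, jitter_sd = 0.03, seed = 1) {
  stopifnot(inherits(fingerprints, "fingerprint_matrix"))
  if (jitter_sd >= 0.1) {
    abort("`jitter_sd` must be < 0.1 so all peaks stay within the bin window")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  bins <- fp_bins(fingerprints)
  rng <- c(min(bins) - 0.2, max(bins) + 0.2)
  lapply(fp_samples(fingerprints), function(id) {
    v <- unclass(fingerprints)[id, ]
    nz <- which(v > 0)
    jitter <- if (jitter_sd > 0) {
      pmin(pmax(rnorm(length(nz), sd = jitter_sd), -0.1), 0.1)
    } else 0
    peak_spectrum(
      tibble(mz = bins[nz] + jitter, intensity = unname(v[nz])),
      id, fp_mode(fingerprints), rng)
  })
}

#' Category sets of the seven study metadata factors
#'
#' The categorical factors used to classify plasma samples in a client-owned
#' dog cohort: breed (9 breeds), age category (months), gender, sexual status
#' within gender, weight category (kg), body condition score and diet group
#' (9 groups).
#'
#' @return Named list of category vectors.
#' @export
dog_factor_specs <- function() {
  list(
    breed = c("Be", "Ch", "CS", "Da", "GR", "Gh", "GS", "LR", "Ma"),
    age_category = c("10-24", "25-48", "49-72", "73+"),
    gender = c("male", "female"),
    sexual_status = c("entire", "neutered"),
    weight_category = c("<10", "10-<20", "20-<30", ">=30"),
    body_condition_score = c("2", "2.5", "3", "3.5", "4+"),
    diet_group = paste0("diet", 1:9)
  )
}

#' Generate a synthetic metadata table
#'
#' Draws categorical factors independently and uniformly, except for one
#' designated factor pair generated with controllable dependence: with
#' probability `strength` the second factor copies the first factor's
#' category index (wrapped to its own category count), otherwise it is drawn
#' independently. `strength = 1` yields a deterministic mapping (saturated
#' chi-squared association); `strength = 0` is full independence.
#'
#' @param n_samples Number of samples.
#' @param factor_specs Named list of category vectors (default
#'   [dog_factor_specs()]).
#' @param association `NULL`, or `list(pair = c(name_a, name_b), strength =
#'   s)` with `s` in \[0, 1\].
#' @param seed Integer seed.
#' @return A tibble with `sample_id` and one column per factor.
#' @export
generate_metadata <- function(n_samples, factor_specs = dog_factor_specs(),
                              association = NULL, seed = 1) {
  if (any(lengths(factor_specs) < 2)) {
    abort("every factor needs >= 2 categories")
  }
  if (!is.null(association)) {
    stopifnot(all(c("pair", "strength") %in% names(association)))
    if (association$strength < 0 || association$strength > 1) {
      abort("association strength must lie in [0, 1]")
    }
    if (!all(association$pair %in% names(factor_specs))) {
      abort("association pair must name two factors in `factor_specs`")
    }
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  idx <- lapply(factor_specs, function(cats) {
    sample.int(length(cats), n_samples, replace = TRUE)
  })
  if (!is.null(association)) {
    a <- association$pair[1]; b <- association$pair[2]
    copy <- runif(n_samples) < association$strength
    nb <- length(factor_specs[[b]])
    idx[[b]][copy] <- ((idx[[a]][copy] - 1L) %% nb) + 1L
  }
  out <- tibble(sample_id = sprintf("s%03d", seq_len(n_samples)))
  for (f in names(factor_specs)) out[[f]] <- factor_specs[[f]][idx[[f]]]
  out
}
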