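#' Centroided peak spectrum
#'
#' Container for one sample's centroided peak list in one ionization mode.
#' FIE-MS acquires one composite spectrum per sample (no chromatographic
#' separation); the peak list is assumed to be the apex-averaged centroid
#' output of upstream processing.
#'
#' @param peaks A data frame with numeric columns `mz` (Daltons) and
#'   `intensity` (arbitrary ion counts, non-negative).
#' @param sample_id Sample identifier.
#' @param mode Ionization mode, `"positive"` or `"negative"`.
#' @param scan_range Numeric length-2 vector, the m/z interval covered by the
#'   acquisition.
#' @return An object of class `peak_spectrum`.
#' @export
#' @examples
#' sp <- peak_spectrum(data.frame(mz = 100.05, intensity = 10), "s1")
#' bin_peaks(sp)[["100"]]
peak_spectrum <- function(peaks, sample_id, mode = c("positive", "negative"),
                          scan_range = c(15, 1200)) {
  mode <- match.arg(mode)
  peaks <- as_tibble(peaks)
  if (!all(c("mz", "intensity") %in% names(peaks))) {
    abort("`peaks` must have columns `mz` and `intensity`")
  }
  if (nrow(peaks) > 0) {
    if (any(!is.finite(peaks$mz)) || any(!is.finite(peaks$intensity))) {
      abort("peak m/z and intensity must be finite")
    }
    if (any(peaks$intensity < 0)) {
      abort(sprintf("negative peak intensity in sample '%s'", sample_id))
    }
    out <- peaks$mz < scan_range[1] | peaks$mz > scan_range[2]
    if (any(out)) {
      abort(sprintf("%d peak(s) outside scan range [%g, %g] in sample '%s'",
                    sum(out), scan_range[1], scan_range[2], sample_id))
    }
  }
  structure(
    list(sample_id = as.character(sample_id), mode = mode,
         scan_range = as.numeric(scan_range), peaks = peaks),
    class = "peak_spectrum"
  )
}

#' @export
print.peak_spectrum <- function(x, ...) {
  cat(sprintf("<peak_spectrum> sample '%s', %s mode, %d peaks, m/z %g-%g\n",
              x$sample_id, x$mode, nrow(x$peaks),
              x$scan_range[1], x$scan_range[2]))
  invisible(x)
}

#' Scan-range scheme
#'
#' The acquisition splits the mass range into overlapping scan windows; the
#' default mirrors the four-window design 15-110, 100-220, 210-510 and
#' 500-1200 m/z. Ranges are treated as closed integer intervals when building
#' the nominal-mass bin axis, so the default union covers bins 15..1200 with
#' overlap regions 100-110, 210-220 and 500-510.
#'
#' @param ranges A list of numeric length-2 vectors, sorted by lower bound.
#' @return An object of class `scan_scheme`.
#' @export
scan_scheme <- function(ranges = list(c(15, 110), c(100, 220),
                                      c(210, 510), c(500, 1200))) {
  if (!length(ranges)) abort("at least one scan range is required")
  lo <- vapply(ranges, `[`, numeric(1), 1)
  hi <- vapply(ranges, `[`, numeric(1), 2)
  if (any(lo >= hi)) abort("each scan range needs lower bound < upper bound")
  if (is.unsorted(lo)) abort("scan ranges must be sorted by lower bound")
  structure(list(ranges = ranges), class = "scan_scheme")
}

#' Bin peaks to integer nominal masses
#'
#' Assigns each peak to its nearest integer m/z bin provided the peak lies
#' within `tolerance` Daltons of that integer; peaks with fractional part in
#' the open interval (tolerance, 1 - tolerance) are discarded (their count is
#' reported in the `"n_discarded"` attribute). Intensities of co-binned peaks
#' are summed, so total accepted intensity is conserved exactly.
#'
#' @param spectrum A [peak_spectrum()].
#' @param tolerance Half-width of the acceptance window in Daltons
#'   (default 0.1). Must lie in (0, 0.5): at 0.5 and beyond every assignment
#'   would be ambiguous.
#' @return A named numeric vector over every integer bin inside the spectrum's
#'   scan range, with attribute `n_discarded`.
#' @export
bin_peaks <- function(spectrum, tolerance = 0.1) {
  stopifnot(inherits(spectrum, "peak_spectrum"))
  if (!is.numeric(tolerance) || length(tolerance) != 1 || tolerance <= 0) {
    abort("`tolerance` must be a positive number")
  }
  if (tolerance >= 0.5) {
    abort("`tolerance` >= 0.5 makes bin assignment ambiguous")
  }
  bins <- seq.int(ceiling(spectrum$scan_range[1]),
                  floor(spectrum$scan_range[2]))
  out <- numeric(length(bins))
  names(out) <- bins
  n_discarded <- 0L
  if (nrow(spectrum$peaks) > 0) {
    mz <- spectrum$peaks$mz
    nearest <- round(mz)
    # absorb the representation error of mz itself at the window boundary
    # (e.g. 700.1 - 700 exceeds 0.1 by ~2e-14 in binary)
    eps <- 4 * .Machine$double.eps * pmax(abs(mz), 1)
    ok <- abs(mz - nearest) <= tolerance + eps & nearest >= bins[1] &
      nearest <= bins[length(bins)]
    n_discarded <- sum(!ok)
    if (any(ok)) {
      acc <- tapply(spectrum$peaks$intensity[ok], nearest[ok], sum)
      out[names(acc)] <- as.numeric(acc)
    }
  }
  attr(out, "n_discarded") <- n_discarded
  out
}

#' Merge per-range bin vectors onto one nominal-mass axis
#'
#' Bins covered by a single scan range are copied through; bins inside an
#' overlap region take the mean of the contributing ranges' values.
#'
#' @param per_range_vectors A list of named bin vectors as returned by
#'   [bin_peaks()], one per scan range of `scheme`, in scheme order.
#' @param scheme A [scan_scheme()].
#' @return A named numeric vector over the union of all integer bins.
#' @export
merge_scan_ranges <- function(per_range_vectors, scheme = scan_scheme()) {
  stopifnot(inherits(scheme, "scan_scheme"))
  if (length(per_range_vectors) != length(scheme$ranges)) {
    abort(sprintf("expected %d bin vectors (one per scan range), got %d",
                  length(scheme$ranges), length(per_range_vectors)))
  }
  axes <- lapply(scheme$ranges, function(r) {
    seq.int(ceiling(r[1]), floor(r[2]))
  })
  for (i in seq_along(axes)) {
    if (length(per_range_vectors[[i]]) != length(axes[[i]])) {
      abort(sprintf(
        "bin vector %d has length %d but its scan range covers %d bins",
        i, length(per_range_vectors[[i]]), length(axes[[i]])))
    }
  }
  all_bins <- sort(unique(unlist(axes)))
  total <- numeric(length(all_bins))
  nhit <- integer(length(all_bins))
  names(total) <- all_bins
  for (i in seq_along(axes)) {
    idx <- match(axes[[i]], all_bins)
    total[idx] <- total[idx] + as.numeric(per_range_vectors[[i]])
    nhit[idx] <- nhit[idx] + 1L
  }
  total / nhit
}

#' Fingerprint matrix
#'
#' A samples x integer-m/z-bins intensity matrix for one ionization mode, with
#' processing-state flags. Positive- and negative-mode data are always kept as
#' separate matrices. State flags record which pre-processing steps have been
#' applied (`binned`, `baseline_subtracted`, `log_transformed`,
#' `tic_normalized`) and gate the legal ordering of the steps.
#'
#' @param values Numeric matrix, samples in rows. Row names are sample ids;
#'   column names are integer nominal masses (strictly increasing).
#' @param mode Ionization mode.
#' @param state Character vector of processing flags already applied.
#' @return An object of class `fingerprint_matrix` (a numeric matrix with
#'   `mode` and `state` attributes).
#' @export
fingerprint_matrix <- function(values, mode = c("positive", "negative"),
                               state = "binned") {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || anyDuplicated(rownames(values))) {
    abort("`values` needs unique row names (sample ids)")
  }
  bins <- suppressWarnings(as.numeric(colnames(values)))
  if (is.null(colnames(values)) || any(is.na(bins)) ||
      any(bins != round(bins)) || is.unsorted(bins, strictly = TRUE)) {
    abort("column names must be strictly increasing integer nominal masses")
  }
  if (any(!is.finite(values))) abort("fingerprint values must be finite")
  known <- c("binned", "baseline_subtracted", "log_transformed",
             "tic_normalized")
  if (!all(state %in% known)) {
    abort(sprintf("unknown state flag(s): %s",
                  paste(setdiff(state, known), collapse = ", ")))
  }
  structure(values, mode = mode, state = unique(state),
            class = c("fingerprint_matrix", "matrix", "array"))
}

#' @rdname fingerprint_matrix
#' @param x A `fingerprint_matrix`.
#' @export
fp_bins <- function(x) as.integer(colnames(x))

#' @rdname fingerprint_matrix
#' @export
fp_samples <- function(x) rownames(x)

#' @rdname fingerprint_matrix
#' @export
fp_state <- function(x) attr(x, "state")

#' @rdname fingerprint_matrix
#' @export
fp_mode <- function(x) attr(x, "mode")

#' @export
print.fingerprint_matrix <- function(x, ...) {
  cat(sprintf("<fingerprint_matrix> %d samples x %d bins (%s mode)\n",
              nrow(x), ncol(x), fp_mode(x)))
  cat("  state:", paste(fp_state(x), collapse = " -> "), "\n")
  invisible(x)
}

#' @exportS3Method
tidy.fingerprint_matrix <- function(x, ...) {
  tibble(
    sample_id = rep(fp_samples(x), times = ncol(x)),
    bin = rep(fp_bins(x), each = nrow(x)),
    intensity = as.numeric(x)
  )
}

with_state <- function(x, add) {
  fingerprint_matrix(unclass(x), mode = fp_mode(x),
                     state = c(fp_state(x), add))
}

require_state <- function(x, step, forbid) {
  stopifnot(inherits(x, "fingerprint_matrix"))
  st <- fp_state(x)
  if (!"binned" %in% st) abort(sprintf("%s requires binned data", step))
  bad <- intersect(forbid, st)
  if (length(bad)) {
    abort(sprintf("%s cannot be applied to data already %s",
                  step, paste(bad, collapse = "/")))
  }
  invisible(x)
}

#' Subtract a per-sample scalar baseline
#'
#' Simple background correction: for each sample the given quantile of its
#' positive bin intensities is subtracted from every bin and results are
#' floored at zero. Must be applied to raw binned intensities, before the
#' log transform or TIC normalization.
#'
#' @param x A [fingerprint_matrix()].
#' @param quantile Baseline quantile of each sample's positive intensities,
#'   in (0, 1); default 0.05.
#' @return The corrected `fingerprint_matrix` with state flag
#'   `baseline_subtracted` added.
#' @export
subtract_baseline <- function(x, quantile = 0.05) {
  require_state(x, "subtract_baseline",
                c("baseline_subtracted", "log_transformed", "tic_normalized"))
  if (!is.numeric(quantile) || quantile <= 0 || quantile >= 1) {
    abort("`quantile` must lie strictly between 0 and 1")
  }
  vals <- unclass(x)
  base <- apply(vals, 1, function(row) {
    pos <- row[row > 0]
    if (!length(pos)) return(0)
    stats::quantile(pos, quantile, names = FALSE)
  })
  vals <- pmax(vals - base, 0)
  with_state(fingerprint_matrix(vals, fp_mode(x), fp_state(x)),
             "baseline_subtracted")
}

#' Log-transform intensities
#'
#' Applies `log10(x + 1)` element-wise to damp the heavy-tailed variance of
#' ion-count data. The +1 offset keeps exact zeros at zero and the transform
#' strictly monotone.
#'
#' @param x A [fingerprint_matrix()] with non-negative values.
#' @return The transformed `fingerprint_matrix` with flag `log_transformed`.
#' @export
log_transform <- function(x) {
  require_state(x, "log_transform", "log_transformed")
  vals <- unclass(x)
  if (any(vals < 0)) abort("log_transform requires non-negative values")
  with_state(fingerprint_matrix(log10(vals + 1), fp_mode(x), fp_state(x)),
             "log_transformed")
}

#' Normalize each sample to total ion current
#'
#' Divides each row by its sum so bin values become relative abundances
#' summing to one, removing per-sample infusion/concentration scale.
#'
#' @param x A [fingerprint_matrix()]; every row must have a positive sum.
#' @return The normalized `fingerprint_matrix` with flag `tic_normalized`.
#' @export
tic_normalize <- function(x) {
  require_state(x, "tic_normalize", "tic_normalized")
  vals <- unclass(x)
  rs <- rowSums(vals)
  if (any(rs <= 0)) {
    abort(sprintf("non-positive total ion current for sample(s): %s",
                  paste(rownames(vals)[rs <= 0], collapse = ", ")))
  }
  with_state(fingerprint_matrix(vals / rs, fp_mode(x), fp_state(x)),
             "tic_normalized")
}

#' Run the full pre-processing chain
#'
#' Convenience wrapper applying baseline subtraction, log10 transform and TIC
#' normalization in order to a binned fingerprint matrix. The default order
#' (log10 then TIC) follows the processing description of the original
#' workflow; `order = "tic-log"` gives the more common TIC-first variant.
#'
#' @inheritParams subtract_baseline
#' @param baseline_quantile Passed to [subtract_baseline()].
#' @param order `"log-tic"` (default) or `"tic-log"`.
#' @param log10_transform Set `FALSE` to skip the log step (the TIC-normalized
#'   output is then exactly scale-invariant in each sample's raw intensities).
#' @return A fully processed `fingerprint_matrix`.
#' @export
preprocess_fingerprints <- function(x, baseline_quantile = 0.05,
                                    order = c("log-tic", "tic-log"),
                                    log10_transform = TRUE) {
  order <- match.arg(order)
  x <- subtract_baseline(x, baseline_quantile)
  if (!log10_transform) return(tic_normalize(x))
  if (order == "log-tic") tic_normalize(log_transform(x))
  else log_transform(tic_normalize(x))
}

#' Build a fingerprint matrix from peak spectra
#'
#' Bins each sample's spectrum (or merges per-range spectra when a sample has
#' one spectrum per scan window) onto the common integer nominal-mass axis of
#' `scheme` and stacks the samples into a binned [fingerprint_matrix()].
#'
#' @param spectra A list of [peak_spectrum()] objects (one per sample), or a
#'   list of lists of spectra (per sample, one per scan range of `scheme`).
#' @param scheme A [scan_scheme()].
#' @param tolerance Binning tolerance in Daltons; see [bin_peaks()].
#' @return A binned `fingerprint_matrix`. Total discarded-peak count is
#'   attached as attribute `n_discarded`.
#' @export
build_fingerprints <- function(spectra, scheme = scan_scheme(),
                               tolerance = 0.1) {
  if (!length(spectra)) abort("`spectra` is empty")
  one <- function(s) {
    if (inherits(s, "peak_spectrum")) {
      full <- peak_spectrum(s$peaks, s$sample_id, s$mode,
                            range(unlist(scheme$ranges)))
      vecs <- lapply(scheme$ranges, function(r) {
        keep <- full$peaks$mz >= r[1] & full$peaks$mz <= r[2]
        bin_peaks(peak_spectrum(full$peaks[keep, , drop = FALSE],
                                full$sample_id, full$mode, r), tolerance)
      })
      list(id = s$sample_id, mode = s$mode,
           v = merge_scan_ranges(vecs, scheme),
           nd = sum(vapply(vecs, attr, integer(1), "n_discarded")))
    } else {
      vecs <- lapply(s, bin_peaks, tolerance = tolerance)
      list(id = s[[1]]$sample_id, mode = s[[1]]$mode,
           v = merge_scan_ranges(vecs, scheme),
           nd = sum(vapply(vecs, attr, integer(1), "n_discarded")))
    }
  }
  rows <- lapply(spectra, one)
  modes <- unique(vapply(rows, `[[`, character(1), "mode"))
  if (length(modes) != 1) {
    abort("all spectra must share one ionization mode; process modes separately")
  }
  m <- do.call(rbind, lapply(rows, `[[`, "v"))
  rownames(m) <- vapply(rows, `[[`, character(1), "id")
  out <- fingerprint_matrix(m, modes, "binned")
  attr(out, "n_discarded") <- sum(vapply(rows, `[[`, numeric(1), "nd"))
  out
}

#' Read and write fingerprint matrices and peak lists
#'
#' Fingerprint matrices are stored as delimited text with a `sample_id` first
#' column and integer-bin column headers; peak lists as two-column
#' (`mz`, `intensity`) delimited text, one file per sample per mode named
#' `<sample_id>.<mode>.tsv`.
#'
#' @param path File (or, for peak lists, directory) path.
#' @param x Object to write.
#' @param mode Ionization mode of the stored matrix / peak lists.
#' @param state State flags of the stored matrix.
#' @name fingerprint-io
NULL

#' @rdname fingerprint-io
#' @export
write_fingerprints <- function(x, path) {
  stopifnot(inherits(x, "fingerprint_matrix"))
  df <- tibble(sample_id = fp_samples(x))
  df <- dplyr::bind_cols(df, as_tibble(unclass(x)))
  readr::write_tsv(df, path)
  meta <- list(mode = fp_mode(x), state = fp_state(x))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname fingerprint-io
#' @export
read_fingerprints <- function(path, mode = NULL, state = NULL) {
  df <- readr::read_tsv(path, show_col_types = FALSE)
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    mode <- mode %||% meta$mode
    state <- state %||% meta$state
  }
  m <- as.matrix(df[-1])
  rownames(m) <- df$sample_id
  fingerprint_matrix(m, mode %||% "positive", state %||% "binned")
}

#' @rdname fingerprint-io
#' @export
read_peaklist_dir <- function(path, mode = c("positive", "negative"),
                              scan_range = c(15, 1200)) {
  mode <- match.arg(mode)
  files <- list.files(path, pattern = paste0("\\.", mode, "\\.(tsv|csv)$"),
                      full.names = TRUE)
  if (!length(files)) abort(sprintf("no %s-mode peak lists under %s", mode, path))
  lapply(files, function(f) {
    id <- sub(paste0("\\.", mode, "\\.(tsv|csv)$"), "", basename(f))
    reader <- if (grepl("\\.csv$", f)) readr::read_csv else readr::read_tsv
    peak_spectrum(reader(f, show_col_types = FALSE), id, mode, scan_range)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
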