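test_that("bin_peaks handles empty and single-peak spectra", {
  empty <- peak_spectrum(data.frame(mz = numeric(), intensity = numeric()),
                         "e", scan_range = c(15, 110))
  v <- bin_peaks(empty)
  expect_true(all(v == 0))
  expect_identical(names(v), as.character(15:110))

  one <- peak_spectrum(data.frame(mz = 100.05, intensity = 10), "s",
                       scan_range = c(15, 110))
  v <- bin_peaks(one)
  expect_equal(v[["100"]], 10)
  expect_equal(sum(v), 10)
})

test_that("bin_peaks matches the brute-force assignment oracle and conserves intensity", {
  set.seed(41)
  mz <- runif(1000, 15, 110)
  int <- rexp(1000, 1 / 50)
  sp <- peak_spectrum(data.frame(mz = mz, intensity = int), "s",
                      scan_range = c(15, 110))
  v <- bin_peaks(sp, tolerance = 0.1)
  o <- oracle_bin(mz, int, 15, 110, 0.1)
  expect_equal(as.numeric(v), as.numeric(o))

  accepted <- abs(mz - round(mz)) <= 0.1
  expect_equal(sum(v), sum(int[accepted]))
  expect_equal(attr(v, "n_discarded"), sum(!accepted))
})

test_that("bin_peaks rejects invalid tolerance and negative intensities", {
  sp <- peak_spectrum(data.frame(mz = 50, intensity = 1), "s",
                      scan_range = c(15, 110))
  expect_error(bin_peaks(sp, tolerance = 0.5), "ambiguous")
  expect_error(bin_peaks(sp, tolerance = 0), "positive")
  expect_error(
    peak_spectrum(data.frame(mz = 50, intensity = -1), "s",
                  scan_range = c(15, 110)),
    "negative")
})

test_that("merge_scan_ranges passes disjoint bins through and averages overlaps", {
  sch <- scan_scheme(list(c(15, 110), c(100, 220)))
  v1 <- setNames(rep(1, 96), 15:110)
  v2 <- setNames(rep(3, 121), 100:220)
  v1["105"] <- 4; v2["105"] <- 6
  merged <- merge_scan_ranges(list(v1, v2), sch)
  expect_equal(merged[["105"]], 5)          # mean of two contributions
  expect_equal(merged[["50"]], 1)           # single-range pass-through
  expect_equal(merged[["150"]], 3)
  expect_identical(names(merged), as.character(15:220))
})

test_that("merge_scan_ranges equals the per-bin mean oracle on random vectors", {
  set.seed(7)
  sch <- scan_scheme()
  vecs <- lapply(sch$ranges, function(r) {
    bins <- ceiling(r[1]):floor(r[2])
    setNames(runif(length(bins), 0, 100), bins)
  })
  merged <- merge_scan_ranges(vecs, sch)
  o <- oracle_merge(vecs)
  expect_equal(as.numeric(merged), as.numeric(o))
  expect_identical(names(merged), names(o))
})

test_that("merge_scan_ranges rejects mismatched vector lengths", {
  sch <- scan_scheme(list(c(15, 110), c(100, 220)))
  expect_error(merge_scan_ranges(list(setNames(1, "15"),
                                      setNames(rep(1, 121), 100:220)), sch),
               "covers")
})

test_that("subtract_baseline matches the scalar-quantile oracle, never negative", {
  set.seed(11)
  m <- matrix(rexp(5 * 30, 1 / 100), 5, 30)
  m[1, ] <- 0                                # all-zero row untouched
  m[2, ] <- 42                               # constant row zeroes out
  fp <- fp_of(m)
  out <- subtract_baseline(fp, 0.05)
  expect_true(all(unclass(out) >= 0))
  expect_true(all(unclass(out)[1, ] == 0))
  expect_true(all(unclass(out)[2, ] == 0))
  for (i in 3:5) {
    expect_equal(unname(unclass(out)[i, ]), unname(oracle_baseline_row(m[i, ], 0.05)))
  }
  expect_true("baseline_subtracted" %in% fp_state(out))
})

test_that("log_transform is the element-wise log10(x + 1) map", {
  set.seed(12)
  m <- matrix(rexp(4 * 10), 4, 10)
  m[1, 1] <- 0
  m[1, 2] <- 9
  out <- log_transform(fp_of(m))
  expect_equal(unclass(out)[1, 1], 0)
  expect_equal(unclass(out)[1, 2], 1)
  expect_equal(unname(unclass(out)), unname(log10(m + 1)),
               ignore_attr = TRUE)
  expect_error(log_transform(fp_of(matrix(-1, 1, 1))), "non-negative")
})

test_that("tic_normalize divides by row sums and rejects zero-sum rows", {
  m <- matrix(c(2, 2, 1, 3), 2, byrow = TRUE)
  out <- tic_normalize(fp_of(m))
  expect_equal(unname(unclass(out)[1, ]), c(0.5, 0.5))
  expect_equal(unname(unclass(out)[2, ]), c(0.25, 0.75))

  set.seed(13)
  m <- matrix(rexp(6 * 12), 6, 12)
  out <- tic_normalize(fp_of(m))
  expect_equal(unname(rowSums(unclass(out))), rep(1, 6), tolerance = 1e-9)
  expect_equal(unname(unclass(out)), unname(m / rowSums(m)),
               ignore_attr = TRUE)

  bad <- matrix(c(1, 1, 0, 0), 2, byrow = TRUE)
  rownames(bad) <- c("ok", "empty"); colnames(bad) <- c("100", "101")
  expect_error(tic_normalize(fingerprint_matrix(bad)), "empty")
})

test_that("processing-state flags enforce the legal step order", {
  m <- fp_of(matrix(rexp(20), 4, 5))
  b <- subtract_baseline(m)
  expect_error(subtract_baseline(b), "already")
  lg <- log_transform(b)
  expect_error(subtract_baseline(lg), "already")
  expect_error(log_transform(lg), "already")
  tn <- tic_normalize(lg)
  expect_error(tic_normalize(tn), "already")
  expect_setequal(fp_state(tn), c("binned", "baseline_subtracted",
                                  "log_transformed", "tic_normalized"))
})

test_that("with the log step disabled the pipeline is exactly scale-invariant", {
  set.seed(14)
  m <- matrix(rexp(3 * 40, 1 / 100), 3, 40)
  scaled <- m
  scaled[2, ] <- scaled[2, ] * 7.3          # rescale one sample's raw peaks
  a <- preprocess_fingerprints(fp_of(m), log10_transform = FALSE)
  b <- preprocess_fingerprints(fp_of(scaled), log10_transform = FALSE)
  expect_equal(unclass(a), unclass(b))
})

test_that("build_fingerprints round-trips through peak lists and merges modes strictly", {
  set.seed(15)
  sp1 <- peak_spectrum(data.frame(mz = c(20.02, 150.05, 700.1),
                                  intensity = c(5, 7, 9)), "d1")
  sp2 <- peak_spectrum(data.frame(mz = c(20.08, 300.0),
                                  intensity = c(2, 4)), "d2")
  fp <- build_fingerprints(list(sp1, sp2))
  expect_s3_class(fp, "fingerprint_matrix")
  expect_equal(unclass(fp)["d1", "700"], 9)
  expect_equal(unclass(fp)["d2", "20"], 2)
  expect_equal(sum(unclass(fp)), 27)

  neg <- peak_spectrum(data.frame(mz = 50, intensity = 1), "d3",
                       mode = "negative")
  expect_error(build_fingerprints(list(sp1, neg)), "mode")
})

test_that("fingerprint matrices round-trip through TSV with state sidecar", {
  dir <- withr::local_tempdir()
  m <- fp_of(matrix(rexp(12), 3, 4))
  out <- preprocess_fingerprints(m)
  path <- file.path(dir, "fp.tsv")
  write_fingerprints(out, path)
  back <- read_fingerprints(path)
  expect_equal(unclass(back), unclass(out), tolerance = 1e-12)
  expect_setequal(fp_state(back), fp_state(out))
  expect_identical(fp_mode(back), fp_mode(out))
})
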