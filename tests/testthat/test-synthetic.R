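test_that("generators are pure functions of design and seed", {
  des <- synthetic_design(n_bins = 30, samples_per_class = 5, seed = 71)
  a <- generate_fingerprints(des)
  b <- generate_fingerprints(des)
  expect_identical(unclass(a$fingerprints), unclass(b$fingerprints))
  expect_identical(a$labels, b$labels)
  c <- generate_fingerprints(des, seed = 72)
  expect_false(identical(unclass(a$fingerprints), unclass(c$fingerprints)))

  m1 <- generate_metadata(30, seed = 5)
  m2 <- generate_metadata(30, seed = 5)
  expect_identical(m1, m2)
})

test_that("design validation rejects inconsistent structure", {
  expect_error(synthetic_design(
    discriminatory_bins = data.frame(bin = 700, class = "class2", shift = 1),
    adduct_clusters = list(list(anchor = 700, offsets = 1, scales = 0.5))),
    "overlap")
  expect_error(synthetic_design(
    discriminatory_bins = data.frame(bin = 5, class = "class2", shift = 1)),
    "15..1200")
  expect_error(synthetic_design(
    discriminatory_bins = data.frame(bin = 100, class = "class9", shift = 1)),
    "class1")
  expect_error(synthetic_design(noise_sd = -1), ">= 0")
  expect_error(generate_metadata(
    10, association = list(pair = c("breed", "gender"), strength = 2)),
    "\\[0, 1\\]")
})

test_that("a null design gives chance-level downstream classification", {
  runs <- lapply(1:4, function(seed) {
    des <- synthetic_design(n_bins = 40, samples_per_class = 10, seed = seed)
    sim <- generate_fingerprints(des)
    fp <- preprocess_fingerprints(sim$fingerprints)
    bootstrap_classify(fp, sim$labels, n_bootstraps = 10, n_trees = 100,
                       seed = seed)
  })
  aucs <- vapply(runs, function(r) r$aggregate[["auc"]], numeric(1))
  expect_gte(mean(aucs), 0.4)
  expect_lte(mean(aucs), 0.6)
  expect_false(any(vapply(runs, `[[`, logical(1), "adequate")))
})

test_that("planted adduct clusters are recovered exactly by correlation clustering", {
  des <- synthetic_design(
    n_bins = 50, samples_per_class = 10, noise_sd = 0.05,
    adduct_clusters = list(list(anchor = 400, offsets = c(1, 16),
                                scales = c(0.3, 0.15))), seed = 74)
  sim <- generate_fingerprints(des)
  fp <- preprocess_fingerprints(sim$fingerprints, order = "tic-log")
  cl <- correlation_clusters(fp, threshold = 0.7)
  expect_equal(cl[[1]]$member_bins, c(400, 401, 416))
  expect_true(all(abs(cl[[1]]$pairwise_r) > 0.9))
  expect_true(all(lengths(lapply(cl[-1], `[[`, "member_bins")) == 1))

  rel <- interpret_cluster(cl[[1]])
  expect_identical(
    rel$relation[rel$bin_a == 400 & rel$bin_b == 416], "na_k_adduct_pair")
  expect_identical(
    rel$relation[rel$bin_a == 400 & rel$bin_b == 401], "isotopologue_pair")
})

test_that("TIC normalization removes the planted per-sample scale factors", {
  des <- synthetic_design(n_bins = 40, samples_per_class = 6,
                          tic_scale_range = c(0.25, 4), seed = 75)
  sim <- generate_fingerprints(des)
  raw <- unclass(sim$fingerprints)
  unscaled <- fp_of(raw / sim$truth$tic_factors)
  a <- tic_normalize(fp_of(raw))
  b <- tic_normalize(unscaled)
  expect_equal(unclass(a), unclass(b), tolerance = 1e-12)
})

test_that("peak-list emission round-trips exactly through binning", {
  des <- synthetic_design(n_bins = 25, samples_per_class = 4, seed = 76)
  sim <- generate_fingerprints(des)
  for (jit in c(0, 0.03)) {
    specs <- generate_peaklists(sim$fingerprints, jitter_sd = jit, seed = 77)
    m <- unclass(sim$fingerprints)
    for (sp in specs) {
      v <- bin_peaks(sp, tolerance = 0.1)
      expect_equal(unname(v[colnames(m)]), unname(m[sp$sample_id, ]))
      expect_equal(sum(v), sum(m[sp$sample_id, ]))   # conservation
      expect_equal(attr(v, "n_discarded"), 0L)
    }
  }
  expect_error(generate_peaklists(sim$fingerprints, jitter_sd = 0.1), "< 0.1")
})

test_that("replicate designs share individual profiles within replicates", {
  des <- synthetic_design(n_bins = 30, samples_per_class = 5,
                          noise_sd = 0.3, replicate_sd = 0.02,
                          n_replicates = 3, seed = 78)
  sim <- generate_fingerprints(des)
  expect_equal(nrow(sim$fingerprints), 30)
  expect_equal(length(levels(sim$individual)), 10)
  fp <- log_transform(fp_of(unclass(sim$fingerprints)))
  m <- unclass(fp)
  d_within <- mean(dist(m[sim$individual == "ind001", ]))
  d_between <- mean(dist(rbind(m[sim$individual == "ind001", ][1, ],
                               m[sim$individual == "ind002", ][1, ])))
  expect_lt(d_within, d_between)
})

test_that("metadata association strength drives chi-squared detectability", {
  md <- generate_metadata(
    100, list(a = c("x", "y"), b = c("u", "v")),
    association = list(pair = c("a", "b"), strength = 1), seed = 79)
  p <- chi2_test(contingency_table(md, "a", "b"))$p_value
  expect_lt(p, 0.0024)

  md0 <- generate_metadata(100, list(a = c("x", "y"), b = c("u", "v")),
                           association = list(pair = c("a", "b"),
                                              strength = 0), seed = 79)
  p0 <- chi2_test(contingency_table(md0, "a", "b"))$p_value
  expect_gt(p0, 0.0024)
})
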