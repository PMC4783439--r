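test_that("feature_auc reproduces exhaustive pair counting and trivial cases", {
  expect_equal(feature_auc(c(1, 2, 3, 4), c("a", "a", "b", "b")), 1)
  expect_equal(feature_auc(c(1, 3, 2, 4), c("a", "a", "b", "b")), 0.75)
  expect_equal(feature_auc(rep(2, 6), rep(c("a", "b"), 3)), 0.5)
  expect_error(feature_auc(1:4, rep("a", 4)), "2 classes")

  set.seed(51)
  for (i in 1:10) {
    v <- sample(1:6, 14, replace = TRUE)
    labs <- rep(c("a", "b"), 7)
    raw <- oracle_auc(v[labs == "a"], v[labs == "b"])
    expect_equal(feature_auc(v, labs, fold = FALSE), raw)
    expect_equal(feature_auc(v, labs), max(raw, 1 - raw))
  }
})

test_that("feature_auc equals the Mann-Whitney U statistic over n1*n2", {
  set.seed(52)
  v <- rnorm(20)
  labs <- rep(c("a", "b"), each = 10)
  u <- suppressWarnings(
    wilcox.test(v[labs == "a"], v[labs == "b"])$statistic)
  expect_equal(feature_auc(v, labs, fold = FALSE), unname(u) / 100)
})

test_that("feature_t_test matches the pooled closed form and degenerate rules", {
  res <- feature_t_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(abs(res$t_stat), 3.674, tolerance = 1e-3)
  expect_equal(res$p_value, 0.0213, tolerance = 1e-3)
  o <- oracle_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$t_stat, o$t)
  expect_equal(res$p_value, o$p)

  same <- feature_t_test(rep(2, 3), rep(2, 4))
  expect_equal(same$t_stat, 0)
  expect_equal(same$p_value, 1)

  set.seed(53)
  a <- rnorm(9); b <- rnorm(11)
  o <- oracle_t(a, b)
  res <- feature_t_test(a, b)
  expect_equal(res$t_stat, o$t)
  expect_equal(res$p_value, o$p)
  # Welch form differs from pooled under unequal variances
  expect_false(isTRUE(all.equal(
    feature_t_test(a, b * 5, var_equal = FALSE)$p_value,
    feature_t_test(a, b * 5)$p_value)))
})

test_that("t-test type-I error is calibrated at the 5% level (quick check)", {
  set.seed(54)
  rej <- mean(vapply(1:1000, function(i) {
    feature_t_test(rnorm(10), rnorm(10))$p_value < 0.05
  }, logical(1)))
  expect_gt(rej, 0.03)
  expect_lt(rej, 0.07)
})

test_that("an uninformative feature has near-zero importance", {
  imps <- vapply(1:10, function(seed) {
    set.seed(seed)
    m <- matrix(rnorm(60 * 5), 60, 5)
    rownames(m) <- sprintf("s%d", 1:60); colnames(m) <- 100:104
    labs <- rep(c("a", "b"), each = 30)
    rf_importance(m, labs, n_trees = 400, seed = seed)$importance[3]
  }, numeric(1))
  expect_lt(abs(mean(imps)), 0.02)
  expect_lt(max(abs(imps)), 0.05)
})

test_that("a planted separating feature is ranked first by all three rankers", {
  set.seed(55)
  m <- matrix(rnorm(40 * 51), 40, 51)
  labs <- rep(c("a", "b"), each = 20)
  m[labs == "b", 26] <- m[labs == "b", 26] + 6   # perfectly separating
  rownames(m) <- sprintf("s%d", 1:40); colnames(m) <- 100:150
  rk <- rank_features(m, labs, n_trees = 200, seed = 55)
  planted <- rk[rk$bin == 125, ]
  expect_equal(planted$rank_importance, 1)
  expect_equal(planted$rank_auc, 1)
  expect_equal(planted$rank_p, 1)
  expect_true(planted$selected)
  expect_true(all(sort(rk$rank_importance) == seq_len(nrow(rk))))
  expect_true(all(sort(rk$rank_auc) == seq_len(nrow(rk))))
  expect_true(all(sort(rk$rank_p) == seq_len(nrow(rk))))
})

test_that("permutation importance agrees with delete-and-retrain accuracy loss", {
  # slow reference oracle: refit without the feature and compare OOB error
  set.seed(56)
  m <- matrix(rnorm(40 * 10), 40, 10)
  labs <- factor(rep(c("a", "b"), each = 20))
  m[labs == "b", 4] <- m[labs == "b", 4] + 4
  rownames(m) <- sprintf("s%d", 1:40); colnames(m) <- 100:109
  imp <- rf_importance(m, labs, n_trees = 300, seed = 56)$importance[4]

  oob_acc <- function(x) {
    rf <- randomForest::randomForest(x, labs, ntree = 300)
    1 - rf$err.rate[300, "OOB"]
  }
  set.seed(57)
  drop_loss <- unname(oob_acc(m) - oob_acc(m[, -4]))
  expect_gt(imp, 0.1)
  expect_gt(drop_loss, 0.1)
  expect_equal(imp, drop_loss, tolerance = 0.25)
})

test_that("the selection rule gates on both p-value and importance", {
  rk <- tibble::tibble(
    bin = 1:3, importance = c(0.01, 0.001, 0.05),
    p_value = c(0.01, 0.01, 0.5))
  sel <- rk$p_value < 0.05 & rk$importance > 0.002
  expect_identical(sel, c(TRUE, FALSE, FALSE))
})

test_that("correlation_clusters recovers a planted cluster among noise bins", {
  set.seed(58)
  n <- 30
  latent <- rnorm(n)
  m <- matrix(rnorm(n * 47), n, 47)
  cluster <- cbind(latent + rnorm(n, sd = 0.05),
                   2 * latent + rnorm(n, sd = 0.05),
                   -1.5 * latent + rnorm(n, sd = 0.05))
  m <- cbind(cluster, m)
  rownames(m) <- sprintf("s%d", seq_len(n))
  colnames(m) <- seq(200, length.out = 50)
  cl <- correlation_clusters(m, threshold = 0.7)
  expect_equal(cl[[1]]$member_bins, c(200, 201, 202))
  expect_true(all(lengths(lapply(cl[-1], `[[`, "member_bins")) == 1))
  expect_equal(unname(diag(cl[[1]]$pairwise_r)), rep(1, 3))  # self r = 1
})

test_that("clusters equal union-find components and are order/scale invariant", {
  set.seed(59)
  n <- 25
  base <- rnorm(n)
  m <- cbind(base, base * 3 + rnorm(n, sd = 0.1), rnorm(n), rnorm(n),
             base - rnorm(n, sd = 0.1))
  rownames(m) <- sprintf("s%d", 1:n); colnames(m) <- c(300:303, 310)
  cl <- correlation_clusters(m, threshold = 0.7)
  comp <- oracle_components(cor(m), 0.7)
  got <- unname(lapply(cl, `[[`, "member_bins"))
  want <- unname(lapply(comp, function(idx) sort(as.numeric(colnames(m)[idx]))))
  expect_setequal(got, want)

  perm <- sample(ncol(m))
  cl_perm <- correlation_clusters(m[, perm], threshold = 0.7)
  expect_setequal(unname(lapply(cl_perm, `[[`, "member_bins")), got)

  scaled <- sweep(m, 2, runif(ncol(m), 0.1, 10), `*`)
  cl_scaled <- correlation_clusters(scaled, threshold = 0.7)
  expect_setequal(unname(lapply(cl_scaled, `[[`, "member_bins")), got)
})

test_that("constant bins produce a warning and no edges", {
  m <- cbind(rnorm(10), rep(1, 10), rnorm(10))
  rownames(m) <- sprintf("s%d", 1:10); colnames(m) <- c("100", "101", "102")
  expect_warning(cl <- correlation_clusters(m, threshold = 0.7), "constant")
  expect_true(list(101) %in% lapply(cl, `[[`, "member_bins"))
})
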