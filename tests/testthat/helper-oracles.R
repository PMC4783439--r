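# Independent brute-force oracles. These deliberately re-derive each quantity
# from first principles, sharing no code path with the package internals.

# assign each peak to round(mz) iff within tol, by explicit loop
oracle_bin <- function(mz, intensity, lo, hi, tol = 0.1) {
  bins <- seq.int(ceiling(lo), floor(hi))
  out <- setNames(numeric(length(bins)), bins)
  for (i in seq_along(mz)) {
    b <- round(mz[i])
    if (abs(mz[i] - b) <= tol && b >= bins[1] && b <= bins[length(bins)]) {
      out[as.character(b)] <- out[as.character(b)] + intensity[i]
    }
  }
  out
}

# per-bin mean over the range vectors that cover the bin
oracle_merge <- function(vectors) {
  bins <- sort(unique(unlist(lapply(vectors, function(v) as.numeric(names(v))))))
  vapply(bins, function(b) {
    vals <- unlist(lapply(vectors, function(v) v[as.character(b)]))
    mean(vals[!is.na(vals)])
  }, numeric(1)) |> setNames(bins)
}

# explicit quantile -> subtract -> floor on one row
oracle_baseline_row <- function(row, q) {
  pos <- row[row > 0]
  base <- if (length(pos)) quantile(pos, q, names = FALSE) else 0
  pmax(row - base, 0)
}

# Pearson chi-squared by the direct formula
oracle_chi2 <- function(tab) {
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - E)^2 / E)
}

# AUC by exhaustive cross-pair counting
oracle_auc <- function(pos_scores, neg_scores) {
  wins <- 0
  for (p in pos_scores) for (n in neg_scores) {
    wins <- wins + (p > n) + 0.5 * (p == n)
  }
  wins / (length(pos_scores) * length(neg_scores))
}

# pooled-variance two-sample t by the closed form
oracle_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * pt(-abs(t), n1 + n2 - 2))
}

# connected components of the |r| > thr graph by union-find
oracle_components <- function(r, thr) {
  n <- nrow(r)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (!is.na(r[i, j]) && abs(r[i, j]) > thr) {
      parent[find(i)] <- find(j)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  unname(split(seq_len(n), roots))
}

# monoisotopic mass by explicit per-element summation (own constants)
oracle_mass <- function(counts) {
  tabl <- c(C = 12, H = 1.0078250319, N = 14.0030740052, O = 15.9949146221,
            P = 30.9737615120, S = 31.9720707300, Na = 22.9897692820,
            K = 38.9637064864)
  total <- 0
  for (el in names(counts)) total <- total + tabl[[el]] * counts[[el]]
  total
}

# small helper: fingerprint matrix straight from a numeric matrix
fp_of <- function(m, state = "binned", mode = "positive") {
  if (is.null(rownames(m))) rownames(m) <- sprintf("s%02d", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- seqLen_bins(ncol(m))
  fingerprint_matrix(m, mode, state)
}
seqLen_bins <- function(p) as.character(seq(100, by = 1, length.out = p))

# two-class Gaussian toy matrix: n per class, p bins, shift on first k bins
toy_two_class <- function(n = 10, p = 20, shift = 0, k = 5, sd = 1,
                          seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(2 * n * p, sd = sd), 2 * n, p)
  m[(n + 1):(2 * n), seq_len(k)] <- m[(n + 1):(2 * n), seq_len(k)] + shift
  rownames(m) <- sprintf("s%02d", seq_len(2 * n))
  colnames(m) <- seq(100, by = 1, length.out = p)
  list(x = m, labels = rep(c("a", "b"), each = n))
}
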