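# Independent brute-force oracles used to check the package's statistics.
# These deliberately avoid the code paths (and where possible the base-R
# functions) used by the implementation.

# Average-rank normalization by explicit sorting: sort the values, walk
# tied blocks, assign each block the mean of its 1-based positions,
# rescale to [0, 1].
brute_rank_norm <- function(v) {
  g <- length(v)
  ord <- order(v)
  sorted <- v[ord]
  ranks_sorted <- numeric(g)
  i <- 1L
  while (i <= g) {
    j <- i
    while (j < g && sorted[j + 1L] == sorted[i]) j <- j + 1L
    ranks_sorted[i:j] <- mean(i:j)
    i <- j + 1L
  }
  ranks <- numeric(g)
  ranks[ord] <- ranks_sorted
  (ranks - 1) / (g - 1)
}

# Delta for one gene of one dataset: explicit per-sample ranking then
# group-mean difference.
brute_gene_delta <- function(mat, states, gene) {
  rn <- sapply(seq_len(ncol(mat)), function(j) brute_rank_norm(mat[, j]))
  rownames(rn) <- rownames(mat)
  mean(rn[gene, states == "disease"]) - mean(rn[gene, states == "normal"])
}

# Two-sided Fisher p for a 2x2 table by full enumeration of the
# hypergeometric support with the minimum-likelihood rule.
enum_fisher_p <- function(tab) {
  m <- as.matrix(tab)
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  support <- max(0L, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  p_obs <- dhyper(m[1, 1], c1, n - c1, r1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Textbook Pearson chi-square statistic.
formula_chi2 <- function(tab) {
  m <- as.matrix(tab)
  e <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - e)^2 / e)
}

# Kruskal-Wallis H from scratch: pooled average ranks, between-group rank
# sums, tie-correction divisor.
formula_kw_h <- function(groups) {
  pooled <- unlist(groups)
  n <- length(pooled)
  r <- rank(pooled, ties.method = "average")
  idx <- rep(seq_along(groups), lengths(groups))
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, idx, sum)^2 / lengths(groups)) - 3 * (n + 1)
  t_sizes <- table(pooled)
  c_div <- 1 - sum(t_sizes^3 - t_sizes) / (n^3 - n)
  h / c_div
}

# Exact two-sided permutation mid-p for the two-sample rank-sum problem:
# enumerate every split of the pooled values into groups of the observed
# sizes; the boundary atom (splits exactly as extreme as observed) enters
# with half weight, which is the discrete analogue of a normal tail
# without continuity correction.
perm_ranksum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled, ties.method = "average")
  mu <- n1 * (length(pooled) + 1) / 2
  obs <- abs(sum(r[seq_len(n1)]) - mu)
  splits <- utils::combn(length(pooled), n1)
  dev <- abs(colSums(matrix(r[splits], nrow = n1)) - mu)
  mean(dev > obs + 1e-12) + 0.5 * mean(abs(dev - obs) <= 1e-12)
}

# Exact permutation mid-p for Kruskal-Wallis with three groups: enumerate
# all partitions of the pooled values into the observed group sizes.
perm_kw_p <- function(groups) {
  stopifnot(length(groups) == 3L)
  pooled <- unlist(groups)
  n <- length(pooled)
  sizes <- lengths(groups)
  obs <- formula_kw_h(groups)
  idx_all <- seq_len(n)
  n_gt <- 0L; n_eq <- 0L; total <- 0L
  for (first in utils::combn(idx_all, sizes[1], simplify = FALSE)) {
    rest <- setdiff(idx_all, first)
    for (second in utils::combn(rest, sizes[2], simplify = FALSE)) {
      third <- setdiff(rest, second)
      h <- formula_kw_h(list(pooled[first], pooled[second], pooled[third]))
      total <- total + 1L
      if (h > obs + 1e-9) n_gt <- n_gt + 1L
      else if (abs(h - obs) <= 1e-9) n_eq <- n_eq + 1L
    }
  }
  (n_gt + 0.5 * n_eq) / total
}

# Small random expression dataset for property tests.
random_dataset <- function(n_genes, n_disease, n_normal, id = "ds",
                           disease = "dz") {
  mat <- matrix(stats::rnorm(n_genes * (n_disease + n_normal)),
                nrow = n_genes,
                dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                                sprintf("%s_s%02d", id, seq_len(n_disease + n_normal))))
  ann <- data.frame(
    sample_id = colnames(mat),
    disease_concept = disease,
    state = rep(c("disease", "normal"), c(n_disease, n_normal)),
    tissue = "t",
    stringsAsFactors = FALSE
  )
  expression_dataset(id, mat, ann)
}
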