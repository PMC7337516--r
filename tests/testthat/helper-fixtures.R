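# Shared fixtures and independent brute-force oracles used across tests.

make_cm <- function(values, kind = "peak", labels = NULL) {
  count_matrix(values,
               feature_ids = sprintf("f%02d", seq_len(nrow(values))),
               cell_ids = sprintf("c%02d", seq_len(ncol(values))),
               feature_kind = kind, cell_labels = labels)
}

# brute-force adjusted Rand index by enumerating all item pairs
ari_brute <- function(a, b) {
  n <- length(a)
  same_a <- same_b <- both <- 0
  pairs <- utils::combn(n, 2)
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1, k]; j <- pairs[2, k]
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    same_a <- same_a + sa
    same_b <- same_b + sb
    both <- both + (sa && sb)
  }
  total <- ncol(pairs)
  expected <- same_a * same_b / total
  max_index <- (same_a + same_b) / 2
  if (max_index == expected) return(1)
  (both - expected) / (max_index - expected)
}

# exhaustive hypergeometric upper tail: draw `draws` genes from `universe`,
# probability that overlap with `set` is >= observed
hyper_enum <- function(universe, set, draws, observed) {
  combos <- utils::combn(universe, draws)
  hits <- apply(combos, 2, function(q) length(intersect(q, set)))
  mean(hits >= observed)
}

# exact two-sided Wilcoxon rank-sum p by enumerating rank assignments
wilcox_enum <- function(x, y) {
  n1 <- length(x)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  all_w <- apply(utils::combn(n1 + length(y), n1), 2, function(idx) {
    sum(seq_len(n1 + length(y))[idx]) - n1 * (n1 + 1) / 2
  })
  min(1, 2 * min(mean(all_w <= w_obs), mean(all_w >= w_obs)))
}

# hand step-up BH
bh_by_hand <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- p[o] * m / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# tiny genome fixture for motif scanning
toy_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

consensus_pwm <- function(id, tf, bases) {
  mat <- matrix(0, 4, length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  for (i in seq_along(bases)) mat[bases[i], i] <- 1
  list(id = id, tf = tf, matrix = mat)
}

quick_config <- function(n, iter = 400, seed = 1, ...) {
  factorization_config(n_patterns = n, n_iterations = iter, seed = seed, ...)
}
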