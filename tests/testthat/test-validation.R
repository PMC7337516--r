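test_that("gene ranking follows the PatternMarker association", {
  A <- rbind(hot = c(0, 5),     # one-hot on pattern 2
             mid = c(2, 3),
             off = c(4, 0))     # zero amplitude in pattern 2
  colnames(A) <- paste0("Pattern_", 1:2)
  fit <- structure(list(A = A, P = matrix(1, 2, 3), chi2_trace = 0,
                        init_chi2 = 1, final_chi2 = 0, config = NULL),
                   class = "FactorizationResult")
  rk <- rank_genes_for_pattern(fit, 2)
  expect_equal(rk$gene[1], "hot")
  expect_equal(rk$score[1], 0)            # negated distance, best possible
  expect_equal(rk$gene[3], "off")         # bottom of the list
  # hand-computed middle score: scaled (2/3, 1) -> distance to e2 = 2/3
  expect_equal(rk$score[rk$gene == "mid"], -2 / 3)

  # all-zero rows are excluded with a warning
  A0 <- rbind(A, dead = c(0, 0))
  fit0 <- fit; fit0$A <- A0
  expect_warning(rk0 <- rank_genes_for_pattern(fit0, 1), "all-zero")
  expect_false("dead" %in% rk0$gene)
  expect_error(rank_genes_for_pattern(fit, 9), "invalid pattern")
})

test_that("preranked GSEA detects top-concentrated regulons", {
  genes <- paste0("G", 1:100)
  ranking <- data.frame(gene = genes, score = seq(2, -2, length.out = 100))
  reg_top <- list(TFtop = genes[1:5])
  res <- preranked_gsea(ranking, reg_top, n_permutations = 500, seed = 1)
  expect_gt(res$enrichment_score, 0.9)
  expect_lte(res$p_value, 0.01)           # at the permutation resolution
  expect_equal(res$n_targets_in_ranking, 5L)

  # uniformly spaced regulon is unenriched
  reg_flat <- list(TFflat = genes[seq(5, 100, by = 10)])
  res_flat <- preranked_gsea(ranking, reg_flat, n_permutations = 500, seed = 2)
  expect_lt(abs(res_flat$enrichment_score), 0.4)
  expect_gt(res_flat$p_value, 0.3)

  # regulon absent from the ranking is skipped and recorded
  res_both <- preranked_gsea(ranking,
                             list(TFtop = genes[1:5], ghost = c("NOPE1", "NOPE2")),
                             n_permutations = 200, seed = 3)
  expect_identical(res_both$tf, "TFtop")
  expect_true("ghost" %in% names(attr(res_both, "skipped")))
  # a regulon covering the whole ranking is degenerate, not scored
  expect_warning(
    res_all <- preranked_gsea(ranking, list(all = genes),
                              n_permutations = 100, seed = 4),
    "no regulon eligible")
  expect_equal(nrow(res_all), 0)
  expect_match(attr(res_all, "skipped")[["all"]], "degenerate")
})

test_that("reversing the ranking negates the enrichment score", {
  set.seed(59)
  genes <- paste0("G", 1:80)
  ranking <- data.frame(gene = genes,
                        score = sort(rnorm(80), decreasing = TRUE))
  rev_ranking <- data.frame(gene = rev(genes), score = rev(-ranking$score))
  for (k in c(5, 15)) {
    reg <- list(TF = sample(genes, k))
    es_f <- preranked_gsea(ranking, reg, n_permutations = 50,
                           seed = 5)$enrichment_score
    es_r <- preranked_gsea(rev_ranking, reg, n_permutations = 50,
                           seed = 5)$enrichment_score
    expect_equal(es_f, -es_r, tolerance = 1e-12)
  }
})

test_that("enrichment scores agree with the independent fgsea implementation", {
  set.seed(61)
  genes <- paste0("G", 1:120)
  stats <- sort(rnorm(120, sd = 1.5), decreasing = TRUE)
  ranking <- data.frame(gene = genes, score = stats)
  regs <- list(R1 = sample(genes, 10), R2 = genes[1:8], R3 = genes[100:115])
  mine <- preranked_gsea(ranking, regs, n_permutations = 100, seed = 6)
  ref <- suppressWarnings(
    fgsea::fgseaSimple(regs, setNames(stats, genes), nperm = 100))
  for (tf in mine$tf) {
    expect_equal(mine$enrichment_score[mine$tf == tf],
                 ref$ES[ref$pathway == tf], tolerance = 1e-8)
  }
})

test_that("permutation p-values are roughly uniform under a null", {
  set.seed(67)
  genes <- paste0("G", 1:60)
  ranking <- data.frame(gene = genes, score = sort(runif(60, -1, 1),
                                                   decreasing = TRUE))
  regs <- lapply(1:100, function(i) sample(genes, 8))
  names(regs) <- paste0("null", 1:100)
  res <- preranked_gsea(ranking, regs, n_permutations = 200, seed = 7)
  frac <- mean(res$p_value <= 0.3)
  # binomial tolerance around 0.3 with n = 100
  expect_lt(abs(frac - 0.3), 4 * sqrt(0.3 * 0.7 / 100))
})

test_that("validate_tfs intersects candidates with significant GSEA hits", {
  cand <- data.frame(motif_id = c("M1", "M2"), tf_name = c("TFA", "TFB"),
                     n_marker_peaks_with_site = c(12L, 9L), rank = c(1L, 2L))
  gsea <- data.frame(tf = c("TFA", "TFB"),
                     enrichment_score = c(0.8, 0.4),
                     p_value = c(0.001, 0.12), q_value = c(0.015, 0.2),
                     n_targets_in_ranking = c(10L, 7L))
  out <- validate_tfs(cand, gsea, alpha = 0.05,
                      fold_acc = c(TFA = 2.4))
  expect_identical(out$tf, "TFA")         # q = 0.015 <= 0.05 supported
  expect_equal(out$fold_accessibility, 2.4)
  out2 <- validate_tfs(cand, gsea, alpha = 0.01)
  expect_equal(nrow(out2), 0)             # q = 0.015 > 0.01
  empty <- validate_tfs(cand[0, ], gsea)
  expect_equal(nrow(empty), 0)
  expect_error(validate_tfs(cand, gsea, alpha = 2), "alpha")
})
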