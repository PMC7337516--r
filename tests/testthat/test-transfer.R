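test_that("feature matching pairs overlapping peaks one-to-one", {
  src <- peak_set(c("chr1", "chr1"), c(0, 300), c(100, 400),
                  id = c("s1", "s2"))
  tgt <- peak_set("chr1", 50, 150, id = "t1")
  m <- match_features(src, tgt, mode = "peak_overlap")
  expect_equal(m$source_feature_id, "s1")
  expect_equal(m$target_feature_id, "t1")

  # a source peak overlapping two targets pairs with the larger overlap
  src2 <- peak_set("chr1", 0, 100, id = "s")
  tgt2 <- peak_set(c("chr1", "chr1"), c(20, 80), c(100, 200),
                   id = c("big", "small"))  # overlaps 80 bp and 20 bp
  m2 <- match_features(src2, tgt2, mode = "peak_overlap")
  expect_equal(m2$target_feature_id, "big")

  # one-to-one: each feature appears at most once
  set.seed(43)
  starts <- sort(sample(0:5000, 30)) * 10
  srcR <- peak_set(rep("chr1", 30), starts, starts + 900)
  tgtR <- peak_set(rep("chr1", 30), starts + 450, starts + 1350)
  mR <- match_features(srcR, tgtR, mode = "peak_overlap")
  expect_false(anyDuplicated(mR$source_feature_id) > 0)
  expect_false(anyDuplicated(mR$target_feature_id) > 0)
  # symmetric in count
  mRev <- match_features(tgtR, srcR, mode = "peak_overlap")
  expect_equal(nrow(mR), nrow(mRev))

  # identifier mode is plain intersection
  mi <- match_features(c("M1", "M2"), c("M2", "M3"), mode = "shared_motif")
  expect_equal(mi$source_feature_id, "M2")
  expect_error(match_features(c("A"), c("B"), mode = "shared_id"),
               "no shared feature")
  far <- peak_set("chr1", 9000, 9100, id = "far")
  expect_error(match_features(src2, far, mode = "peak_overlap"),
               "no shared feature")
})

test_that("projection solves per-cell least squares exactly on consistent systems", {
  set.seed(47)
  A <- matrix(rgamma(40 * 3, 2), 40, 3,
              dimnames = list(paste0("f", 1:40), paste0("Pattern_", 1:3)))
  P_true <- matrix(rnorm(3 * 15), 3, 15)
  target <- count_matrix(pmax(A %*% P_true, 0) + 1,  # any values work; use exact:
                         paste0("f", 1:40), paste0("tc", 1:15), "peak")
  # build an exactly consistent non-negative target instead
  P_pos <- matrix(rgamma(3 * 15, 2), 3, 15)
  target <- count_matrix(A %*% P_pos, paste0("f", 1:40), paste0("tc", 1:15), "peak")
  matching <- data.frame(source_feature_id = paste0("f", 1:40),
                         target_feature_id = paste0("f", 1:40))
  proj <- project(A, matching, target)
  expect_equal(unname(proj$P_projected), unname(P_pos), tolerance = 1e-8)

  # identity amplitude returns the data itself
  I5 <- diag(5); rownames(I5) <- paste0("g", 1:5)
  tgt5 <- count_matrix(matrix(rpois(20, 4), 5, 4), paste0("g", 1:5),
                       paste0("c", 1:4), "peak")
  mi <- data.frame(source_feature_id = paste0("g", 1:5),
                   target_feature_id = paste0("g", 1:5))
  pr5 <- project(I5, mi, tgt5)
  expect_equal(unname(pr5$P_projected), unname(as.matrix(tgt5$values)))

  # noisy recovery stays within the conditioned noise scale
  sigma <- 0.01
  set.seed(48)
  noisy <- count_matrix(pmax(A %*% P_pos + matrix(rnorm(40 * 15, 0, sigma), 40), 0),
                        paste0("f", 1:40), paste0("tc", 1:15), "peak")
  prn <- project(A, matching, noisy)
  expect_lt(max(abs(prn$P_projected - P_pos)), 5 * sigma * prn$condition_number)

  # rank deficiency is fatal with a condition-number report
  Abad <- cbind(A[, 1], A[, 1], A[, 2])
  rownames(Abad) <- rownames(A)
  expect_error(project(Abad, matching, target), "rank deficient")
})

test_that("projection onto own patterns beats no projection and is permutation-equivariant", {
  spec <- synthetic_spec(seed = 5, n_peaks = 120, marker_peaks_per_type = 25,
                         cells_per_type = 15)
  d <- generate_atac(spec)
  flt <- filter_sparse(d$matrix)
  fit <- run_cogaps(flt$matrix, config = quick_config(3, iter = 300, seed = 7))
  matching <- data.frame(source_feature_id = feature_ids(flt$matrix),
                         target_feature_id = feature_ids(flt$matrix))
  proj <- project(fit$A, matching, flt$matrix)
  C <- as.matrix(flt$matrix$values)
  resid_ols <- norm(C - fit$A %*% proj$P_projected, "F")
  resid_fit <- norm(C - fit$A %*% fit$P, "F")
  expect_lte(resid_ols, resid_fit + 1e-8)

  # permuting source patterns permutes projected rows identically
  perm <- c(3, 1, 2)
  proj_perm <- project(fit$A[, perm], matching, flt$matrix)
  expect_equal(unname(proj_perm$P_projected), unname(proj$P_projected[perm, ]),
               tolerance = 1e-8)
})

test_that("projected group tests single out the planted population", {
  set.seed(53)
  A <- matrix(rgamma(60 * 2, 2), 60, 2,
              dimnames = list(paste0("f", 1:60), paste0("Pattern_", 1:2)))
  labels <- rep(c("hot", "coldA", "coldB"), each = 10)
  P_t <- matrix(0.3, 2, 30)
  P_t[1, labels == "hot"] <- 3   # pattern 1 elevated in 'hot'
  target <- count_matrix(A %*% P_t + matrix(runif(60 * 30, 0, 0.05), 60),
                         paste0("f", 1:60), paste0("c", 1:30), "peak",
                         cell_labels = labels)
  matching <- data.frame(source_feature_id = paste0("f", 1:60),
                         target_feature_id = paste0("f", 1:60))
  proj <- project(A, matching, target)
  gt <- projected_group_test(proj)
  top1 <- gt$top[gt$top$pattern == "Pattern_1", ]
  expect_equal(top1$group, "hot")
  expect_lt(top1$q_value, 0.05)
  expect_error(projected_group_test(proj, rep("one", 30)), "2 groups")
})
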