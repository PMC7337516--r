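test_that("peaks map to genes through body or promoter overlap", {
  # BED-style peak [100, 200)
  peaks <- peak_set("chr1", 100, 200, id = "pk")
  # gene body [150, 400) in BED terms -> 151..400 closed
  genes <- gene_annotation("g1", "G1", "chr1", 151, 400, "+")
  expect_identical(map_peaks_to_genes(peaks, genes)$pk, "G1")

  # half-open abutment: gene body [200, 300) does not touch peak [100, 200)
  genes2 <- gene_annotation("g2", "G2", "chr1", 201, 300, "+")
  expect_length(map_peaks_to_genes(peaks, genes2, promoter_up = 0,
                                   promoter_down = 0)$pk, 0)

  # promoter window reaches upstream of the TSS on the + strand:
  # TSS at 1500 (0-based) with 1500 bp upstream covers the peak
  genes3 <- gene_annotation("g3", "G3", "chr1", 1501, 3000, "+")
  expect_identical(map_peaks_to_genes(peaks, genes3, promoter_up = 1500,
                                      promoter_down = 500)$pk, "G3")
  expect_length(map_peaks_to_genes(peaks, genes3, promoter_up = 100,
                                   promoter_down = 100)$pk, 0)

  # mirrored on the - strand: promoter extends to the right of the gene end
  genes4 <- gene_annotation("g4", "G4", "chr2", 50, 80, "-")
  peaks4 <- peak_set("chr2", 100, 160, id = "pkM")
  expect_identical(map_peaks_to_genes(peaks4, genes4, promoter_up = 100,
                                      promoter_down = 10)$pkM, "G4")

  # chromosome absent from the annotation maps to the empty set
  peaks5 <- peak_set("chrZ", 0, 100, id = "pkZ")
  expect_length(map_peaks_to_genes(peaks5, genes)$pkZ, 0)
})

test_that("pathway overlap p-values are exact hypergeometric tails", {
  universe <- paste0("G", 1:20)
  sets <- list(S = paste0("G", 1:4))
  query <- c("G1", "G2", "G3", "G10", "G11")
  tab <- pathway_overlap(query, sets, universe)
  expect_equal(tab$overlap_count, 3)
  expect_equal(tab$p_value, 155 / 4845)
  # matches exhaustive enumeration of all possible draws
  expect_equal(tab$p_value, hyper_enum(universe, sets$S, 5, 3))

  # zero overlap is the p = 1 boundary
  tab0 <- pathway_overlap(c("G19", "G20"), list(S = paste0("G", 1:4)), universe)
  expect_equal(tab0$p_value, 1)

  # enumeration oracle on a second configuration (universe <= 15)
  uni <- paste0("g", 1:12)
  st <- list(A = paste0("g", 1:5))
  q <- paste0("g", c(1, 2, 6, 7))
  expect_equal(pathway_overlap(q, st, uni)$p_value,
               hyper_enum(uni, st$A, 4, 2))

  expect_error(pathway_overlap(character(0), sets, universe), "empty")
  expect_error(pathway_overlap("NOTHERE", sets, universe), "universe")
})

test_that("BH correction is the step-up procedure", {
  # hand-computed: (0.01, 0.04) -> (0.02, 0.04)
  uni <- paste0("G", 1:20)
  expect_equal(bh_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  set.seed(41)
  p <- runif(10)
  q <- bh_adjust(p)
  expect_equal(q, bh_by_hand(p))
  expect_true(all(q <= 1))
  expect_true(all(q >= p))
  # monotone non-decreasing in sorted-p order
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("motif scanning finds consensus sites on both strands", {
  pwm <- consensus_pwm("M1", "TF_A", c("A", "A", "C", "G"))
  set.seed(83)
  rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE,
                                       prob = c(0.3, 0.2, 0.2, 0.3)),
                                collapse = "")
  # chr2 alternates AT: contains neither AACG nor its reverse complement CGTT
  genome <- toy_genome(c(
    chr1 = paste0(rand_seq(14), "AACG", rand_seq(14)),  # forward site
    chr2 = paste(rep("AT", 16), collapse = ""),         # no site
    chr3 = paste0(rand_seq(14), "CGTT", rand_seq(14)))) # site on - strand
  peaks <- peak_set(c("chr1", "chr2", "chr3"), c(0, 0, 0), c(32, 32, 32),
                    id = c("p1", "p2", "p3"))
  mm <- scan_motifs(peaks, genome, list(pwm), p_threshold = 1e-3)
  expect_equal(as.numeric(mm["p1", "M1"]), 1)
  expect_equal(as.numeric(mm["p2", "M1"]), 0)
  expect_equal(as.numeric(mm["p3", "M1"]), 1)

  # scanning a sequence and its reverse complement gives the same matches
  rc <- Biostrings::reverseComplement(genome)
  names(rc) <- names(genome)
  mm_rc <- scan_motifs(peaks, rc, list(pwm), p_threshold = 1e-3)
  expect_equal(as.matrix(mm), as.matrix(mm_rc))

  # peak running past the contig end is fatal
  bad <- peak_set("chr1", 10, 100, id = "far")
  expect_error(scan_motifs(bad, genome, list(pwm)), "contig end")
  # unknown contig is fatal
  off <- peak_set("chrNA", 0, 10, id = "off")
  expect_error(scan_motifs(off, genome, list(pwm)), "absent")
})

test_that("TF enrichment ranks motifs by marker-peak hit counts", {
  peaks <- paste0("p", 1:50)
  mm <- matrix(0, 50, 3, dimnames = list(peaks, c("M1", "M2", "M3")))
  mm[1:10, 1] <- 1    # 10 marker hits
  mm[1:3, 2] <- 1     # 3
  mm[4:10, 3] <- 1    # 7
  mm <- motif_match_matrix(mm)
  tab <- tf_enrichment(peaks, mm, top_k = 2)
  expect_equal(tab$motif_id[1], "M1")
  expect_equal(tab$n_marker_peaks_with_site, c(10L, 7L))
  expect_equal(tab$rank, c(1L, 2L))

  # ties at the boundary are all returned
  mm2 <- mm
  mm2[11:17, 2] <- 1  # M2 now also has 7 + 3 = 10? no: rebuild cleanly
  mm2 <- matrix(0, 50, 3, dimnames = list(peaks, c("M1", "M2", "M3")))
  mm2[1:9, 1] <- 1
  mm2[10:16, 2] <- 1
  mm2[20:26, 3] <- 1  # M2 and M3 tied at 7, boundary at top_k = 2
  tab2 <- tf_enrichment(peaks, motif_match_matrix(mm2), top_k = 2)
  expect_equal(nrow(tab2), 3)
  expect_equal(tab2$rank, c(1L, 2L, 2L))

  # top_k beyond the motif count returns everything
  expect_equal(nrow(tf_enrichment(peaks, mm, top_k = 99)), 3)
  # no hits at all warns and returns an empty table
  none <- motif_match_matrix(matrix(0, 50, 1, dimnames = list(peaks, "M0")))
  expect_warning(empty <- tf_enrichment(peaks, none), "no motif")
  expect_equal(nrow(empty), 0)
})

test_that("fold accessibility is the hand-computable peak-count ratio", {
  # 4 cells; gene peaks accessible in 4 and 2 cells; all-peak mean 1.5
  m <- rbind(p1 = c(1, 1, 1, 1),
             p2 = c(1, 1, 0, 0),
             p3 = c(0, 0, 0, 0),
             p4 = c(0, 0, 0, 0))
  cm <- count_matrix(m, rownames(m), paste0("c", 1:4), "peak")
  peaks <- peak_set(rep("chr1", 4), c(0, 1000, 5000, 9000),
                    c(500, 1500, 5500, 9500), id = rownames(m))
  genes <- gene_annotation("tf1", "TF1", "chr1", 1, 1400, "+")
  fa <- fold_accessibility(cm, peaks, "TF1", genes, cell_subset = paste0("c", 1:4))
  expect_equal(fa, (4 + 2) / 2 / 1.5)   # = 2.0

  # invariant to positive rescaling (zero pattern only)
  cm2 <- count_matrix(m * 0.0037, rownames(m), paste0("c", 1:4), "peak")
  expect_equal(fold_accessibility(cm2, peaks, "TF1", genes,
                                  cell_subset = paste0("c", 1:4)), fa)

  # gene peaks at the global mean give exactly 1
  m3 <- rbind(p1 = c(1, 1, 0, 0), p2 = c(1, 1, 0, 0))
  cm3 <- count_matrix(m3, rownames(m3), paste0("c", 1:4), "peak")
  expect_equal(fold_accessibility(cm3, peaks[1:2], "TF1", genes,
                                  cell_subset = paste0("c", 1:4)), 1)

  # TSS-restricted variant uses only the TSS-overlapping peak
  fa_tss <- fold_accessibility(cm, peaks, "TF1", genes,
                               cell_subset = paste0("c", 1:4), tss_only = TRUE)
  expect_equal(fa_tss, 4 / 1.5)

  expect_error(fold_accessibility(cm, peaks, "TF1",
                                  gene_annotation("far", "FAR", "chr9", 1, 10, "+"),
                                  cell_subset = paste0("c", 1:4)),
               "not found|not covered")
  genes_far <- gene_annotation("far", "FAR", "chr1", 100000, 100100, "+")
  expect_error(fold_accessibility(cm, peaks, "FAR", genes_far,
                                  cell_subset = paste0("c", 1:4)), "not covered")
  expect_error(fold_accessibility(cm3, peaks[1:2], "TF1", genes,
                                  cell_subset = c("c3", "c4")),
               "inaccessible")
})
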