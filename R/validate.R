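## Multi-omic validation: rank genes per pattern from an RNA factorization
## with the PatternMarker statistic, test TF regulons against the ranking by
## preranked GSEA (weighted Kolmogorov-Smirnov running sum with seeded
## gene-label permutations), and intersect with the scATAC TF candidates.

#' Rank genes by association with one pattern
#'
#' Genes are scored by the negated PatternMarker distance to the pattern's
#' unit vector (higher = more uniquely associated with the pattern) and
#' returned in descending score order. All-zero gene rows are excluded with
#' a warning.
#'
#' @param rna_result a \code{FactorizationResult} from an expression matrix
#'   (genes x cells).
#' @param pattern pattern index or name.
#' @return A \code{RankedGeneList} data.frame with columns \code{gene} and
#'   \code{score}, best first; no duplicate genes, all scores finite.
#' @export
rank_genes_for_pattern <- function(rna_result, pattern) {
  stopifnot(inherits(rna_result, "FactorizationResult"))
  A <- rna_result$A
  if (is.character(pattern)) pattern <- match(pattern, colnames(A))
  if (is.na(pattern) || pattern < 1 || pattern > ncol(A))
    stop("invalid pattern index")
  zero <- rowSums(A) == 0
  if (any(zero)) {
    warning(sprintf("excluding %d all-zero gene row(s)", sum(zero)))
    A <- A[!zero, , drop = FALSE]
  }
  pm <- pattern_marker(A)
  score <- -pm$score[, pattern]
  ord <- order(score, decreasing = TRUE)
  data.frame(gene = rownames(A)[ord], score = unname(score[ord]),
             stringsAsFactors = FALSE)
}

## weighted-KS enrichment score (weight exponent 1 on |score|) of the genes
## at positions `hits` (logical over the ranking, best first)
.gsea_es <- function(hits, weights) {
  w <- abs(weights)
  n <- length(hits)
  n_hit <- sum(hits)
  if (n_hit == 0 || n_hit == n) return(NA_real_)
  wh <- w * hits
  denom_hit <- sum(wh)
  if (denom_hit == 0) {                      # all hit weights zero: uniform
    wh <- as.numeric(hits)
    denom_hit <- n_hit
  }
  p_hit <- cumsum(wh) / denom_hit
  p_miss <- cumsum(!hits) / (n - n_hit)
  run <- p_hit - p_miss
  run[which.max(abs(run))]
}

#' Preranked GSEA of TF regulons against a gene ranking
#'
#' Classical preranked gene set enrichment: the running-sum weighted
#' Kolmogorov-Smirnov enrichment score (weight exponent 1 on the absolute
#' ranking score), with p-values from seeded gene-label permutations
#' (regulons are compared to random gene sets of the same size) and
#' Benjamini-Hochberg correction across the tested TFs. Only the supplied
#' regulons are tested; in the multi-omic workflow these are the TFs
#' nominated by the scATAC-seq analysis. Regulons with fewer than
#' \code{min_size} members present in the ranking are skipped and recorded.
#' A regulon covering the entire ranking is degenerate and also skipped.
#'
#' @param ranking a \code{RankedGeneList} (see
#'   \code{\link{rank_genes_for_pattern}}).
#' @param regulons named list TF -> character vector of target genes.
#' @param n_permutations number of gene-label permutations (default 10000).
#' @param seed RNG seed for the permutations.
#' @param min_size minimum represented regulon size (default 5).
#' @return A \code{GseaResult} data.frame with columns \code{tf},
#'   \code{enrichment_score}, \code{p_value}, \code{q_value},
#'   \code{n_targets_in_ranking}; attribute \code{skipped} lists TFs not
#'   tested and why.
#' @export
preranked_gsea <- function(ranking, regulons, n_permutations = 10000,
                           seed = 42, min_size = 5) {
  if (anyDuplicated(ranking$gene)) stop("ranking contains duplicate genes")
  if (!all(is.finite(ranking$score))) stop("ranking scores must be finite")
  ord <- order(ranking$score, decreasing = TRUE)
  genes <- ranking$gene[ord]
  weights <- ranking$score[ord]
  n <- length(genes)
  sizes <- vapply(regulons, function(r) sum(unique(r) %in% genes), integer(1))
  skipped <- character(0)
  test <- names(regulons)[sizes >= min_size & sizes < n]
  sk <- names(regulons)[sizes < min_size]
  if (length(sk))
    skipped <- c(skipped, setNames(rep("below min_size", length(sk)), sk))
  dg <- names(regulons)[sizes >= n]
  if (length(dg))
    skipped <- c(skipped, setNames(rep("covers entire ranking (degenerate)", length(dg)), dg))
  if (length(test) == 0) {
    warning("no regulon eligible for testing")
    out <- data.frame(tf = character(0), enrichment_score = numeric(0),
                      p_value = numeric(0), q_value = numeric(0),
                      n_targets_in_ranking = integer(0))
    attr(out, "skipped") <- skipped
    return(out)
  }
  set.seed(seed)
  rows <- lapply(test, function(tf) {
    members <- unique(regulons[[tf]])
    hits <- genes %in% members
    k <- sum(hits)
    es <- .gsea_es(hits, weights)
    null_es <- vapply(seq_len(n_permutations), function(b) {
      h <- logical(n)
      h[sample.int(n, k)] <- TRUE
      .gsea_es(h, weights)
    }, numeric(1))
    ## one-sided in the direction of the observed ES, as in classical GSEA
    same_side <- if (es >= 0) null_es[null_es >= 0] else null_es[null_es < 0]
    p <- (sum(abs(same_side) >= abs(es)) + 1) / (length(same_side) + 1)
    data.frame(tf = tf, enrichment_score = es, p_value = p,
               n_targets_in_ranking = k, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_adjust(out$p_value)
  out <- out[, c("tf", "enrichment_score", "p_value", "q_value",
                 "n_targets_in_ranking")]
  attr(out, "skipped") <- skipped
  out[order(out$p_value), , drop = FALSE]
}

#' TFs supported by both scATAC and scRNA evidence
#'
#' Intersects the scATAC-derived TF candidates with the GSEA results and
#' returns the candidates whose regulon enrichment passes the FDR cutoff.
#'
#' @param atac_candidates \code{TfEnrichment} table from
#'   \code{\link{tf_enrichment}}.
#' @param gsea \code{GseaResult} from \code{\link{preranked_gsea}}.
#' @param alpha FDR cutoff in (0, 1), default 0.05.
#' @param fold_acc optional named numeric of fold accessibilities per TF.
#' @return data.frame of supported TFs with enrichment score, q-value and
#'   fold accessibility where available.
#' @export
validate_tfs <- function(atac_candidates, gsea, alpha = 0.05,
                         fold_acc = NULL) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0, 1)")
  if (nrow(atac_candidates) == 0)
    return(data.frame(tf = character(0), enrichment_score = numeric(0),
                      q_value = numeric(0), fold_accessibility = numeric(0)))
  m <- merge(atac_candidates[, c("tf_name", "n_marker_peaks_with_site")],
             gsea, by.x = "tf_name", by.y = "tf")
  m <- m[m$q_value <= alpha, , drop = FALSE]
  if (nrow(m) == 0)
    return(data.frame(tf = character(0), enrichment_score = numeric(0),
                      q_value = numeric(0), fold_accessibility = numeric(0)))
  data.frame(tf = m$tf_name, enrichment_score = m$enrichment_score,
             q_value = m$q_value,
             fold_accessibility =
               if (is.null(fold_acc)) NA_real_ else unname(fold_acc[m$tf]),
             stringsAsFactors = FALSE, row.names = NULL)
}
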