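## Transfer learning: project patterns learned in one data set into another
## over a matched feature space by per-cell ordinary least squares, then test
## pattern-group associations in the target.

#' Match features between a source and a target data set
#'
#' Peak mode pairs every source/target peak with >= 1 bp interval overlap,
#' reduced to a one-to-one matching greedily by descending overlap length
#' (ties to the lower source coordinate). Motif/id mode intersects
#' identifiers exactly.
#'
#' @param source,target named \code{GRanges} (peak mode) or character id
#'   vectors (motif / shared-id mode).
#' @param mode one of \code{"peak_overlap"}, \code{"shared_motif"},
#'   \code{"shared_id"}.
#' @return A \code{FeatureMatching} data.frame with columns
#'   \code{source_feature_id}, \code{target_feature_id} and attribute
#'   \code{match_mode}.
#' @export
match_features <- function(source, target,
                           mode = c("peak_overlap", "shared_motif", "shared_id")) {
  mode <- match.arg(mode)
  if (mode == "peak_overlap") {
    hits <- GenomicRanges::findOverlaps(source, target)
    if (length(hits) == 0) stop("no shared feature space: no overlapping peaks")
    qi <- S4Vectors::queryHits(hits)
    si <- S4Vectors::subjectHits(hits)
    ov_width <- GenomicRanges::width(IRanges::pintersect(
      GenomicRanges::ranges(source)[qi], GenomicRanges::ranges(target)[si]))
    ord <- order(-ov_width, GenomicRanges::start(source)[qi], qi, si)
    used_s <- logical(length(source))
    used_t <- logical(length(target))
    keep <- logical(length(ord))
    for (r in ord) {
      if (!used_s[qi[r]] && !used_t[si[r]]) {
        keep[r] <- TRUE
        used_s[qi[r]] <- TRUE
        used_t[si[r]] <- TRUE
      }
    }
    pairs <- data.frame(source_feature_id = names(source)[qi[keep]],
                        target_feature_id = names(target)[si[keep]],
                        stringsAsFactors = FALSE)
  } else {
    shared <- intersect(as.character(source), as.character(target))
    if (length(shared) == 0) stop("no shared feature space: no common identifiers")
    pairs <- data.frame(source_feature_id = shared, target_feature_id = shared,
                        stringsAsFactors = FALSE)
  }
  attr(pairs, "match_mode") <- mode
  pairs
}

#' Project learned patterns into a target data set
#'
#' Restricts the source amplitude matrix A and the target counts to the
#' matched feature space (same order), then solves an ordinary least squares
#' problem per target cell: the projected pattern weights of cell j are
#' \eqn{\hat p_j = \arg\min_p \|c_j - \tilde A p\|_2}. Weights are
#' unconstrained; negative values indicate anti-correlation with a pattern
#' and are preserved.
#'
#' @param A_source features x n amplitude matrix with feature ids as
#'   rownames.
#' @param matching a \code{FeatureMatching} from \code{\link{match_features}}.
#' @param target_matrix a \code{CountMatrix} for the target data set.
#' @return A \code{ProjectionResult}: list with \code{P_projected} (n x
#'   target cells), \code{matching}, and \code{condition_number} of the
#'   restricted amplitude matrix.
#' @export
project <- function(A_source, matching, target_matrix) {
  stopifnot(is_count_matrix(target_matrix))
  src_idx <- match(matching$source_feature_id, rownames(A_source))
  tgt_idx <- match(matching$target_feature_id, feature_ids(target_matrix))
  if (anyNA(src_idx)) stop("matching names source features absent from A")
  if (anyNA(tgt_idx)) stop("matching names target features absent from the target matrix")
  At <- A_source[src_idx, , drop = FALSE]
  n <- ncol(At)
  if (nrow(At) < n)
    stop(sprintf("only %d matched features for %d patterns", nrow(At), n))
  sv <- svd(At, nu = 0, nv = 0)$d
  cond <- sv[1] / sv[length(sv)]
  if (!is.finite(cond) || sv[length(sv)] < 1e-10 * sv[1])
    stop(sprintf("matched amplitude matrix is rank deficient (condition number %.3g)",
                 cond))
  Ct <- as.matrix(target_matrix$values[tgt_idx, , drop = FALSE])
  P_hat <- qr.coef(qr(At), Ct)
  rownames(P_hat) <- colnames(At) %||% paste0("Pattern_", seq_len(n))
  colnames(P_hat) <- cell_ids(target_matrix)
  structure(list(P_projected = P_hat, matching = matching,
                 condition_number = cond,
                 target_labels = target_matrix$cell_labels),
            class = "ProjectionResult")
}

#' Group association of projected patterns in the target data set
#'
#' Runs the pairwise Wilcoxon group tests of
#' \code{\link{group_association}} on the projected pattern weights, and for
#' each pattern reports the group most significantly elevated (the group
#' with the larger median weight in the most significant pair involving
#' it).
#'
#' @param result a \code{ProjectionResult}.
#' @param target_labels group label per target cell; defaults to the labels
#'   carried by the target \code{CountMatrix}.
#' @return list with \code{tests} (the full pairwise table) and \code{top}
#'   (data.frame: pattern, group, q_value of its most significant pair).
#' @export
projected_group_test <- function(result, target_labels = NULL) {
  stopifnot(inherits(result, "ProjectionResult"))
  labels <- target_labels %||% result$target_labels
  if (is.null(labels)) stop("no target labels available")
  tests <- group_association(result$P_projected, labels)
  P <- result$P_projected
  top <- do.call(rbind, lapply(unique(tests$pattern), function(pt) {
    sub <- tests[tests$pattern == pt, ]
    best <- sub[which.min(sub$q_value), ]
    meds <- tapply(P[pt, ], labels, stats::median)
    winner <- if (meds[[best$group1]] >= meds[[best$group2]]) best$group1
              else best$group2
    data.frame(pattern = pt, group = winner, q_value = best$q_value,
               stringsAsFactors = FALSE)
  }))
  list(tests = tests, top = top)
}
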