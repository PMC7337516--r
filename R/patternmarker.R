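## PatternMarker statistic: assign items (features or cells) to the pattern
## whose unit vector their max-scaled weight row is closest to, rank markers
## per pattern, and quantify clustering agreement with the adjusted Rand
## index.

#' PatternMarker scores and assignments
#'
#' For each item (a row of \code{weights}), the row is scaled by its maximum
#' and the Euclidean distance to each pattern's unit vector is computed;
#' lower distance means the item's weight is more uniquely high in that
#' pattern. Each item is assigned to its arg-min pattern. Ties are broken to
#' the lowest pattern index and flagged ambiguous; all-zero rows are left
#' unassigned with a warning, never dropped.
#'
#' @param weights non-negative items x n matrix with rownames as item ids.
#' @return A \code{PatternMarkerResult}: list with \code{score} (items x n,
#'   lower = more marker-like), \code{assignment} (integer pattern index per
#'   item, NA when unassigned), \code{ambiguous} (logical per item), and
#'   \code{markers} (per-pattern character vectors of item ids, best first).
#' @export
pattern_marker <- function(weights) {
  weights <- as.matrix(weights)
  if (is.null(rownames(weights)))
    rownames(weights) <- paste0("item_", seq_len(nrow(weights)))
  if (any(weights < 0)) stop("weights must be non-negative")
  n <- ncol(weights)
  if (n < 1) stop("need at least one pattern")
  rmax <- apply(weights, 1, max)
  zero <- rmax == 0
  if (any(zero))
    warning(sprintf("%d item(s) have all-zero weights and are unassigned", sum(zero)))
  scaled <- weights / ifelse(rmax == 0, 1, rmax)
  ## distance to k-th unit vector: ||w||^2 - 2 w_k + 1
  sq <- rowSums(scaled^2)
  score <- sqrt(pmax(sweep(-2 * scaled, 1, sq + 1, `+`), 0))
  dimnames(score) <- dimnames(weights)
  assignment <- max.col(-score, ties.method = "first")
  ambiguous <- vapply(seq_len(nrow(score)), function(i) {
    s <- score[i, ]
    sum(abs(s - min(s)) < 1e-12) > 1
  }, logical(1))
  assignment[zero] <- NA_integer_
  ambiguous[zero] <- FALSE
  names(assignment) <- names(ambiguous) <- rownames(weights)
  markers <- lapply(seq_len(n), function(k) {
    in_k <- which(!is.na(assignment) & assignment == k)
    ids <- rownames(weights)[in_k]
    ids[order(score[in_k, k])]
  })
  names(markers) <- colnames(weights) %||% paste0("Pattern_", seq_len(n))
  structure(list(score = score, assignment = assignment,
                 ambiguous = ambiguous, markers = markers),
            class = "PatternMarkerResult")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign each cell to its defining pattern
#'
#' Applies the PatternMarker statistic to the columns of the pattern matrix P
#' (i.e. to \code{t(P)}), clustering cells to the pattern each is most
#' uniquely defined by.
#'
#' @param result a \code{FactorizationResult}.
#' @return A \code{PatternMarkerResult} over cells (see
#'   \code{\link{pattern_marker}}).
#' @export
assign_cells <- function(result) {
  stopifnot(inherits(result, "FactorizationResult"))
  pattern_marker(t(result$P))
}

#' Marker features per pattern
#'
#' PatternMarker applied to the rows of the amplitude matrix A, optionally
#' truncated to the top-k best-ranked markers per pattern. All features are
#' retained by default.
#'
#' @param result a \code{FactorizationResult}.
#' @param top_k optional cut: keep at most this many markers per pattern.
#' @return A \code{PatternMarkerResult} over features.
#' @export
marker_features <- function(result, top_k = NULL) {
  stopifnot(inherits(result, "FactorizationResult"))
  pm <- pattern_marker(result$A)
  if (!is.null(top_k))
    pm$markers <- lapply(pm$markers, head, n = top_k)
  pm
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected pair-counting agreement under the permutation model,
#' computed in closed form from the contingency table.
#'
#' @param labels_a,labels_b label vectors of equal length >= 2 (any atomic
#'   type; NAs not allowed).
#' @return ARI in [-1, 1]; 1 for identical partitions up to relabeling.
#' @export
adjusted_rand_index <- function(labels_a, labels_b) {
  if (length(labels_a) != length(labels_b))
    stop(sprintf("label vectors differ in length (%d vs %d)",
                 length(labels_a), length(labels_b)))
  if (length(labels_a) < 2) stop("need at least 2 items")
  if (anyNA(labels_a) || anyNA(labels_b)) stop("labels must not contain NA")
  tab <- table(labels_a, labels_b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(length(labels_a))
  expected <- sum_a * sum_b / n2
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

#' Pattern-group association by pairwise Wilcoxon tests
#'
#' For each pattern (row of P), runs a two-sided Wilcoxon rank-sum test on
#' the pattern weights for every pair of a priori cell groups, with
#' Benjamini-Hochberg correction across all pairs within the pattern. The
#' exact distribution is used when both groups have <= \code{exact_max}
#' cells and no ties; otherwise the normal approximation with continuity and
#' tie correction. Groups with fewer than 2 cells are excluded with a
#' warning.
#'
#' @param P patterns x cells numeric matrix.
#' @param cell_labels group label per cell.
#' @param exact_max exactness cutoff per group (default 10).
#' @return data.frame with columns \code{pattern}, \code{group1},
#'   \code{group2}, \code{p_value}, \code{q_value}.
#' @export
group_association <- function(P, cell_labels, exact_max = 10) {
  P <- as.matrix(P)
  if (length(cell_labels) != ncol(P))
    stop("cell_labels must have one entry per cell")
  cell_labels <- as.character(cell_labels)
  sizes <- table(cell_labels)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning(sprintf("excluding group(s) with < 2 cells: %s",
                    paste(small, collapse = ", ")))
    keep <- !(cell_labels %in% small)
    P <- P[, keep, drop = FALSE]
    cell_labels <- cell_labels[keep]
  }
  groups <- sort(unique(cell_labels))
  if (length(groups) < 2) stop("need at least 2 groups with >= 2 cells")
  pairs <- utils::combn(groups, 2)
  pat_names <- rownames(P) %||% paste0("Pattern_", seq_len(nrow(P)))
  out <- do.call(rbind, lapply(seq_len(nrow(P)), function(k) {
    w <- P[k, ]
    p <- apply(pairs, 2, function(gp) {
      x <- w[cell_labels == gp[1]]
      y <- w[cell_labels == gp[2]]
      exact <- length(x) <= exact_max && length(y) <= exact_max &&
        !any(duplicated(c(x, y)))
      suppressWarnings(
        wilcox.test(x, y, alternative = "two.sided", exact = exact,
                    correct = TRUE)$p.value)
    })
    data.frame(pattern = pat_names[k], group1 = pairs[1, ], group2 = pairs[2, ],
               p_value = p, q_value = bh_adjust(p),
               stringsAsFactors = FALSE, row.names = NULL)
  }))
  out
}

#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin named wrapper over \code{stats::p.adjust(method = "BH")}, used for
#' every FDR correction in the package.
#'
#' @param p numeric vector of p-values.
#' @return q-values, same length and order as \code{p}.
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")
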