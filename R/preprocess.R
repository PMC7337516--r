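## Preprocessing: sparsity filtering, peak-width normalization, motif-level
## summarization and binarization of accessibility counts.

#' Filter features and cells that are almost entirely zero
#'
#' Removes every feature and every cell whose fraction of exact zeros
#' exceeds \code{threshold} (strictly), the standard sparsity filter applied
#' before factorizing single-cell ATAC-seq counts. Both axes are evaluated
#' simultaneously on the input matrix (a single pass, not iterated), so the
#' reported removal counts do not depend on axis order.
#'
#' @param matrix a \code{CountMatrix}.
#' @param threshold maximum tolerated zero fraction, in (0, 1]. The default
#'   0.99 removes anything more than 99\% zero.
#' @return list with \code{matrix} (the filtered \code{CountMatrix}) and
#'   \code{report}, a \code{FilterReport} list with
#'   \code{n_features_removed}, \code{n_cells_removed},
#'   \code{kept_feature_ids}, \code{kept_cell_ids},
#'   \code{sparsity_threshold}.
#' @export
filter_sparse <- function(matrix, threshold = 0.99) {
  stopifnot(is_count_matrix(matrix))
  if (!(threshold > 0 && threshold <= 1))
    stop("threshold must be in (0, 1]")
  v <- matrix$values
  nz_row <- Matrix::rowSums(v != 0)
  nz_col <- Matrix::colSums(v != 0)
  keep_f <- (1 - nz_row / ncol(v)) <= threshold
  keep_c <- (1 - nz_col / nrow(v)) <= threshold
  if (!any(keep_f) || !any(keep_c))
    stop("matrix too sparse: filtering removed all features or all cells")
  out <- count_matrix(v[keep_f, keep_c, drop = FALSE],
                      feature_ids = feature_ids(matrix)[keep_f],
                      cell_ids = cell_ids(matrix)[keep_c],
                      feature_kind = matrix$feature_kind,
                      cell_labels = if (is.null(matrix$cell_labels)) NULL
                                    else matrix$cell_labels[keep_c])
  report <- structure(list(
    n_features_removed = sum(!keep_f),
    n_cells_removed = sum(!keep_c),
    kept_feature_ids = feature_ids(out),
    kept_cell_ids = cell_ids(out),
    sparsity_threshold = threshold), class = "FilterReport")
  list(matrix = out, report = report)
}

#' Normalize peak counts by peak width
#'
#' Divides each feature row by the nucleotide width of its peak, the
#' correction applied when peaks were not called at a fixed width. Zeros stay
#' zero.
#'
#' @param matrix a \code{CountMatrix} with \code{feature_kind == "peak"}.
#' @param peaks \code{GRanges} carrying every matrix feature id in its names.
#' @return A width-normalized \code{CountMatrix}.
#' @export
normalize_by_width <- function(matrix, peaks) {
  stopifnot(is_count_matrix(matrix))
  if (matrix$feature_kind != "peak")
    stop("width normalization applies to peak matrices only")
  idx <- match(feature_ids(matrix), names(peaks))
  if (anyNA(idx))
    stop(sprintf("missing peak interval(s) for feature id(s): %s",
                 paste(head(feature_ids(matrix)[is.na(idx)], 5), collapse = ", ")))
  w <- GenomicRanges::width(peaks)[idx]
  out <- Matrix::Diagonal(x = 1 / w) %*% matrix$values
  count_matrix(out, feature_ids = feature_ids(matrix),
               cell_ids = cell_ids(matrix), feature_kind = "peak",
               cell_labels = matrix$cell_labels)
}

#' Summarize a peak matrix to motif-level counts
#'
#' Aggregates raw peak counts into motif counts: the count of motif m in cell
#' j is the sum over all peaks matched to m of the peak's count in j. Motifs
#' matching no peak are dropped with a warning.
#'
#' @param matrix a peak \code{CountMatrix}.
#' @param matches binary peaks x motifs match matrix (see
#'   \code{\link{motif_match_matrix}} / \code{\link{scan_motifs}}); its peak
#'   ids must cover the matrix feature ids.
#' @return A \code{CountMatrix} with \code{feature_kind == "motif"}.
#' @export
summarize_to_motifs <- function(matrix, matches) {
  stopifnot(is_count_matrix(matrix))
  missing <- setdiff(feature_ids(matrix), rownames(matches))
  if (length(missing))
    stop(sprintf("match matrix lacks %d peak id(s), e.g. %s",
                 length(missing), missing[1]))
  mm <- matches[feature_ids(matrix), , drop = FALSE]
  hits <- Matrix::colSums(mm) > 0
  if (!all(hits)) {
    warning(sprintf("dropping %d motif(s) matching no peak: %s", sum(!hits),
                    paste(head(colnames(mm)[!hits], 5), collapse = ", ")))
    mm <- mm[, hits, drop = FALSE]
  }
  if (ncol(mm) == 0) stop("no motif matches any peak in the matrix")
  out <- Matrix::t(mm) %*% matrix$values
  count_matrix(out, feature_ids = colnames(mm), cell_ids = cell_ids(matrix),
               feature_kind = "motif", cell_labels = matrix$cell_labels)
}

#' Binarize counts to accessible / not accessible
#'
#' @param matrix a \code{CountMatrix}.
#' @return A \code{CountMatrix} with entries 1 where the input is positive,
#'   else 0. Any normalization is irrelevant: accessibility is count > 0.
#' @export
binarize <- function(matrix) {
  stopifnot(is_count_matrix(matrix))
  v <- matrix$values
  v@x <- as.numeric(v@x > 0)
  v <- Matrix::drop0(v)
  count_matrix(v, feature_ids = feature_ids(matrix),
               cell_ids = cell_ids(matrix),
               feature_kind = matrix$feature_kind,
               cell_labels = matrix$cell_labels)
}
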