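## Domain containers. Deliberately light S3 wrappers around the field's
## standard objects: sparse matrices from Matrix, intervals as GRanges.

#' Construct a CountMatrix
#'
#' A features-by-cells non-negative count matrix with identifiers, the
#' central data container of the package. Values are stored sparse
#' (\code{dgCMatrix}); real (e.g. width-normalized) values are allowed.
#'
#' @param values numeric matrix or Matrix, features x cells, non-negative.
#' @param feature_ids character, unique, length \code{nrow(values)}.
#' @param cell_ids character, unique, length \code{ncol(values)}.
#' @param feature_kind one of \code{"peak"}, \code{"motif"}, \code{"gene"}.
#' @param cell_labels optional character vector of a priori population labels
#'   (one per cell), e.g. FACS or cell-line annotations used for validation.
#' @return An object of class \code{CountMatrix}.
#' @export
count_matrix <- function(values, feature_ids = rownames(values),
                         cell_ids = colnames(values),
                         feature_kind = c("peak", "motif", "gene"),
                         cell_labels = NULL) {
  feature_kind <- match.arg(feature_kind)
  values <- methods::as(methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                                "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (is.null(feature_ids) || is.null(cell_ids))
    stop("feature_ids and cell_ids are required")
  feature_ids <- as.character(feature_ids)
  cell_ids <- as.character(cell_ids)
  if (length(feature_ids) != nrow(values))
    stop(sprintf("feature_ids length (%d) does not match row count (%d)",
                 length(feature_ids), nrow(values)))
  if (length(cell_ids) != ncol(values))
    stop(sprintf("cell_ids length (%d) does not match column count (%d)",
                 length(cell_ids), ncol(values)))
  if (anyDuplicated(feature_ids)) stop("feature_ids must be unique")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (length(values@x) && min(values@x) < 0)
    stop("negative entries are not allowed in a CountMatrix")
  if (!is.null(cell_labels)) {
    cell_labels <- as.character(cell_labels)
    if (length(cell_labels) != length(cell_ids))
      stop("cell_labels must have one entry per cell")
  }
  dimnames(values) <- list(feature_ids, cell_ids)
  structure(list(values = values, feature_kind = feature_kind,
                 cell_labels = cell_labels),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

#' @export
print.CountMatrix <- function(x, ...) {
  d <- dim(x$values)
  nz <- length(x$values@x)
  cat(sprintf("CountMatrix: %d %ss x %d cells (%.1f%% nonzero)%s\n",
              d[1], x$feature_kind, d[2], 100 * nz / prod(d),
              if (is.null(x$cell_labels)) "" else ", labeled"))
  invisible(x)
}

#' Feature and cell identifiers of a CountMatrix
#' @param x a \code{CountMatrix}.
#' @return character vector of identifiers.
#' @export
feature_ids <- function(x) rownames(x$values)

#' @rdname feature_ids
#' @export
cell_ids <- function(x) colnames(x$values)

is_count_matrix <- function(x) inherits(x, "CountMatrix")

#' Build a PeakSet from BED-style coordinates
#'
#' Peaks are kept as a named \code{GRanges}. Input coordinates follow the BED
#' convention (0-based start, half-open); they are converted to the 1-based
#' closed convention GRanges uses, so overlap algebra is handled by
#' GenomicRanges throughout.
#'
#' @param chrom character chromosome names.
#' @param start integer 0-based inclusive starts.
#' @param end integer exclusive ends; must satisfy \code{end > start}.
#' @param id peak identifiers; default \code{"chrom:start-end"} in the BED
#'   coordinates of the source.
#' @return A \code{GRanges} with unique names (the peak ids).
#' @export
peak_set <- function(chrom, start, end, id = NULL) {
  if (any(end <= start)) stop("peak end must be greater than start")
  if (any(start < 0)) stop("peak start must be non-negative")
  if (is.null(id)) id <- sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
  if (anyDuplicated(id)) stop("peak ids must be unique")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start + 1L, end))
  names(gr) <- id
  gr
}

#' Build a gene annotation table
#'
#' @param gene_id unique gene identifiers.
#' @param symbol gene symbols (default the ids).
#' @param chrom,start,end gene body in 1-based closed coordinates (GRanges
#'   convention; use \code{\link{read_gene_annotation}} for GTF input).
#' @param strand "+" or "-".
#' @return A named \code{GRanges} with metadata columns \code{symbol} and
#'   \code{tss} (the strand-aware transcription start coordinate).
#' @export
gene_annotation <- function(gene_id, symbol = gene_id, chrom, start, end, strand) {
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  if (!all(strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand = strand)
  names(gr) <- gene_id
  gr$symbol <- as.character(symbol)
  gr$tss <- ifelse(strand == "+", GenomicRanges::start(gr), GenomicRanges::end(gr))
  gr
}

#' Construct a binary peaks-by-motifs match matrix
#'
#' @param values binary matrix or sparse Matrix (peaks x motifs).
#' @param peak_ids,motif_ids identifiers matching the matrix dimensions.
#' @return A sparse \code{dgCMatrix} of 0/1 with peak ids as rownames and
#'   motif ids as colnames.
#' @export
motif_match_matrix <- function(values, peak_ids = rownames(values),
                               motif_ids = colnames(values)) {
  m <- methods::as(methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                           "dMatrix"), "generalMatrix"), "CsparseMatrix")
  m <- Matrix::drop0(m)
  if (length(m@x) && !all(m@x == 1))
    stop("motif match matrix entries must be 0 or 1")
  if (is.null(peak_ids) || is.null(motif_ids))
    stop("peak_ids and motif_ids are required")
  dimnames(m) <- list(as.character(peak_ids), as.character(motif_ids))
  m
}
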