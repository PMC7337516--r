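## Readers and writers for the external formats the pipeline touches.
## Parsing of standard formats is delegated to Matrix (MTX), rtracklayer
## (GTF), Biostrings (FASTA) and fgsea (GMT); JASPAR text and TRRUST-style
## regulon TSVs are parsed here.

#' Read a peak-by-cell count matrix
#'
#' Loads a MatrixMarket counts file together with its BED peak intervals and
#' barcode file, validates that the three agree, and returns a matched
#' \code{CountMatrix} / peak \code{GRanges} pair. File order is preserved on
#' both axes.
#'
#' @param mtx_path MatrixMarket file, features x cells.
#' @param peaks_bed_path BED3+ file; a 4th column is used as the peak id when
#'   present, otherwise ids default to \code{"chrom:start-end"}.
#' @param barcodes_path TSV of cell barcodes, one row per cell. An optional
#'   3rd column supplies a priori population labels (a 2-column file is also
#'   accepted, with labels in column 2).
#' @return list with elements \code{matrix} (\code{CountMatrix}) and
#'   \code{peaks} (\code{GRanges}).
#' @export
read_peak_matrix <- function(mtx_path, peaks_bed_path, barcodes_path) {
  m <- methods::as(Matrix::readMM(mtx_path), "dMatrix")
  bed <- utils::read.delim(peaks_bed_path, header = FALSE,
                           stringsAsFactors = FALSE)
  if (ncol(bed) < 3) stop("BED file must have at least 3 columns")
  bc <- utils::read.delim(barcodes_path, header = FALSE,
                          stringsAsFactors = FALSE)
  if (nrow(bed) != nrow(m))
    stop(sprintf("dimension mismatch: MTX has %d rows but BED has %d records",
                 nrow(m), nrow(bed)))
  if (nrow(bc) != ncol(m))
    stop(sprintf("dimension mismatch: MTX has %d columns but barcode file has %d records",
                 ncol(m), nrow(bc)))
  if (length(m@x) && min(m@x) < 0)
    stop("count matrix contains negative values")
  ids <- if (ncol(bed) >= 4) as.character(bed[[4]]) else NULL
  peaks <- peak_set(bed[[1]], bed[[2]], bed[[3]], id = ids)
  labels <- if (ncol(bc) >= 3) as.character(bc[[3]])
            else if (ncol(bc) == 2) as.character(bc[[2]])
            else NULL
  cm <- count_matrix(m, feature_ids = names(peaks),
                     cell_ids = as.character(bc[[1]]),
                     feature_kind = "peak", cell_labels = labels)
  list(matrix = cm, peaks = peaks)
}

#' Write a CountMatrix (plus peaks/barcodes) to disk
#'
#' Inverse of \code{\link{read_peak_matrix}}: MatrixMarket values, BED
#' intervals (0-based half-open, id in column 4) and a barcode TSV with an
#' optional label column.
#'
#' @param x a \code{CountMatrix}.
#' @param dir output directory (created if missing).
#' @param peaks \code{GRanges} matching the features (required when
#'   \code{feature_kind == "peak"}).
#' @return Invisibly, the paths written.
#' @export
write_peak_matrix <- function(x, dir, peaks = NULL) {
  stopifnot(is_count_matrix(x))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mtx <- file.path(dir, "matrix.mtx")
  Matrix::writeMM(x$values, mtx)
  paths <- c(matrix = mtx)
  if (x$feature_kind == "peak") {
    if (is.null(peaks)) stop("peaks are required to write a peak matrix")
    if (!identical(names(peaks), feature_ids(x)))
      stop("peak ids do not match matrix feature ids")
    bed <- file.path(dir, "peaks.bed")
    utils::write.table(
      data.frame(as.character(GenomicRanges::seqnames(peaks)),
                 GenomicRanges::start(peaks) - 1L,
                 GenomicRanges::end(peaks), names(peaks)),
      bed, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    paths <- c(paths, peaks = bed)
  } else {
    feat <- file.path(dir, "features.tsv")
    writeLines(feature_ids(x), feat)
    paths <- c(paths, features = feat)
  }
  bcp <- file.path(dir, "barcodes.tsv")
  if (is.null(x$cell_labels)) {
    writeLines(cell_ids(x), bcp)
  } else {
    utils::write.table(data.frame(cell_ids(x), ".", x$cell_labels), bcp,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(c(paths, barcodes = bcp))
}

#' Read gene annotation from a GTF file
#'
#' Uses gene-level records when present, otherwise derives one record per
#' gene as the union (min start, max end) of its transcripts. Records with an
#' unknown strand are skipped with a warning.
#'
#' @param gtf_path path to a GTF file.
#' @return A named \code{GRanges} (see \code{\link{gene_annotation}}).
#' @export
read_gene_annotation <- function(gtf_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  type <- as.character(gr$type)
  sel <- gr[type == "gene"]
  if (length(sel) == 0) {
    tx <- gr[type %in% c("transcript", "mRNA")]
    if (length(tx) == 0) stop("GTF contains no gene or transcript records")
    ## one record per gene spanning the union of its transcripts
    df <- data.frame(gene_id = as.character(tx$gene_id),
                     chrom = as.character(GenomicRanges::seqnames(tx)),
                     start = GenomicRanges::start(tx),
                     end = GenomicRanges::end(tx),
                     strand = as.character(GenomicRanges::strand(tx)),
                     symbol = if (is.null(tx$gene_name)) NA_character_
                              else as.character(tx$gene_name),
                     stringsAsFactors = FALSE)
    by_gene <- split(df, df$gene_id)
    agg <- do.call(rbind, lapply(by_gene, function(g) {
      data.frame(gene_id = g$gene_id[1], chrom = g$chrom[1],
                 start = min(g$start), end = max(g$end),
                 strand = g$strand[1],
                 symbol = if (all(is.na(g$symbol))) g$gene_id[1]
                          else g$symbol[!is.na(g$symbol)][1],
                 stringsAsFactors = FALSE)
    }))
    sel <- GenomicRanges::GRanges(agg$chrom,
                                  IRanges::IRanges(agg$start, agg$end),
                                  strand = agg$strand)
    names(sel) <- agg$gene_id
    sel$gene_id <- agg$gene_id
    sel$gene_name <- agg$symbol
  }
  strand <- as.character(GenomicRanges::strand(sel))
  bad <- !(strand %in% c("+", "-"))
  if (any(bad)) {
    warning(sprintf("skipping %d gene record(s) with unknown strand", sum(bad)))
    sel <- sel[!bad]
    strand <- strand[!bad]
  }
  ids <- if (!is.null(sel$gene_id)) as.character(sel$gene_id) else names(sel)
  sym <- if (!is.null(sel$gene_name)) as.character(sel$gene_name) else ids
  sym[is.na(sym)] <- ids[is.na(sym)]
  gene_annotation(gene_id = ids, symbol = sym,
                  chrom = as.character(GenomicRanges::seqnames(sel)),
                  start = GenomicRanges::start(sel),
                  end = GenomicRanges::end(sel),
                  strand = strand)
}

#' Read a GMT gene-set collection
#'
#' @param path GMT file (set name, description, then member symbols).
#' @return Named list of character vectors; empty sets are dropped with a
#'   warning.
#' @export
read_gmt <- function(path) {
  sets <- fgsea::gmtPathways(path)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning(sprintf("dropping %d empty gene set(s): %s", sum(empty),
                    paste(names(sets)[empty], collapse = ", ")))
    sets <- sets[!empty]
  }
  if (anyDuplicated(names(sets))) stop("gene set names must be unique")
  sets
}

#' Read TF regulons from a TRRUST-style TSV
#'
#' Expects at least two columns: TF symbol and target gene symbol. A third
#' (regulation mode) column is accepted and ignored by all computations.
#'
#' @param path TSV path, no header.
#' @return Named list mapping TF symbol to a character vector of unique
#'   target symbols.
#' @export
read_regulons <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("regulon file must have TF and target columns")
  reg <- lapply(split(as.character(tab[[2]]), as.character(tab[[1]])), unique)
  empty <- lengths(reg) == 0
  if (any(empty)) {
    warning("dropping empty regulon(s)")
    reg <- reg[!empty]
  }
  reg
}

#' Read position weight matrices in JASPAR text format
#'
#' Accepts both the bracketed JASPAR layout (\code{A [ 3 10 ... ]}) and plain
#' whitespace-separated count rows in A, C, G, T order after each
#' \code{>ID NAME} header. Counts are column-normalized to probabilities.
#'
#' @param path JASPAR-format text file.
#' @return List of motifs, each \code{list(id, tf, matrix)} where
#'   \code{matrix} is 4 x L with rows A, C, G, T and columns summing to 1.
#' @export
read_pwms <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  headers <- grep("^>", lines)
  if (length(headers) == 0) stop("no motif headers ('>') found")
  out <- vector("list", length(headers))
  bounds <- c(headers, length(lines) + 1L)
  for (i in seq_along(headers)) {
    hdr <- sub("^>\\s*", "", lines[headers[i]])
    parts <- strsplit(trimws(hdr), "\\s+")[[1]]
    id <- parts[1]
    tf <- if (length(parts) > 1) parts[2] else parts[1]
    body <- lines[(headers[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(body) < 4) stop(sprintf("motif %s: expected 4 count rows", id))
    rows <- lapply(body[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      l <- gsub("[\\[\\]]", "", l, perl = TRUE)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    L <- unique(lengths(rows))
    if (length(L) != 1) stop(sprintf("motif %s: ragged count rows", id))
    if (L < 4) stop(sprintf("motif %s: length %d < 4", id, L))
    mat <- do.call(rbind, rows)
    rownames(mat) <- c("A", "C", "G", "T")
    cs <- colSums(mat)
    if (any(cs <= 0)) stop(sprintf("motif %s: zero column sum", id))
    mat <- sweep(mat, 2, cs, "/")
    out[[i]] <- list(id = id, tf = tf, matrix = mat)
  }
  names(out) <- vapply(out, `[[`, character(1), "id")
  if (anyDuplicated(names(out))) stop("motif ids must be unique")
  out
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return A \code{Biostrings::DNAStringSet} named by contig.
#' @export
read_genome <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

## ---- factorization result serialization ------------------------------

#' Write a factorization result to a directory
#'
#' Persists the amplitude matrix as \code{A.tsv}, the pattern matrix as
#' \code{P.tsv} (full precision) and a JSON run manifest with the
#' configuration, dimensions and fit statistics.
#'
#' @param result a \code{FactorizationResult} from \code{\link{run_cogaps}}.
#' @param dir output directory (created if missing).
#' @return Invisibly, the directory.
#' @export
write_factorization <- function(result, dir) {
  stopifnot(inherits(result, "FactorizationResult"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_mat <- function(m, path) {
    df <- data.frame(id = rownames(m),
                     format(m, digits = 17, scientific = TRUE, trim = TRUE),
                     check.names = FALSE, stringsAsFactors = FALSE)
    colnames(df) <- c("id", colnames(m))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_mat(result$A, file.path(dir, "A.tsv"))
  write_mat(result$P, file.path(dir, "P.tsv"))
  manifest <- list(
    tool = "atacPatterns",
    version = as.character(utils::packageVersion("atacPatterns")),
    config = unclass(result$config),
    dimensions = list(features = nrow(result$A), cells = ncol(result$P),
                      n_patterns = ncol(result$A)),
    final_chi2 = result$final_chi2,
    chi2_trace = result$chi2_trace)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a factorization result written by \code{\link{write_factorization}}
#' @param dir directory containing \code{A.tsv}, \code{P.tsv},
#'   \code{manifest.json}.
#' @return A \code{FactorizationResult}.
#' @export
read_factorization <- function(dir) {
  read_mat <- function(path) {
    df <- utils::read.delim(path, check.names = FALSE,
                            stringsAsFactors = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
    storage.mode(m) <- "double"
    m
  }
  A <- read_mat(file.path(dir, "A.tsv"))
  P <- read_mat(file.path(dir, "P.tsv"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  structure(list(A = A, P = P,
                 chi2_trace = as.numeric(manifest$chi2_trace),
                 final_chi2 = as.numeric(manifest$final_chi2),
                 config = manifest$config),
            class = "FactorizationResult")
}
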