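## Regulatory interpretation of pattern-marker peaks: peak-to-gene matching,
## pathway overlap enrichment, PWM motif scanning with a calibrated score
## threshold, TF enrichment ranking and fold accessibility.

#' Map peaks to genes via body or promoter overlap
#'
#' A gene is linked to a peak when the peak overlaps the gene body or the
#' strand-aware promoter window extending \code{promoter_up} bp upstream and
#' \code{promoter_down} bp downstream of the TSS.
#'
#' @param peaks named \code{GRanges} of peaks.
#' @param genes gene annotation \code{GRanges} (see
#'   \code{\link{gene_annotation}}).
#' @param promoter_up,promoter_down promoter window size in bp (defaults
#'   1500 up / 500 down).
#' @return Named list: peak id -> character vector of gene symbols (empty
#'   when nothing overlaps, e.g. for chromosomes absent from the
#'   annotation).
#' @export
map_peaks_to_genes <- function(peaks, genes, promoter_up = 1500,
                               promoter_down = 500) {
  regions <- suppressWarnings(
    c(GenomicRanges::granges(genes),
      GenomicRanges::promoters(genes, upstream = promoter_up,
                               downstream = promoter_down)))
  gene_of_region <- rep(genes$symbol, 2)
  hits <- suppressWarnings(GenomicRanges::findOverlaps(peaks, regions))
  out <- rep(list(character(0)), length(peaks))
  names(out) <- names(peaks)
  if (length(hits)) {
    by_peak <- split(gene_of_region[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits))
    out[as.integer(names(by_peak))] <- lapply(by_peak, unique)
  }
  out
}

#' Hypergeometric overlap enrichment of query genes in gene sets
#'
#' For each set, tests over-representation of the query genes with the
#' one-sided hypergeometric upper tail P(X >= overlap), where the population
#' is the universe, successes are the set members in the universe and draws
#' are the query genes. Benjamini-Hochberg correction across all sets.
#'
#' @param query_genes character vector of gene symbols; must be contained in
#'   \code{universe}.
#' @param sets named list of gene sets (each intersected with the universe).
#' @param universe character vector of all detectable gene symbols,
#'   typically every symbol mappable from the filtered peak set.
#' @return \code{EnrichmentTable} data.frame with columns \code{set_name},
#'   \code{overlap_count}, \code{set_size}, \code{query_size},
#'   \code{universe_size}, \code{p_value}, \code{q_value}, sorted by
#'   ascending p.
#' @export
pathway_overlap <- function(query_genes, sets, universe) {
  query_genes <- unique(query_genes)
  if (length(query_genes) == 0) stop("query gene list is empty")
  universe <- unique(universe)
  out_u <- setdiff(query_genes, universe)
  if (length(out_u))
    stop(sprintf("%d query gene(s) are not in the universe, e.g. %s",
                 length(out_u), out_u[1]))
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(sets[[nm]], universe)
    ov <- length(intersect(s, query_genes))
    p <- stats::phyper(ov - 1, length(s), length(universe) - length(s),
                       length(query_genes), lower.tail = FALSE)
    data.frame(set_name = nm, overlap_count = ov, set_size = length(s),
               query_size = length(query_genes),
               universe_size = length(universe), p_value = p,
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$q_value <- bh_adjust(tab$p_value)
  tab[order(tab$p_value), , drop = FALSE]
}

## ---- motif scanning ---------------------------------------------------

## Exact tail distribution of the log-odds score of one PWM under a 0-order
## background, by dynamic programming over discretized per-position scores.
## Returns the smallest score threshold whose exceedance probability under
## the background is <= p_threshold; falls back to the maximum achievable
## score when even a perfect match is more probable than p_threshold.
.pwm_threshold <- function(score_mat, bg, p_threshold, resolution = 1000) {
  int_scores <- round(score_mat * resolution)
  dist <- 1          # P(partial score == run_lo + index - 1)
  run_lo <- 0L
  for (j in seq_len(ncol(int_scores))) {
    col <- int_scores[, j]
    new_lo <- run_lo + min(col)
    new_hi <- run_lo + length(dist) - 1L + max(col)
    new <- numeric(new_hi - new_lo + 1L)
    for (b in 1:4) {
      off <- run_lo + col[b] - new_lo
      idx <- seq_along(dist) + off
      new[idx] <- new[idx] + dist * bg[b]
    }
    dist <- new
    run_lo <- new_lo
  }
  tail_p <- rev(cumsum(rev(dist)))   # P(score >= run_lo + i - 1)
  ok <- which(tail_p <= p_threshold)
  if (length(ok) == 0) {
    (run_lo + length(dist) - 1L) / resolution
  } else {
    (run_lo + ok[1] - 1L) / resolution
  }
}

## score every length-L window of an integer-coded sequence (NA for N bases)
.scan_scores <- function(codes, score_mat) {
  L <- ncol(score_mat)
  n <- length(codes) - L + 1L
  if (n < 1) return(numeric(0))
  total <- numeric(n)
  for (off in seq_len(L)) {
    s <- score_mat[codes[off:(off + n - 1L)], off]
    s[is.na(s)] <- -Inf
    total <- total + s
  }
  total
}

#' Scan peaks for PWM motif matches
#'
#' Scores every window of each peak sequence (both strands) with the
#' log-odds of the motif against a 0-order background estimated from the
#' scanned sequences themselves. A peak matches a motif when any window
#' reaches the score threshold calibrated so that a random background
#' sequence exceeds it with probability at most \code{p_threshold}
#' (computed exactly by dynamic programming on the discretized score
#' distribution). PWM probabilities are floored at 1e-4 before taking
#' log-odds.
#'
#' @param peaks named \code{GRanges} of peaks.
#' @param genome a \code{DNAStringSet} (see \code{\link{read_genome}}).
#' @param pwms motif list from \code{\link{read_pwms}}.
#' @param p_threshold per-position false-match probability (default 5e-5).
#' @return Binary sparse peaks x motifs match matrix (see
#'   \code{\link{motif_match_matrix}}).
#' @export
scan_motifs <- function(peaks, genome, pwms, p_threshold = 5e-5) {
  chrom <- as.character(GenomicRanges::seqnames(peaks))
  missing <- setdiff(unique(chrom), names(genome))
  if (length(missing))
    stop(sprintf("contig(s) absent from FASTA: %s", paste(missing, collapse = ", ")))
  ends <- GenomicRanges::end(peaks)
  too_far <- ends > Biostrings::width(genome)[match(chrom, names(genome))]
  if (any(too_far))
    stop(sprintf("peak(s) extend beyond contig end, e.g. %s",
                 names(peaks)[too_far][1]))
  seqs <- as.character(Biostrings::subseq(
    genome[chrom], start = GenomicRanges::start(peaks), end = ends))
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
  code <- function(s) {
    v <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
    v
  }
  codes_f <- lapply(seqs, code)
  codes_r <- lapply(rc, code)
  ## 0-order background from the scanned sequences (ignoring N),
  ## strand-symmetrized so both strands see the same null model
  all_codes <- unlist(codes_f)
  bg <- tabulate(all_codes, 4)
  if (sum(bg) == 0) stop("no scannable bases in peak sequences")
  bg <- bg / sum(bg)
  bg <- (bg + rev(bg)) / 2          # A<->T, C<->G complement symmetry
  bg <- pmax(bg, 1e-6)
  bg <- bg / sum(bg)

  n_peaks <- length(peaks)
  mat <- Matrix::Matrix(0, n_peaks, length(pwms), sparse = TRUE)
  for (m in seq_along(pwms)) {
    prob <- pmax(pwms[[m]]$matrix, 1e-4)
    score_mat <- log2(prob / bg)
    ## slack covers the per-column rounding error of the DP discretization
    thr <- .pwm_threshold(score_mat, bg, p_threshold) -
      (0.5 * ncol(score_mat) + 1) / 1000
    hit <- vapply(seq_len(n_peaks), function(i) {
      any(.scan_scores(codes_f[[i]], score_mat) >= thr) ||
        any(.scan_scores(codes_r[[i]], score_mat) >= thr)
    }, logical(1))
    if (any(hit)) mat[which(hit), m] <- 1
  }
  motif_match_matrix(mat, peak_ids = names(peaks),
                     motif_ids = vapply(pwms, `[[`, character(1), "id"))
}

#' Rank TFs by motif hits among marker peaks
#'
#' Counts, per motif, how many of the supplied pattern-marker peaks carry a
#' site, and returns the motifs ranked by that count (descending). The count
#' is binary per peak: a motif counts once per peak regardless of the number
#' of sites. Ties share a rank and all ties at the \code{top_k} boundary are
#' included.
#'
#' @param marker_peaks character vector of peak ids (must be rows of
#'   \code{matches}).
#' @param matches peaks x motifs binary match matrix.
#' @param pwms TF names per motif: either a motif list as from
#'   \code{\link{read_pwms}} or a named character vector (motif id -> TF
#'   name). Optional; ids are reused as names when absent.
#' @param top_k how many top-ranked motifs to return (default 15).
#' @return \code{TfEnrichment} data.frame with columns \code{motif_id},
#'   \code{tf_name}, \code{n_marker_peaks_with_site}, \code{rank}, sorted
#'   descending by count.
#' @export
tf_enrichment <- function(marker_peaks, matches, pwms = NULL, top_k = 15) {
  missing <- setdiff(marker_peaks, rownames(matches))
  if (length(missing))
    stop(sprintf("marker peak(s) absent from match matrix, e.g. %s", missing[1]))
  counts <- Matrix::colSums(matches[marker_peaks, , drop = FALSE])
  if (all(counts == 0)) {
    warning("no motif matches any marker peak")
    return(data.frame(motif_id = character(0), tf_name = character(0),
                      n_marker_peaks_with_site = integer(0), rank = integer(0)))
  }
  tf_names <- if (is.null(pwms)) {
    names(counts)
  } else if (is.character(pwms)) {
    unname(pwms[names(counts)])
  } else {
    nm <- vapply(pwms, `[[`, character(1), "tf")
    ids <- vapply(pwms, `[[`, character(1), "id")
    unname(nm[match(names(counts), ids)])
  }
  ord <- order(counts, decreasing = TRUE)
  counts <- counts[ord]
  tf_names <- tf_names[ord]
  rk <- rank(-counts, ties.method = "min")
  keep <- if (length(counts) <= top_k) seq_along(counts)
          else which(counts >= counts[top_k])   # ties at the boundary stay
  data.frame(motif_id = names(counts)[keep], tf_name = tf_names[keep],
             n_marker_peaks_with_site = as.integer(counts[keep]),
             rank = as.integer(rk[keep]), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Fold accessibility of a gene in a cell population
#'
#' Within the cells of interest, counts per peak how many cells have a
#' nonzero (accessible) signal. The statistic is the mean of that count over
#' the peaks overlapping the gene (body plus promoter window), divided by
#' the mean over all peaks in the matrix. It depends only on the zero
#' pattern, so it is invariant to any positive rescaling of counts. A value
#' above 1 means the gene's peaks are more often accessible than a typical
#' peak in that population; intended as an approximate guide to whether a TF
#' gene is itself accessible, not a precise quantification.
#'
#' @param matrix a peak \code{CountMatrix}.
#' @param peaks named \code{GRanges} matching the matrix features.
#' @param gene gene id or symbol present in \code{genes}.
#' @param genes gene annotation \code{GRanges}.
#' @param cell_subset cell ids (or logical/integer index) selecting the
#'   population of interest.
#' @param promoter_up,promoter_down promoter window (see
#'   \code{\link{map_peaks_to_genes}}).
#' @param tss_only when TRUE, restrict the numerator to peaks overlapping
#'   the transcription start site itself (single-peak variant of the
#'   statistic).
#' @return The fold accessibility (a scalar).
#' @export
fold_accessibility <- function(matrix, peaks, gene, genes, cell_subset,
                               promoter_up = 1500, promoter_down = 500,
                               tss_only = FALSE) {
  stopifnot(is_count_matrix(matrix))
  g <- genes[names(genes) == gene | genes$symbol == gene]
  if (length(g) == 0) stop(sprintf("gene '%s' not found in annotation", gene))
  g <- g[1]
  if (tss_only) {
    target <- GenomicRanges::GRanges(GenomicRanges::seqnames(g),
                                     IRanges::IRanges(g$tss, g$tss))
  } else {
    target <- suppressWarnings(
      c(GenomicRanges::granges(g),
        GenomicRanges::promoters(g, upstream = promoter_up,
                                 downstream = promoter_down)))
  }
  idx <- match(feature_ids(matrix), names(peaks))
  if (anyNA(idx)) stop("matrix features missing from peak set")
  ov <- unique(S4Vectors::queryHits(
    suppressWarnings(GenomicRanges::findOverlaps(peaks[idx], target))))
  if (length(ov) == 0) stop(sprintf("gene not covered: no peak overlaps '%s'", gene))
  if (is.character(cell_subset)) {
    sel <- match(cell_subset, cell_ids(matrix))
    if (anyNA(sel)) stop("unknown cell id(s) in cell_subset")
  } else {
    sel <- seq_len(ncol(matrix$values))[cell_subset]
  }
  if (length(sel) == 0 || anyNA(sel)) stop("cell_subset is empty or invalid")
  acc <- Matrix::rowSums(matrix$values[, sel, drop = FALSE] > 0)
  denom <- mean(acc)
  if (denom == 0) stop("population fully inaccessible: no accessible peak in subset")
  mean(acc[ov]) / denom
}
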