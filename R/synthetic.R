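## Synthetic scATAC-seq / scRNA-seq generator with planted cell populations,
## marker-peak blocks, planted motifs, toy genes on a single contig and one
## planted TF regulon per population. Everything is deterministic per seed
## and generated in memory, so every stage of the pipeline can be tested
## without external data.

#' Specification for a synthetic scATAC-seq data set
#'
#' The generator emulates the block accessibility structure the analysis
#' assumes: each cell type has a disjoint set of marker peaks that are
#' accessible at a high rate in its own cells and at a background rate
#' elsewhere; all other peaks are background everywhere. Counts are
#' Bernoulli(access prob) x (1 + Poisson(1)), stored as reals.
#'
#' @param n_cell_types number of planted populations (default 3).
#' @param cells_per_type cells per population (default 30).
#' @param n_peaks total peaks (default 200).
#' @param marker_peaks_per_type marker peaks per population (default 40).
#' @param background_access_prob accessibility probability outside marker
#'   blocks (default 0.02).
#' @param marker_access_prob accessibility probability of a population's
#'   marker peaks in its own cells (default 0.5; must exceed background).
#' @param peak_width_range integer range of peak widths in bp (default
#'   200-1000; widths vary so width normalization is exercised).
#' @param n_motifs number of motifs; the first \code{n_cell_types} are the
#'   planted TF motifs, the rest decoys (default \code{n_cell_types + 5}).
#' @param motif_specificity fraction of a population's marker peaks carrying
#'   its planted motif (default 0.8); decoy motifs land in 10\% of peaks.
#' @param n_genes number of toy genes tiled along the contig (default 100).
#' @param seed RNG seed.
#' @return A \code{SyntheticSpec} list.
#' @export
synthetic_spec <- function(n_cell_types = 3, cells_per_type = 30,
                           n_peaks = 200, marker_peaks_per_type = 40,
                           background_access_prob = 0.02,
                           marker_access_prob = 0.5,
                           peak_width_range = c(200L, 1000L),
                           n_motifs = n_cell_types + 5,
                           motif_specificity = 0.8,
                           n_genes = 100, seed = 1L) {
  if (marker_access_prob <= background_access_prob)
    stop("marker_access_prob must exceed background_access_prob")
  probs <- c(background_access_prob, marker_access_prob, motif_specificity)
  if (any(probs < 0 | probs > 1)) stop("probabilities must be in [0, 1]")
  counts <- c(n_cell_types, cells_per_type, n_peaks, marker_peaks_per_type,
              n_motifs, n_genes)
  if (any(counts < 1)) stop("counts must be positive")
  if (n_cell_types * marker_peaks_per_type > n_peaks)
    stop("infeasible layout: marker peaks x types exceeds total peaks")
  structure(list(n_cell_types = as.integer(n_cell_types),
                 cells_per_type = as.integer(cells_per_type),
                 n_peaks = as.integer(n_peaks),
                 marker_peaks_per_type = as.integer(marker_peaks_per_type),
                 background_access_prob = background_access_prob,
                 marker_access_prob = marker_access_prob,
                 peak_width_range = as.integer(peak_width_range),
                 n_motifs = as.integer(n_motifs),
                 motif_specificity = motif_specificity,
                 n_genes = as.integer(n_genes),
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic scATAC-seq data set with planted structure
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return list with \code{matrix} (labeled peak \code{CountMatrix}),
#'   \code{peaks} (\code{GRanges} on contig "chrSim"), \code{labels}
#'   (planted type per cell), \code{motif_matches} (peaks x motifs binary
#'   matrix; motif ids "MOTIF_TF<k>" with TF names "TF<k>" for planted
#'   motifs, "DECOY<k>" otherwise), \code{motif_tfs} (named vector motif id
#'   -> TF name), \code{genes} (toy gene annotation),
#'   \code{regulons} (one planted TF regulon per type: the genes overlapping
#'   that type's marker peaks), and \code{marker_peaks} (list of planted
#'   marker peak ids per type).
#' @export
generate_atac <- function(spec) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(spec$seed)
  K <- spec$n_cell_types
  n_cells <- K * spec$cells_per_type
  labels <- rep(paste0("type", seq_len(K)), each = spec$cells_per_type)
  m <- spec$marker_peaks_per_type

  ## accessibility probabilities: marker blocks hot in their own type
  prob <- base::matrix(spec$background_access_prob, spec$n_peaks, n_cells)
  marker_rows <- lapply(seq_len(K), function(t) ((t - 1) * m + 1):(t * m))
  for (t in seq_len(K))
    prob[marker_rows[[t]], labels == paste0("type", t)] <- spec$marker_access_prob
  acc <- base::matrix(rbinom(length(prob), 1, prob), nrow(prob))
  counts <- acc * (1 + base::matrix(rpois(length(prob), 1), nrow(prob)))

  ## peaks tiled along one synthetic contig with gaps
  widths <- sample(seq(spec$peak_width_range[1], spec$peak_width_range[2]),
                   spec$n_peaks, replace = TRUE)
  gaps <- sample(100:500, spec$n_peaks, replace = TRUE)
  starts <- cumsum(c(1000L, (widths + gaps)[-spec$n_peaks]))
  peaks <- peak_set(rep("chrSim", spec$n_peaks), starts, starts + widths)
  cells <- sprintf("cell_%03d", seq_len(n_cells))
  cm <- count_matrix(counts, feature_ids = names(peaks), cell_ids = cells,
                     feature_kind = "peak", cell_labels = labels)

  ## planted motif per type plus decoys
  mm <- base::matrix(0, spec$n_peaks, spec$n_motifs)
  tf_names <- c(paste0("TF", seq_len(K)),
                paste0("DECOY", seq_len(max(spec$n_motifs - K, 0))))
  tf_names <- tf_names[seq_len(spec$n_motifs)]
  for (t in seq_len(K)) {
    rows <- marker_rows[[t]]
    carry <- sample(rows, round(spec$motif_specificity * length(rows)))
    mm[carry, t] <- 1
  }
  if (spec$n_motifs > K)
    for (d in (K + 1):spec$n_motifs)
      mm[sample(spec$n_peaks, max(1, round(0.1 * spec$n_peaks))), d] <- 1
  matches <- motif_match_matrix(mm, peak_ids = names(peaks),
                                motif_ids = paste0("MOTIF_", tf_names))

  ## toy genes tiled over the same contig, strand alternating
  contig_len <- max(GenomicRanges::end(peaks)) + 1000L
  gene_bounds <- round(seq(1, contig_len, length.out = spec$n_genes + 1))
  genes <- gene_annotation(
    gene_id = sprintf("G%03d", seq_len(spec$n_genes)),
    chrom = rep("chrSim", spec$n_genes),
    start = gene_bounds[-length(gene_bounds)],
    end = pmax(gene_bounds[-1] - 1, gene_bounds[-length(gene_bounds)] + 1),
    strand = rep(c("+", "-"), length.out = spec$n_genes))

  ## planted regulon per type: genes overlapping that type's marker peaks
  p2g <- map_peaks_to_genes(peaks, genes)
  regulons <- lapply(seq_len(K), function(t) {
    unique(unlist(p2g[names(peaks)[marker_rows[[t]]]]))
  })
  names(regulons) <- paste0("TF", seq_len(K))

  list(matrix = cm, peaks = peaks, labels = labels,
       motif_matches = matches,
       motif_tfs = setNames(tf_names, paste0("MOTIF_", tf_names)),
       genes = genes, regulons = regulons,
       marker_peaks = setNames(lapply(marker_rows, function(r) names(peaks)[r]),
                               paste0("type", seq_len(K))))
}

#' Generate a matched synthetic scRNA-seq matrix
#'
#' Genes regulated by a population's planted TF are over-expressed in that
#' population's cells by a log-normal fold shift over a shared housekeeping
#' baseline; counts are Poisson. Cells match the scATAC labels one-to-one.
#'
#' @param spec the \code{\link{synthetic_spec}} used for the ATAC data.
#' @param atac the list returned by \code{\link{generate_atac}} (supplies
#'   labels, genes and regulons).
#' @param log_fold mean log fold change of regulon genes in their own type
#'   (default \code{log(4)}); 0 gives no differential expression.
#' @param rna_seed RNG seed (default \code{spec$seed + 1000}).
#' @return A labeled \code{CountMatrix} with \code{feature_kind == "gene"}.
#' @export
generate_matched_rna <- function(spec, atac, log_fold = log(4),
                                 rna_seed = spec$seed + 1000L) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  set.seed(rna_seed)
  genes <- names(atac$genes)
  labels <- atac$labels
  n_cells <- length(labels)
  base_log <- rnorm(length(genes), mean = log(5), sd = 0.3)
  shift <- base::matrix(0, length(genes), n_cells)
  for (t in seq_along(atac$regulons)) {
    tf <- names(atac$regulons)[t]
    gi <- match(atac$regulons[[tf]], genes)
    gi <- gi[!is.na(gi)]
    ci <- which(labels == paste0("type", t))
    if (length(gi) && length(ci))
      shift[gi, ci] <- rnorm(length(gi) * length(ci), mean = log_fold, sd = 0.1)
  }
  lambda <- exp(base_log + shift)
  counts <- base::matrix(rpois(length(lambda), lambda), nrow(lambda))
  count_matrix(counts, feature_ids = genes,
               cell_ids = sprintf("cell_%03d", seq_len(n_cells)),
               feature_kind = "gene", cell_labels = labels)
}

#' Write a complete synthetic fixture set to disk
#'
#' Emits the full standard-format fixture set (MTX + BED + barcodes with
#' labels, regulon TSV, gene-set GMT of the regulons, gene annotation GTF)
#' for a synthetic data set, exercising the same readers real data would go
#' through.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @param dir output directory.
#' @return Invisibly, the generated data list (as from
#'   \code{\link{generate_atac}}).
#' @export
write_synthetic_fixtures <- function(spec, dir) {
  atac <- generate_atac(spec)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_peak_matrix(atac$matrix, dir, peaks = atac$peaks)
  ## regulons as TRRUST-style TSV
  reg <- atac$regulons
  utils::write.table(
    data.frame(tf = rep(names(reg), lengths(reg)), target = unlist(reg),
               mode = "Activation"),
    file.path(dir, "regulons.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE, col.names = FALSE)
  ## the same sets as a GMT collection
  gmt <- vapply(names(reg), function(tf)
    paste(c(tf, "planted_regulon", reg[[tf]]), collapse = "\t"), character(1))
  writeLines(gmt, file.path(dir, "regulons.gmt"))
  ## gene annotation as GTF (1-based closed)
  g <- atac$genes
  gtf <- sprintf('%s\tsynthetic\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_name "%s";',
                 as.character(GenomicRanges::seqnames(g)),
                 GenomicRanges::start(g), GenomicRanges::end(g),
                 as.character(GenomicRanges::strand(g)), names(g), g$symbol)
  writeLines(gtf, file.path(dir, "genes.gtf"))
  invisible(atac)
}
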