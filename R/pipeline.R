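## Workflow orchestration: a YAML-configured end-to-end run over the staged
## analysis (filter -> factorize -> markers -> annotate/enrich -> optional
## gsea), with serialized intermediates and a single JSON run manifest. All
## randomness derives from one top-level seed, with fixed per-stage offsets.

#' Run the staged analysis pipeline from a YAML config
#'
#' The config must name the inputs (\code{mtx}, \code{peaks_bed},
#' \code{barcodes}) and the factorization parameters (\code{n_patterns};
#' optionally \code{n_iterations}, \code{seed}, and the other
#' \code{\link{factorization_config}} fields). Optional keys:
#' \code{filter_threshold} (default 0.99), \code{gmt} plus annotation
#' \code{gtf} for pathway enrichment, \code{regulons} plus \code{rna_*}
#' inputs for GSEA validation, \code{normalize_by_width: true}. Stage
#' outputs are written under \code{out_dir} as TSV/JSON; an existing
#' non-empty output directory is refused unless \code{force}.
#'
#' @param config_path path to a YAML file (or a pre-parsed list).
#' @param out_dir output directory; defaults to \code{out_dir} in the
#'   config.
#' @param force overwrite existing outputs.
#' @return Invisibly, a list of in-memory stage results.
#' @export
run_pipeline <- function(config_path, out_dir = NULL, force = FALSE) {
  cfg <- if (is.list(config_path)) config_path else yaml::read_yaml(config_path)
  for (key in c("mtx", "peaks_bed", "barcodes", "n_patterns"))
    if (is.null(cfg[[key]]))
      stop(sprintf("config validation: missing required key '%s'", key))
  out_dir <- out_dir %||% cfg$out_dir %||% stop("no out_dir given")
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0 && !force)
    stop(sprintf("output directory '%s' is not empty; use force = TRUE", out_dir))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  started <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  seed <- as.integer(cfg$seed %||% 42L)

  ## stage: load
  loaded <- read_peak_matrix(cfg$mtx, cfg$peaks_bed, cfg$barcodes)
  mat <- loaded$matrix
  peaks <- loaded$peaks
  if (isTRUE(cfg$normalize_by_width)) mat <- normalize_by_width(mat, peaks)

  ## stage: filter
  flt <- filter_sparse(mat, threshold = cfg$filter_threshold %||% 0.99)
  jsonlite::write_json(unclass(flt$report),
                       file.path(out_dir, "filter_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  mat <- flt$matrix
  peaks <- peaks[match(feature_ids(mat), names(peaks))]

  ## stage: factorize (per-stage seed derived from the top-level seed)
  fcfg <- factorization_config(
    n_patterns = cfg$n_patterns,
    n_iterations = cfg$n_iterations %||% 10000L,
    seed = seed + 1L,
    uncertainty_floor = cfg$uncertainty_floor %||% 0.1,
    uncertainty_fraction = cfg$uncertainty_fraction %||% 0.1,
    sparsity_scale = cfg$sparsity_scale %||% 1,
    zero_prob = cfg$zero_prob %||% 0.25,
    n_feature_subsets = cfg$n_feature_subsets %||% 1L)
  fit <- run_distributed(mat, config = fcfg)
  write_factorization(fit, file.path(out_dir, "factorization"))

  ## stage: markers
  cells_pm <- assign_cells(fit)
  feats_pm <- marker_features(fit, top_k = cfg$top_k_markers)
  marker_tab <- do.call(rbind, lapply(seq_along(feats_pm$markers), function(k) {
    ids <- feats_pm$markers[[k]]
    if (length(ids) == 0) return(NULL)
    data.frame(item = ids, pattern = k,
               score = feats_pm$score[ids, k],
               rank = seq_along(ids), stringsAsFactors = FALSE)
  }))
  utils::write.table(marker_tab, file.path(out_dir, "marker_features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(cell = names(cells_pm$assignment),
               pattern = cells_pm$assignment,
               ambiguous = cells_pm$ambiguous),
    file.path(out_dir, "cell_assignments.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)

  results <- list(filter_report = flt$report, fit = fit,
                  cell_markers = cells_pm, feature_markers = feats_pm)

  ## stage: annotate / enrich (optional)
  if (!is.null(cfg$gtf)) {
    genes <- read_gene_annotation(cfg$gtf)
    p2g <- map_peaks_to_genes(peaks, genes,
                              promoter_up = cfg$promoter_up %||% 1500,
                              promoter_down = cfg$promoter_down %||% 500)
    utils::write.table(
      data.frame(peak = rep(names(p2g), lengths(p2g)),
                 gene = unlist(p2g)),
      file.path(out_dir, "peak_to_gene.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
    results$peak_to_gene <- p2g
    if (!is.null(cfg$gmt)) {
      sets <- read_gmt(cfg$gmt)
      universe <- unique(unlist(p2g))
      enr <- lapply(seq_along(feats_pm$markers), function(k) {
        q <- unique(unlist(p2g[feats_pm$markers[[k]]]))
        if (length(q) == 0) return(NULL)
        cbind(pattern = k, pathway_overlap(q, sets, universe))
      })
      enr <- do.call(rbind, enr)
      utils::write.table(enr, file.path(out_dir, "pathway_enrichment.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      results$enrichment <- enr
    }
  }

  manifest <- list(
    tool = "atacPatterns",
    version = as.character(utils::packageVersion("atacPatterns")),
    subcommand = "run_pipeline",
    config = cfg, seed = seed,
    input_checksums = vapply(c(mtx = cfg$mtx, peaks_bed = cfg$peaks_bed,
                               barcodes = cfg$barcodes),
                             function(f) as.character(tools::md5sum(f)),
                             character(1)),
    outputs = list.files(out_dir, recursive = TRUE),
    started = started,
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
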