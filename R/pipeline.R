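#' Run configuration
#'
#' Collects the file paths, thresholds and seed of a pipeline run.
#'
#' @param catalog,consensus_map paths to the catalog and consensus map.
#' @param study_maps named character vector of study-map paths keyed by
#'   map id (or a single path used for all).
#' @param annotation,marker_positions,expression optional candidate-gene
#'   inputs (GFF3, marker bp table, expression table).
#' @param out_dir output directory.
#' @param seed integer seed.
#' @param max_ci_cm projection rejection ceiling (cM).
#' @param small_n_max path-switch threshold (QTL per chromosome).
#' @param k_max mixture component cap.
#' @param min_qtl,min_studies MQTL admission rule.
#' @param tpm_threshold expression filter threshold.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(catalog, consensus_map, study_maps,
                       annotation = NULL, marker_positions = NULL,
                       expression = NULL, out_dir = tempdir(), seed = 1L,
                       max_ci_cm = 50, small_n_max = 10L, k_max = 10L,
                       min_qtl = 2L, min_studies = 2L, tpm_threshold = 3) {
  stopifnot(max_ci_cm > 0, small_n_max > 0, k_max > 0, tpm_threshold > 0)
  structure(as.list(environment()), class = "run_config")
}

#' Run the full meta-QTL pipeline
#'
#' Reads the catalog and maps, screens inclusion, standardizes CIs,
#' projects onto the consensus map, runs the per-regime meta-analysis,
#' detects cross-regime overlap regions and (when annotation inputs are
#' configured) candidate genes. All result tables are written as TSV under
#' \code{config$out_dir} together with a JSON run manifest (seed, config,
#' chosen K per chromosome). Re-running with the same config and seed
#' reproduces identical tables.
#'
#' @param config a \code{\link{run_config}}.
#' @return Invisibly, a list: \code{catalog}, \code{projected},
#'   \code{fit}, \code{overlaps}, \code{genes} (or NULL), \code{manifest}.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  consensus <- read_map(config$consensus_map, map_id = "consensus")
  paths <- config$study_maps
  study_maps <- lapply(paths, read_map)
  if (!is.null(names(paths)))
    for (i in seq_along(study_maps))
      attr(study_maps[[i]], "map_id") <- names(paths)[i]
  names(study_maps) <- vapply(study_maps, attr, "", "map_id")

  catalog <- read_catalog(config$catalog)
  catalog <- validate_inclusion(catalog)
  catalog <- fill_missing_ci(catalog)
  rej <- attr(catalog, "rejections")
  utils::write.table(rej, file.path(config$out_dir, "rejections.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  projected <- project_qtl(catalog, study_maps, consensus,
                           max_ci_cm = config$max_ci_cm)
  write_projected(projected, file.path(config$out_dir, "projected.tsv"))

  fit <- metaqtl(projected, consensus, seed = config$seed,
                 k_max = config$k_max, small_n_max = config$small_n_max,
                 min_qtl = config$min_qtl,
                 min_studies = config$min_studies)
  write_mqtl_table(fit$mqtl, file.path(config$out_dir, "mqtl.tsv"))

  overlaps <- find_overlaps(
    fit$mqtl[fit$mqtl$regime == "irrigated", , drop = FALSE],
    fit$mqtl[fit$mqtl$regime == "rainfed", , drop = FALSE],
    consensus)
  utils::write.table(overlaps, file.path(config$out_dir, "overlaps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  genes <- NULL
  if (!is.null(config$annotation) && !is.null(config$marker_positions) &&
      !is.null(config$expression)) {
    genes <- candidate_genes(fit$mqtl,
                             read_marker_positions(config$marker_positions),
                             read_genes_gff3(config$annotation),
                             read_expression(config$expression),
                             threshold = config$tpm_threshold)
    utils::write.table(genes, file.path(config$out_dir, "genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    seed = config$seed,
    config = config[!vapply(config, is.null, TRUE)],
    n_records = nrow(catalog),
    n_included = sum(catalog$included),
    n_projected = sum(projected$status == "projected"),
    chosen_k = lapply(fit$results, function(r)
      vapply(r, function(cr) cr$model$K, 0L)),
    n_mqtl = nrow(fit$mqtl),
    n_overlap_regions = nrow(overlaps))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, force = TRUE, digits = NA)
  invisible(list(catalog = catalog, projected = projected, fit = fit,
                 overlaps = overlaps, genes = genes, manifest = manifest))
}
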