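#' @title Candidate genes under meta-QTL intervals
#' @name candidate-genes
#' @description A meta-QTL's flanking markers are located on the physical
#'   (bp) assembly; the bracketed interval is intersected with the gene
#'   annotation and the resulting gene list filtered by expression under
#'   stress conditions.
NULL

#' Read a marker physical-position table
#'
#' Delimited text with columns \code{marker}, \code{chromosome},
#' \code{pos_bp}.
#'
#' @param path file path.
#' @param sep separator.
#' @return data.frame with those columns.
#' @export
read_marker_positions <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("marker", "chromosome", "pos_bp")
  if (!all(need %in% names(df)))
    stop("marker table must have columns: ", paste(need, collapse = ", "))
  if (any(df$pos_bp < 1)) stop("bp positions must be >= 1")
  df
}

#' Physical interval spanned by a meta-QTL's flanking markers
#'
#' @param left_marker,right_marker flanking marker names.
#' @param marker_table data.frame from
#'   \code{\link{read_marker_positions}}.
#' @return list \code{(chromosome, start_bp, end_bp)} (ascending), or
#'   \code{NULL} with a warning when a marker is absent or the markers map
#'   to different chromosomes.
#' @export
mqtl_physical_interval <- function(left_marker, right_marker, marker_table) {
  i <- match(left_marker, marker_table$marker)
  j <- match(right_marker, marker_table$marker)
  if (is.na(i) || is.na(j)) {
    warning("flanking marker(s) absent from physical table: ",
            paste(c(left_marker, right_marker)[c(is.na(i), is.na(j))],
                  collapse = ", "))
    return(NULL)
  }
  if (marker_table$chromosome[i] != marker_table$chromosome[j]) {
    warning("flanking markers on different chromosomes: ",
            left_marker, " / ", right_marker)
    return(NULL)
  }
  bp <- sort(c(marker_table$pos_bp[i], marker_table$pos_bp[j]))
  list(chromosome = marker_table$chromosome[i],
       start_bp = bp[1L], end_bp = bp[2L])
}

#' Read gene features from a GFF3 annotation
#'
#' @param path GFF3 file.
#' @param feature_type feature type(s) to keep, default \code{"gene"}.
#' @return data.frame: \code{gene_id}, \code{chromosome}, \code{start_bp},
#'   \code{end_bp}, \code{description} (1-based inclusive coordinates).
#' @export
read_genes_gff3 <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[gr$type %in% feature_type]
  id <- if (!is.null(gr$ID)) gr$ID else gr$gene_id
  desc <- if ("description" %in% names(S4Vectors::mcols(gr)))
    gr$description else NA_character_
  data.frame(gene_id = as.character(id),
             chromosome = as.character(GenomicRanges::seqnames(gr)),
             start_bp = GenomicRanges::start(gr),
             end_bp = GenomicRanges::end(gr),
             description = as.character(desc),
             stringsAsFactors = FALSE)
}

#' Genes intersecting a physical interval
#'
#' Any-overlap rule on 1-based inclusive coordinates.
#'
#' @param interval list \code{(chromosome, start_bp, end_bp)}.
#' @param genes gene data.frame from \code{\link{read_genes_gff3}}.
#' @return The intersecting genes, sorted by start position.
#' @export
genes_in_interval <- function(interval, genes) {
  g <- genes[genes$chromosome == interval$chromosome, , drop = FALSE]
  if (!nrow(g)) return(g)
  q <- IRanges::IRanges(interval$start_bp, interval$end_bp)
  subj <- IRanges::IRanges(g$start_bp, g$end_bp)
  hits <- IRanges::findOverlaps(q, subj)
  g <- g[S4Vectors::subjectHits(hits), , drop = FALSE]
  g <- g[order(g$start_bp), , drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Read a gene expression table
#'
#' Long-format delimited text: \code{gene_id}, \code{condition},
#' \code{tpm}.
#'
#' @param path file path.
#' @param sep separator.
#' @return data.frame with those columns.
#' @export
read_expression <- function(path, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("gene_id", "condition", "tpm")
  if (!all(need %in% names(df)))
    stop("expression table must have columns: ",
         paste(need, collapse = ", "))
  if (any(df$tpm < 0)) stop("tpm must be nonnegative")
  df
}

#' Filter genes by stress expression
#'
#' Keeps genes whose expression strictly exceeds \code{threshold} (tpm) in
#' at least one of the selected conditions, sorted by descending maximal
#' tpm.
#'
#' @param genes gene data.frame (needs \code{gene_id}).
#' @param expression expression table from \code{\link{read_expression}}.
#' @param threshold tpm threshold (strict), default 3.
#' @param conditions optional character vector restricting which condition
#'   labels count (e.g. drought / drought+heat experiments); default all.
#' @return data.frame: gene columns plus \code{max_tpm} and
#'   \code{condition} of the maximum.
#' @export
filter_expressed <- function(genes, expression, threshold = 3,
                             conditions = NULL) {
  stopifnot(threshold > 0)
  ex <- expression
  if (!is.null(conditions)) ex <- ex[ex$condition %in% conditions, ,
                                     drop = FALSE]
  ex <- ex[ex$gene_id %in% genes$gene_id & ex$tpm > threshold, ,
           drop = FALSE]
  if (!nrow(ex)) {
    out <- genes[0, , drop = FALSE]
    out$max_tpm <- numeric()
    out$condition <- character()
    return(out)
  }
  ex <- ex[order(-ex$tpm), , drop = FALSE]
  best <- ex[!duplicated(ex$gene_id), , drop = FALSE]
  out <- merge(genes, best[, c("gene_id", "tpm", "condition")],
               by = "gene_id")
  names(out)[names(out) == "tpm"] <- "max_tpm"
  out <- out[order(-out$max_tpm), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Candidate genes for each meta-QTL
#'
#' Convenience driver: for every MQTL with both flanking markers placed on
#' the physical map, list the genes in the bracketed interval passing the
#' expression filter.
#'
#' @param mqtl MQTL table (needs \code{mqtl_id}, \code{left_marker},
#'   \code{right_marker}).
#' @param marker_table marker physical positions.
#' @param genes gene annotation data.frame.
#' @param expression expression table.
#' @param threshold tpm threshold.
#' @param conditions condition labels to consider.
#' @return data.frame: \code{mqtl_id}, \code{gene_id}, \code{start_bp},
#'   \code{end_bp}, \code{max_tpm}, \code{condition}.
#' @export
candidate_genes <- function(mqtl, marker_table, genes, expression,
                            threshold = 3, conditions = NULL) {
  rows <- list()
  for (i in seq_len(nrow(mqtl))) {
    ivl <- withCallingHandlers(
      mqtl_physical_interval(mqtl$left_marker[i], mqtl$right_marker[i],
                             marker_table),
      warning = function(w) invokeRestart("muffleWarning"))
    if (is.null(ivl)) next
    g <- genes_in_interval(ivl, genes)
    g <- filter_expressed(g, expression, threshold, conditions)
    if (!nrow(g)) next
    g$mqtl_id <- mqtl$mqtl_id[i]
    rows[[length(rows) + 1L]] <-
      g[, c("mqtl_id", "gene_id", "start_bp", "end_bp", "max_tpm",
            "condition")]
  }
  if (!length(rows))
    return(data.frame(mqtl_id = character(), gene_id = character(),
                      start_bp = numeric(), end_bp = numeric(),
                      max_tpm = numeric(), condition = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
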