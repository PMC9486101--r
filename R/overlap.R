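#' 95\%-CI interval of a meta-QTL
#'
#' \code{[peak - width/2, peak + width/2]}, clipped at 0. A zero width
#' yields a degenerate point interval (flagged via attribute
#' \code{degenerate}).
#'
#' @param peak_cm MQTL peak (cM).
#' @param ci95_width_cm MQTL 95\% CI width (cM).
#' @return Numeric length-2 vector \code{c(lo, hi)}.
#' @examples
#' mqtl_interval(42.27, 8.43)  # 38.055 46.485
#' @export
mqtl_interval <- function(peak_cm, ci95_width_cm) {
  lo <- max(0, peak_cm - ci95_width_cm / 2)
  hi <- max(0, peak_cm + ci95_width_cm / 2)
  structure(c(lo, hi), degenerate = (ci95_width_cm == 0))
}

#' Genomic regions where the two regimes' meta-QTL overlap
#'
#' For each chromosome, every pairwise intersection between one
#' irrigated-regime MQTL CI and one rainfed-regime MQTL CI is computed
#' (touching endpoints count); intersections that themselves overlap are
#' merged into maximal connected regions. The region interval is the hull
#' of its merged intersections, the region peak its midpoint. Symmetric in
#' its two arguments.
#'
#' @param irrigated,rainfed MQTL tables (as produced by
#'   \code{\link{metaqtl}}; need columns \code{mqtl_id},
#'   \code{chromosome}, \code{peak_cm}, \code{ci95_width_cm}).
#' @param consensus optional consensus \code{genetic_map} used to attach
#'   flanking markers to each region.
#' @return data.frame: \code{chromosome}, \code{interval_lo},
#'   \code{interval_hi}, \code{peak_cm}, \code{irrigated_mqtl},
#'   \code{rainfed_mqtl}, \code{left_marker}, \code{right_marker}; sorted
#'   by chromosome then position.
#' @export
find_overlaps <- function(irrigated, rainfed, consensus = NULL) {
  empty <- data.frame(chromosome = character(), interval_lo = numeric(),
                      interval_hi = numeric(), peak_cm = numeric(),
                      irrigated_mqtl = character(),
                      rainfed_mqtl = character(),
                      left_marker = character(), right_marker = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(irrigated) || !nrow(rainfed)) return(empty)
  ivl <- function(m) {
    t(mapply(function(p, w) mqtl_interval(p, w), m$peak_cm,
             m$ci95_width_cm))
  }
  out <- list()
  for (chrom in sort(intersect(irrigated$chromosome, rainfed$chromosome))) {
    a <- irrigated[irrigated$chromosome == chrom, , drop = FALSE]
    b <- rainfed[rainfed$chromosome == chrom, , drop = FALSE]
    ia <- ivl(a); ib <- ivl(b)
    # pairwise intersections (touching counts)
    inter <- list()
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      lo <- max(ia[i, 1L], ib[j, 1L])
      hi <- min(ia[i, 2L], ib[j, 2L])
      if (lo <= hi)
        inter[[length(inter) + 1L]] <-
          list(lo = lo, hi = hi, i = a$mqtl_id[i], d = b$mqtl_id[j])
    }
    if (!length(inter)) next
    # merge connected intersections into maximal regions
    ord <- order(vapply(inter, `[[`, 0, "lo"))
    inter <- inter[ord]
    cur <- inter[[1L]]
    cur$i <- list(cur$i); cur$d <- list(cur$d)
    flush <- function(cur) {
      lo <- cur$lo; hi <- cur$hi
      fl <- if (!is.null(consensus))
        flanking_markers(map_chromosome(consensus, chrom), lo, hi)
      else list(left = NA_character_, right = NA_character_)
      data.frame(chromosome = chrom, interval_lo = lo, interval_hi = hi,
                 peak_cm = (lo + hi) / 2,
                 irrigated_mqtl = paste(sort(unique(unlist(cur$i))),
                                        collapse = ","),
                 rainfed_mqtl = paste(sort(unique(unlist(cur$d))),
                                      collapse = ","),
                 left_marker = fl$left, right_marker = fl$right,
                 stringsAsFactors = FALSE)
    }
    if (length(inter) > 1L) for (r in inter[-1L]) {
      if (r$lo <= cur$hi) {
        cur$hi <- max(cur$hi, r$hi)
        cur$i <- c(cur$i, r$i); cur$d <- c(cur$d, r$d)
      } else {
        out[[length(out) + 1L]] <- flush(cur)
        cur <- r
        cur$i <- list(cur$i); cur$d <- list(cur$d)
      }
    }
    out[[length(out) + 1L]] <- flush(cur)
  }
  if (!length(out)) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$chromosome, res$interval_lo), , drop = FALSE]
  rownames(res) <- NULL
  res
}
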