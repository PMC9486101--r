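#' @title Homothetic projection of QTL onto a consensus map
#' @name projection
#' @description A QTL observed on a study's own linkage map is transferred
#'   to the consensus map by linear rescaling between the tightest pair of
#'   markers shared by both maps that brackets the position (piecewise
#'   homothety). No extrapolation is performed beyond the outermost shared
#'   marker: positions that cannot be bracketed lead to rejection.
NULL

#' Find the tightest shared anchor pair bracketing a position
#'
#' Markers common to the source and consensus map (exact name match after
#' whitespace trimming) are searched for the pair with minimal source-map
#' span that brackets \code{pos_cm} and has distinct positions on both
#' maps. A position coinciding exactly with a shared marker anchors to that
#' marker directly.
#'
#' @param source_map,consensus \code{genetic_map}s.
#' @param chromosome chromosome name.
#' @param pos_cm position on the source map (cM).
#' @return A list with \code{left}, \code{right} (marker names),
#'   \code{s} (their source positions) and \code{c} (consensus positions),
#'   or \code{NULL} when no shared pair brackets the position. When the
#'   position sits exactly on a shared marker, \code{left == right}.
#' @export
shared_anchor_pair <- function(source_map, consensus, chromosome, pos_cm) {
  sm <- map_chromosome(source_map, chromosome)
  cm <- map_chromosome(consensus, chromosome)
  common <- intersect(sm$marker, cm$marker)
  if (!length(common)) return(NULL)
  s <- sm$pos_cm[match(common, sm$marker)]
  cc <- cm$pos_cm[match(common, cm$marker)]
  ord <- order(s)
  common <- common[ord]; s <- s[ord]; cc <- cc[ord]

  exact <- which(s == pos_cm)
  if (length(exact)) {
    i <- exact[1L]
    return(list(left = common[i], right = common[i],
                s = c(s[i], s[i]), c = c(cc[i], cc[i])))
  }
  li <- which(s < pos_cm)
  ri <- which(s > pos_cm)
  if (!length(li) || !length(ri)) return(NULL)
  best <- NULL
  for (i in rev(li)) {
    for (j in ri) {
      if (cc[j] == cc[i]) next      # need distinct consensus positions
      span <- s[j] - s[i]
      if (is.null(best) || span < best$span)
        best <- list(i = i, j = j, span = span)
      break                          # further right only widens the span
    }
    if (!is.null(best) && (pos_cm - s[i]) >= best$span) break
  }
  if (is.null(best)) {
    # fallback: exhaustive search (rare: consensus-coincident neighbours)
    for (i in rev(li)) for (j in ri) {
      if (cc[j] == cc[i]) next
      span <- s[j] - s[i]
      if (is.null(best) || span < best$span) best <- list(i = i, j = j,
                                                          span = span)
    }
  }
  if (is.null(best)) return(NULL)
  list(left = common[best$i], right = common[best$j],
       s = c(s[best$i], s[best$j]), c = c(cc[best$i], cc[best$j]))
}

#' Project one position through an anchor pair
#'
#' Linear (homothetic) rescaling:
#' \eqn{c_L + (x - s_L)(c_R - c_L)/(s_R - s_L)}.
#'
#' @param pos_cm position on the source map.
#' @param anchors an anchor pair from \code{\link{shared_anchor_pair}}.
#' @return Position on the consensus map (cM).
#' @export
project_position <- function(pos_cm, anchors) {
  if (anchors$left == anchors$right) return(anchors$c[1L])
  if (anchors$s[2L] == anchors$s[1L]) stop("zero source span in anchor pair")
  anchors$c[1L] + (pos_cm - anchors$s[1L]) *
    (anchors$c[2L] - anchors$c[1L]) / (anchors$s[2L] - anchors$s[1L])
}

# project a CI bound: tightest bracketing pair if available, otherwise the
# nearest interior anchor pair (bound outside shared-marker span), flagged.
project_bound <- function(pos_cm, source_map, consensus, chromosome,
                          peak_anchors) {
  a <- shared_anchor_pair(source_map, consensus, chromosome, pos_cm)
  if (is.null(a)) {
    a <- peak_anchors
    extrapolated <- TRUE
  } else extrapolated <- FALSE
  list(pos = project_position(pos_cm, a), extrapolated = extrapolated)
}

#' Project a catalog of QTL onto the consensus map
#'
#' Each included record's peak and CI bounds are projected, each through
#' its own tightest anchor pair. Records whose peak cannot be bracketed by
#' shared markers are rejected (\code{rejected_no_shared_markers}); records
#' whose projected CI exceeds \code{max_ci_cm} are rejected
#' (\code{rejected_large_ci}). Projected CI bounds are clipped to the
#' consensus chromosome. CI bounds falling outside the shared-marker span
#' are projected through the peak's anchor pair and flagged
#' (\code{bound_extrapolated}).
#'
#' @param catalog a validated \code{qtl_catalog} with materialized CIs.
#' @param source_maps a single \code{genetic_map} or named list of maps
#'   keyed by \code{map_id}.
#' @param consensus the consensus \code{genetic_map}.
#' @param max_ci_cm rejection ceiling for the projected CI width (cM).
#' @return A data.frame of class \code{projected_qtl}: catalog columns plus
#'   \code{cons_peak_cm}, \code{cons_ci_lo_cm}, \code{cons_ci_hi_cm},
#'   \code{status}, \code{anchor_left}, \code{anchor_right},
#'   \code{bound_extrapolated}.
#' @export
project_qtl <- function(catalog, source_maps, consensus, max_ci_cm = 50) {
  df <- as.data.frame(catalog)
  if ("included" %in% names(df)) df <- df[df$included, , drop = FALSE]
  if (inherits(source_maps, "genetic_map"))
    source_maps <- stats::setNames(list(source_maps),
                                   attr(source_maps, "map_id"))
  lens <- chromosome_lengths(consensus)
  n <- nrow(df)
  out <- df
  out$cons_peak_cm <- out$cons_ci_lo_cm <- out$cons_ci_hi_cm <- NA_real_
  out$status <- NA_character_
  out$anchor_left <- out$anchor_right <- NA_character_
  out$bound_extrapolated <- FALSE
  for (i in seq_len(n)) {
    r <- df[i, ]
    smap <- source_maps[[r$map_id]]
    if (is.null(smap) || !(r$chromosome %in% consensus$chromosome) ||
        is.null(a <- shared_anchor_pair(smap, consensus, r$chromosome,
                                        r$peak_cm))) {
      out$status[i] <- "rejected_no_shared_markers"
      next
    }
    peak <- project_position(r$peak_cm, a)
    lo <- project_bound(r$ci_lo_cm, smap, consensus, r$chromosome, a)
    hi <- project_bound(r$ci_hi_cm, smap, consensus, r$chromosome, a)
    len <- lens[[r$chromosome]]
    b <- sort(c(lo$pos, hi$pos))
    lo_c <- max(0, min(b[1L], len))
    hi_c <- max(0, min(b[2L], len))
    peak <- max(lo_c, min(peak, hi_c))
    if (hi_c - lo_c > max_ci_cm) {
      out$status[i] <- "rejected_large_ci"
      next
    }
    out$status[i] <- "projected"
    out$cons_peak_cm[i] <- peak
    out$cons_ci_lo_cm[i] <- lo_c
    out$cons_ci_hi_cm[i] <- hi_c
    out$anchor_left[i] <- a$left
    out$anchor_right[i] <- a$right
    out$bound_extrapolated[i] <- lo$extrapolated || hi$extrapolated
  }
  rownames(out) <- NULL
  structure(out, class = c("projected_qtl", "data.frame"))
}

#' Write projected QTL to delimited text
#' @param projected a \code{projected_qtl} data.frame.
#' @param path output path.
#' @export
write_projected <- function(projected, path) {
  utils::write.table(as.data.frame(projected), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = ".")
  invisible(path)
}
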