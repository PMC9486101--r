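#' @title Synthetic multi-study QTL catalogs with known ground truth
#' @name synthetic-data
#' @description Generators emulating the structure of a curated
#'   literature QTL catalog: a dense consensus map, per-study maps sharing
#'   only a marker subset (with monotone map distortion), and QTL peaks
#'   dispersed around true meta-QTL positions with design-driven CI widths
#'   and a right-skewed PVE distribution. All generators are deterministic
#'   per seed (R's default Mersenne-Twister RNG).
NULL

#' Simulate a consensus genetic map
#'
#' Marker positions are uniform over each chromosome with an expected
#' count of \code{length_cm * marker_density} (Poisson), sorted; the
#' first and last markers are pinned to 0 and the chromosome length so the
#' map spans the chromosome.
#'
#' @param n_chrom number of chromosomes (named from the wheat set
#'   \code{1A..7B} when \code{n_chrom <= 14}).
#' @param length_cm chromosome length(s), recycled.
#' @param marker_density expected markers per cM.
#' @param seed integer seed.
#' @return A \code{genetic_map} with \code{map_id = "consensus"}.
#' @export
simulate_consensus_map <- function(n_chrom = 14L, length_cm = 188,
                                   marker_density = 1, seed = 1L) {
  stopifnot(marker_density > 0)
  set.seed(as.integer(seed))
  length_cm <- rep_len(length_cm, n_chrom)
  chroms <- if (n_chrom <= length(CHROMOSOMES)) CHROMOSOMES[seq_len(n_chrom)]
            else paste0("chr", seq_len(n_chrom))
  rows <- lapply(seq_len(n_chrom), function(ci) {
    len <- length_cm[ci]
    n <- max(2L, stats::rpois(1L, len * marker_density))
    pos <- sort(stats::runif(n, 0, len))
    pos[1L] <- 0; pos[n] <- len
    data.frame(marker = sprintf("M%s_%04d", chroms[ci], seq_len(n)),
               chromosome = chroms[ci], pos_cm = pos,
               stringsAsFactors = FALSE)
  })
  as_genetic_map(do.call(rbind, rows), map_id = "consensus")
}

#' Derive a study map from the consensus map
#'
#' Retains a random subset of consensus markers and applies a monotone
#' piecewise-linear distortion (segment slopes drawn in
#' \code{[1 - distortion, 1 + distortion]}), so marker order is preserved
#' while local cM scales differ, as between real study maps.
#'
#' @param consensus consensus \code{genetic_map}.
#' @param subset_fraction fraction of markers retained, in (0, 1].
#' @param distortion slope half-range \code{d >= 0} (\code{d < 1}).
#' @param seed integer seed.
#' @param map_id id of the derived map.
#' @param n_segments distortion segments per chromosome.
#' @return A \code{genetic_map}. Attribute \code{warp} stores the
#'   per-chromosome distortion functions (consensus cM -> study cM).
#' @export
simulate_study_map <- function(consensus, subset_fraction = 0.3,
                               distortion = 0.1, seed = 1L,
                               map_id = "study", n_segments = 5L) {
  stopifnot(subset_fraction > 0, subset_fraction <= 1,
            distortion >= 0, distortion < 1)
  set.seed(as.integer(seed))
  warp <- list()
  rows <- list()
  for (chrom in unique(consensus$chromosome)) {
    cm <- map_chromosome(consensus, chrom)
    len <- max(cm$pos_cm)
    knots <- seq(0, len, length.out = n_segments + 1L)
    slopes <- stats::runif(n_segments, 1 - distortion, 1 + distortion)
    heights <- c(0, cumsum(slopes * diff(knots)))
    f <- stats::approxfun(knots, heights, rule = 2)
    warp[[chrom]] <- f
    keep <- which(stats::runif(nrow(cm)) < subset_fraction)
    if (length(keep) < 2L) keep <- c(1L, nrow(cm))
    d <- cm[keep, , drop = FALSE]
    d$pos_cm <- f(d$pos_cm)
    rows[[chrom]] <- d
  }
  m <- as_genetic_map(do.call(rbind, rows), map_id = map_id)
  attr(m, "warp") <- warp
  m
}

#' Default simulation truth
#'
#' Describes the study conditions the generator emulates: true meta-QTL
#' positions per chromosome with per-regime activity, and a panel of
#' studies with realistic designs (mostly RIL populations of about
#' 100-250 lines, a few F2/F2:3/DH/MAGIC), each mapping a random subset of
#' consensus markers.
#'
#' @param consensus consensus \code{genetic_map}.
#' @param n_mqtl_per_chrom true MQTL per chromosome.
#' @param n_studies number of studies.
#' @param seed integer seed.
#' @param sigma_between SD (cM) of study QTL peaks around their true MQTL.
#' @param n_qtl_total total QTL in the catalog.
#' @param rainfed_fraction fraction of QTL observed under the rainfed
#'   regime.
#' @param subset_fraction,distortion study-map parameters, see
#'   \code{\link{simulate_study_map}}.
#' @return A list of class \code{simulation_truth}.
#' @export
simulation_truth <- function(consensus, n_mqtl_per_chrom = 3L,
                             n_studies = 25L, seed = 1L,
                             sigma_between = 2,
                             n_qtl_total = 724L,
                             rainfed_fraction = 468 / 724,
                             subset_fraction = 0.3, distortion = 0.1) {
  set.seed(as.integer(seed))
  chroms <- unique(consensus$chromosome)
  lens <- chromosome_lengths(consensus)
  mqtl <- list()
  for (chrom in chroms) {
    len <- lens[[chrom]]
    # evenly spread with jitter, keeping well inside the chromosome
    base <- seq(len * 0.15, len * 0.85,
                length.out = n_mqtl_per_chrom)
    pos <- sort(base + stats::runif(n_mqtl_per_chrom, -len * 0.03,
                                    len * 0.03))
    mqtl[[chrom]] <- data.frame(
      mqtl_truth_id = sprintf("TRUE_%s.%d", chrom,
                              seq_len(n_mqtl_per_chrom)),
      chromosome = chrom, pos_cm = pos,
      irrigated = TRUE, rainfed = TRUE,
      stringsAsFactors = FALSE)
  }
  designs <- data.frame(
    study_id = sprintf("study%02d", seq_len(n_studies)),
    pop_type = rep(c("RIL", "RIL", "RIL", "F2", "DH", "RIL", "F2:3",
                     "MAGIC"), length.out = n_studies),
    pop_size = round(stats::runif(n_studies, 93, 338)),
    stringsAsFactors = FALSE)
  structure(list(mqtl = do.call(rbind, mqtl), studies = designs,
                 sigma_between = sigma_between,
                 n_qtl_total = as.integer(n_qtl_total),
                 rainfed_fraction = rainfed_fraction,
                 subset_fraction = subset_fraction,
                 distortion = distortion, seed = as.integer(seed)),
            class = "simulation_truth")
}

#' Simulate a multi-study QTL catalog from a truth object
#'
#' Each catalog record draws a generating true MQTL (uniform), a study, a
#' regime (\code{rainfed_fraction}), a trait (TGW most frequent, then the
#' rest of the 19-trait vocabulary), a peak Normal(true position,
#' \code{sigma_between}) expressed in STUDY-map coordinates through the
#' study map's distortion, a PVE from Beta(4, 25) (right-skewed; mean
#' 0.138, 84\% of mass below 0.20), and a LOD loosely tied to the PVE.
#' A configurable fraction of records omits the CI (exercising the
#' formula-based standardization); the rest carry the formula CI
#' explicitly.
#'
#' @param truth a \code{\link{simulation_truth}}.
#' @param consensus consensus \code{genetic_map}.
#' @param study_maps named list of study \code{genetic_map}s (one per
#'   study, keyed by study id), as from \code{\link{simulate_study_map}}.
#' @param seed integer seed.
#' @param missing_ci_fraction fraction of records with CI left missing.
#' @return A \code{qtl_catalog} with extra column
#'   \code{mqtl_truth_id} (the generating true MQTL).
#' @export
simulate_catalog <- function(truth, consensus, study_maps, seed = 1L,
                             missing_ci_fraction = 0.5) {
  set.seed(as.integer(seed))
  n <- truth$n_qtl_total
  tv <- trait_vocabulary()$code
  trait_w <- ifelse(tv == "TGW", 6, 1)       # TGW most frequent
  lens <- chromosome_lengths(consensus)
  mq <- truth$mqtl
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    m <- mq[sample.int(nrow(mq), 1L), ]
    st <- truth$studies[sample.int(nrow(truth$studies), 1L), ]
    regime <- if (stats::runif(1) < truth$rainfed_fraction) "rainfed"
              else "irrigated"
    smap <- study_maps[[st$study_id]]
    warp <- attr(smap, "warp")[[m$chromosome]]
    peak_cons <- stats::rnorm(1L, m$pos_cm, truth$sigma_between)
    peak_cons <- min(max(peak_cons, 0), lens[[m$chromosome]])
    peak <- warp(peak_cons)
    pve <- max(stats::rbeta(1L, 4, 25), 0.007)
    lod <- round(2.5 + 30 * pve + stats::rnorm(1L, 0, 0.5), 2)
    w <- estimate_ci_width(st$pop_type, st$pop_size, pve)
    has_ci <- stats::runif(1) >= missing_ci_fraction
    rows[[i]] <- data.frame(
      qtl_id = sprintf("q%04d", i), study_id = st$study_id,
      pop_type = st$pop_type, pop_size = st$pop_size,
      trait = sample(tv, 1L, prob = trait_w), regime = regime,
      chromosome = m$chromosome, map_id = st$study_id,
      peak_cm = peak,
      ci_lo_cm = if (has_ci) max(0, peak - w / 2) else NA_real_,
      ci_hi_cm = if (has_ci) peak + w / 2 else NA_real_,
      lod = max(lod, 2.5), pve = pve,
      mqtl_truth_id = m$mqtl_truth_id,
      stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  cat <- as_qtl_catalog(df[, CATALOG_COLUMNS])
  cat$mqtl_truth_id <- df$mqtl_truth_id
  cat
}

#' Simulate a complete ready-to-analyze dataset
#'
#' One-call generator: consensus map, per-study maps, catalog, inclusion
#' screening, CI standardization and projection.
#'
#' @param seed integer seed driving every stage.
#' @param n_chrom,length_cm,marker_density consensus-map parameters.
#' @param ... passed to \code{\link{simulation_truth}}.
#' @param missing_ci_fraction see \code{\link{simulate_catalog}}.
#' @param max_ci_cm projection rejection ceiling.
#' @return List: \code{consensus}, \code{study_maps}, \code{truth},
#'   \code{catalog}, \code{projected}.
#' @export
simulate_dataset <- function(seed = 1L, n_chrom = 14L, length_cm = 188,
                             marker_density = 1, ...,
                             missing_ci_fraction = 0.5, max_ci_cm = 50) {
  consensus <- simulate_consensus_map(n_chrom, length_cm, marker_density,
                                      seed = seed)
  truth <- simulation_truth(consensus, seed = seed + 1L, ...)
  study_maps <- lapply(seq_len(nrow(truth$studies)), function(i)
    simulate_study_map(consensus, truth$subset_fraction, truth$distortion,
                       seed = seed + 10L + i,
                       map_id = truth$studies$study_id[i]))
  names(study_maps) <- truth$studies$study_id
  catalog <- simulate_catalog(truth, consensus, study_maps,
                              seed = seed + 2L,
                              missing_ci_fraction = missing_ci_fraction)
  truth_ids <- catalog$mqtl_truth_id
  names(truth_ids) <- catalog$qtl_id
  catalog <- validate_inclusion(catalog)
  catalog <- fill_missing_ci(catalog)
  projected <- project_qtl(catalog, study_maps, consensus,
                           max_ci_cm = max_ci_cm)
  projected$mqtl_truth_id <- truth_ids[projected$qtl_id]
  list(consensus = consensus, study_maps = study_maps, truth = truth,
       catalog = catalog, projected = projected)
}

#' Recovery metrics of a meta-QTL fit against simulation truth
#'
#' Detected MQTL are greedily matched one-to-one to true MQTL positions
#' (closest pairs first) within \code{tolerance_cm}. Reported metrics:
#' \code{k_accuracy} (fraction of chromosome-regime analyses whose
#' detected MQTL count equals the true count), \code{rmse_cm} (over
#' matched pairs), \code{purity} (fraction of members of matched MQTL
#' whose generating true MQTL is the matched one), and counts.
#'
#' @param truth a \code{\link{simulation_truth}}.
#' @param fit a \code{metaqtl} object fitted on projected data carrying
#'   \code{mqtl_truth_id}.
#' @param projected the \code{projected_qtl} used in the fit (with
#'   \code{mqtl_truth_id}).
#' @param tolerance_cm matching tolerance.
#' @return list of metrics.
#' @export
recovery_report <- function(truth, fit, projected, tolerance_cm = 5) {
  tmq <- truth$mqtl
  rmse_sq <- c(); n_match <- 0L; pure <- 0L; members <- 0L
  k_hits <- 0L; k_total <- 0L
  truth_of <- stats::setNames(projected$mqtl_truth_id, projected$qtl_id)
  for (rg in names(fit$results)) for (cr in fit$results[[rg]]) {
    tt <- tmq[tmq$chromosome == cr$chromosome & tmq[[rg]], , drop = FALSE]
    k_total <- k_total + 1L
    if (nrow(cr$mqtl) == nrow(tt)) k_hits <- k_hits + 1L
    if (!nrow(cr$mqtl) || !nrow(tt)) next
    d <- outer(cr$mqtl$peak_cm, tt$pos_cm,
               function(a, b) abs(a - b))
    matched <- list()
    used_i <- used_j <- integer()
    repeat {
      if (all(!is.finite(d)) || min(d) > tolerance_cm) break
      ij <- arrayInd(which.min(d), dim(d))
      i <- ij[1L]; j <- ij[2L]
      matched[[length(matched) + 1L]] <- c(i, j)
      rmse_sq <- c(rmse_sq, d[i, j]^2)
      n_match <- n_match + 1L
      d[i, ] <- Inf; d[, j] <- Inf
    }
    for (m in matched) {
      ids <- strsplit(cr$mqtl$member_qtl_ids[m[1L]], ",")[[1L]]
      gen <- truth_of[ids]
      members <- members + length(ids)
      pure <- pure + sum(gen == tt$mqtl_truth_id[m[2L]], na.rm = TRUE)
    }
  }
  list(k_accuracy = if (k_total) k_hits / k_total else NA_real_,
       rmse_cm = if (n_match) sqrt(mean(rmse_sq)) else NA_real_,
       purity = if (members) pure / members else NA_real_,
       n_matched = n_match, n_true = nrow(tmq))
}
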