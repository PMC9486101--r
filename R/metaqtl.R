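#' @title Meta-QTL construction and the per-regime analysis driver
#' @name metaqtl-engine
NULL

#' Build meta-QTL from a chosen per-chromosome model
#'
#' Observations are assigned to their argmax-posterior component. A
#' component is admitted as a meta-QTL only when it holds at least
#' \code{min_qtl} member QTL from at least \code{min_studies} distinct
#' studies. The MQTL peak is the precision-weighted mean of its members and
#' its 95\% CI width is \eqn{3.92 (\sum_i 1/s_i^2)^{-1/2}} (precision
#' addition). Flanking markers are the nearest consensus markers at or
#' outside the CI bounds. Observations not in an admitted component become
#' singletons, each annotated with the leftover rule it triggers:
#' \code{no_overlap} (its CI intersects no admitted MQTL CI),
#' \code{multi_overlap} (it intersects more than one), or
#' \code{peak_outside} (it intersects exactly one but its peak lies outside
#' that MQTL's CI).
#'
#' @param obs data.frame with columns \code{qtl_id}, \code{study_id},
#'   \code{trait}, \code{x} (consensus peak, cM), \code{s} (SD, cM).
#' @param model a fitted \code{mqtl_mixture} or \code{mqtl_partition}.
#' @param consensus consensus \code{genetic_map}.
#' @param chromosome chromosome name.
#' @param regime \code{"irrigated"} or \code{"rainfed"}.
#' @param min_qtl,min_studies admission thresholds.
#' @param prefix id prefix, default \code{"YIELD_MQTL"}.
#' @return A list of class \code{chromosome_result}: \code{chromosome},
#'   \code{regime}, \code{model}, \code{mqtl} (data.frame), \code{members}
#'   (per-observation MQTL id or NA), \code{singletons} (data.frame with
#'   \code{reason}), \code{n}.
#' @export
build_mqtl <- function(obs, model, consensus, chromosome, regime,
                       min_qtl = 2L, min_studies = 2L,
                       prefix = "YIELD_MQTL") {
  n <- nrow(obs)
  z <- model$assignment
  suffix <- c(irrigated = "I", rainfed = "D")[[regime]]
  comp_ids <- sort(unique(z))
  admitted <- list()
  for (k in comp_ids) {
    idx <- which(z == k)
    if (length(idx) >= min_qtl &&
        length(unique(obs$study_id[idx])) >= min_studies) {
      w <- 1 / obs$s[idx]^2
      peak <- sum(w * obs$x[idx]) / sum(w)
      width <- 3.92 / sqrt(sum(w))
      admitted[[length(admitted) + 1L]] <-
        list(comp = k, idx = idx, peak = peak, width = width)
    }
  }
  # order left-to-right and name
  if (length(admitted)) {
    admitted <- admitted[order(vapply(admitted, `[[`, 0, "peak"))]
    cmap <- map_chromosome(consensus, chromosome)
    rows <- lapply(seq_along(admitted), function(i) {
      a <- admitted[[i]]
      lo <- max(0, a$peak - a$width / 2)
      hi <- a$peak + a$width / 2
      fl <- flanking_markers(cmap, lo, hi)
      data.frame(
        mqtl_id = sprintf("%s%s.%d_%s", prefix, chromosome, i, suffix),
        chromosome = chromosome, regime = regime,
        peak_cm = a$peak, ci95_width_cm = a$width,
        ci_lo_cm = lo, ci_hi_cm = hi,
        n_qtl = length(a$idx),
        n_studies = length(unique(obs$study_id[a$idx])),
        traits = paste(unique(obs$trait[a$idx]), collapse = ","),
        left_marker = fl$left, right_marker = fl$right,
        member_qtl_ids = paste(obs$qtl_id[a$idx], collapse = ","),
        stringsAsFactors = FALSE)
    })
    mqtl <- do.call(rbind, rows)
  } else {
    mqtl <- empty_mqtl_table()
  }
  members <- rep(NA_character_, n)
  for (i in seq_along(admitted))
    members[admitted[[i]]$idx] <- mqtl$mqtl_id[i]
  single_idx <- which(is.na(members))
  singletons <- obs[single_idx, , drop = FALSE]
  singletons$reason <- vapply(single_idx, function(i)
    leftover_reason(obs$x[i], obs$s[i], mqtl), "")
  structure(list(chromosome = chromosome, regime = regime, model = model,
                 mqtl = mqtl, members = members, singletons = singletons,
                 n = n),
            class = "chromosome_result")
}

empty_mqtl_table <- function() {
  data.frame(mqtl_id = character(), chromosome = character(),
             regime = character(), peak_cm = numeric(),
             ci95_width_cm = numeric(), ci_lo_cm = numeric(),
             ci_hi_cm = numeric(), n_qtl = integer(), n_studies = integer(),
             traits = character(), left_marker = character(),
             right_marker = character(), member_qtl_ids = character(),
             stringsAsFactors = FALSE)
}

# nearest consensus markers at/outside the CI bounds
flanking_markers <- function(cmap, lo, hi) {
  if (!nrow(cmap)) return(list(left = NA_character_, right = NA_character_))
  li <- which(cmap$pos_cm <= lo)
  ri <- which(cmap$pos_cm >= hi)
  list(left = if (length(li)) cmap$marker[max(li)] else cmap$marker[1L],
       right = if (length(ri)) cmap$marker[min(ri)] else
         cmap$marker[nrow(cmap)])
}

# the three leftover rules, as interval tests against admitted MQTL CIs
leftover_reason <- function(x, s, mqtl) {
  if (!nrow(mqtl)) return("no_overlap")
  lo <- x - 3.92 * s / 2
  hi <- x + 3.92 * s / 2
  hits <- which(mqtl$ci_lo_cm <= hi & mqtl$ci_hi_cm >= lo)
  if (length(hits) == 0L) "no_overlap"
  else if (length(hits) > 1L) "multi_overlap"
  else if (x < mqtl$ci_lo_cm[hits] || x > mqtl$ci_hi_cm[hits]) "peak_outside"
  else "no_overlap"  # inside one admitted MQTL but its component was not admitted
}

#' Run the meta-analysis for one water regime
#'
#' Per chromosome: with ten or fewer projected QTL the best-contiguous-
#' partition path is used; with more, Gaussian mixtures are fitted by EM
#' for \code{K = 1..min(n, k_max)} and the component count chosen by the
#' five-criterion vote. Deterministic given \code{seed}.
#'
#' @param projected a \code{projected_qtl} data.frame (only rows with
#'   \code{status == "projected"} and the matching \code{regime} are used).
#' @param consensus consensus \code{genetic_map}.
#' @param regime \code{"irrigated"} or \code{"rainfed"}.
#' @param seed integer seed (random restarts of the EM).
#' @param k_max cap on mixture components.
#' @param small_n_max switch point between the two paths (QTL per
#'   chromosome at or below this use the partition path).
#' @param min_qtl,min_studies MQTL admission thresholds.
#' @return List of \code{chromosome_result} keyed by chromosome.
#' @export
run_regime <- function(projected, consensus, regime, seed = 1L,
                       k_max = 10L, small_n_max = 10L,
                       min_qtl = 2L, min_studies = 2L) {
  df <- as.data.frame(projected)
  df <- df[df$status == "projected" & df$regime == regime, , drop = FALSE]
  results <- list()
  for (chrom in sort(unique(df$chromosome))) {
    d <- df[df$chromosome == chrom, , drop = FALSE]
    obs <- data.frame(qtl_id = d$qtl_id, study_id = d$study_id,
                      trait = d$trait, x = d$cons_peak_cm,
                      s = sd_from_ci(pmax(d$cons_ci_hi_cm - d$cons_ci_lo_cm,
                                          1e-6)),
                      stringsAsFactors = FALSE)
    n <- nrow(obs)
    if (n <= small_n_max) {
      pp <- partition_path(obs$x, obs$s)
      model <- pp$model
      model$selection <- pp$selection
    } else {
      ks <- seq_len(min(n, k_max))
      models <- lapply(ks, function(K)
        fit_mixture(obs$x, obs$s, K, seed = seed + 1000L * K))
      sel <- select_model(models)
      model <- models[[sel$index]]
      model$selection <- sel
    }
    results[[chrom]] <- build_mqtl(obs, model, consensus, chrom, regime,
                                   min_qtl, min_studies)
  }
  results
}

#' Fit meta-QTL across chromosomes and regimes
#'
#' The top-level fitting function: takes projected QTL and a consensus map
#' and returns a fitted meta-QTL object covering both water regimes (or a
#' chosen subset).
#'
#' @param projected a \code{projected_qtl} data.frame from
#'   \code{\link{project_qtl}}.
#' @param consensus consensus \code{genetic_map}.
#' @param regimes regimes to analyze.
#' @param seed integer seed.
#' @param ... further arguments passed to \code{\link{run_regime}}.
#' @return An object of class \code{metaqtl}: list with \code{results}
#'   (regime -> chromosome -> \code{chromosome_result}), \code{mqtl}
#'   (combined MQTL table), \code{singletons}, \code{seed}, \code{call}.
#' @examples
#' \donttest{
#' sim <- simulate_dataset(seed = 7)
#' fit <- metaqtl(sim$projected, sim$consensus, seed = 7)
#' summary(fit)
#' }
#' @export
metaqtl <- function(projected, consensus, regimes = REGIMES, seed = 1L,
                    ...) {
  results <- lapply(stats::setNames(regimes, regimes), function(rg)
    run_regime(projected, consensus, rg, seed = seed, ...))
  mqtl <- do.call(rbind, unlist(lapply(results, function(r)
    lapply(r, `[[`, "mqtl")), recursive = FALSE))
  if (is.null(mqtl)) mqtl <- empty_mqtl_table()
  rownames(mqtl) <- NULL
  singles <- do.call(rbind, unlist(lapply(results, function(r)
    lapply(r, function(cr) {
      if (!nrow(cr$singletons)) return(NULL)
      cbind(cr$singletons, chromosome = cr$chromosome, regime = cr$regime,
            stringsAsFactors = FALSE)
    })), recursive = FALSE))
  structure(list(results = results, mqtl = mqtl,
                 singletons = singles, seed = seed,
                 call = match.call()),
            class = "metaqtl")
}

#' @export
print.metaqtl <- function(x, ...) {
  cat("Meta-QTL fit\n")
  for (rg in names(x$results)) {
    m <- x$mqtl[x$mqtl$regime == rg, , drop = FALSE]
    nobs <- sum(vapply(x$results[[rg]], `[[`, 0L, "n"))
    cat(sprintf("  %s: %d QTL on %d chromosomes -> %d MQTL\n",
                rg, nobs, length(x$results[[rg]]), nrow(m)))
  }
  invisible(x)
}

#' @export
summary.metaqtl <- function(object, ...) {
  out <- list(seed = object$seed)
  for (rg in names(object$results)) {
    m <- object$mqtl[object$mqtl$regime == rg, , drop = FALSE]
    out[[rg]] <- list(
      n_mqtl = nrow(m),
      mean_qtl_per_mqtl = if (nrow(m)) mean(m$n_qtl) else NA_real_,
      max_qtl_per_mqtl = if (nrow(m)) max(m$n_qtl) else NA_integer_,
      ci_width = if (nrow(m)) c(min = min(m$ci95_width_cm),
                                mean = mean(m$ci95_width_cm),
                                max = max(m$ci95_width_cm)) else NULL,
      chosen_k = vapply(object$results[[rg]], function(cr) cr$model$K, 0L))
  }
  class(out) <- "summary.metaqtl"
  out
}

#' @export
print.summary.metaqtl <- function(x, ...) {
  for (rg in setdiff(names(x), "seed")) {
    s <- x[[rg]]
    cat(sprintf("%s: %d MQTL", rg, s$n_mqtl))
    if (s$n_mqtl) {
      cat(sprintf(", mean %.2f QTL/MQTL (max %d), CI %.2f-%.2f (mean %.2f) cM",
                  s$mean_qtl_per_mqtl, s$max_qtl_per_mqtl,
                  s$ci_width["min"], s$ci_width["max"], s$ci_width["mean"]))
    }
    cat("\n")
  }
  invisible(x)
}

#' @export
coef.metaqtl <- function(object, ...) {
  object$mqtl[, c("mqtl_id", "chromosome", "regime", "peak_cm",
                  "ci95_width_cm", "n_qtl", "n_studies")]
}

#' Plot meta-QTL positions along chromosomes
#'
#' One horizontal lane per chromosome; MQTL are drawn as segments spanning
#' their 95\% CI with a point at the peak, colour-coded by regime.
#'
#' @param x a \code{metaqtl} object.
#' @param ... passed to \code{plot}.
#' @export
plot.metaqtl <- function(x, ...) {
  m <- x$mqtl
  if (!nrow(m)) { warning("no MQTL to plot"); return(invisible(x)) }
  chroms <- sort(unique(m$chromosome))
  y <- match(m$chromosome, chroms) +
    ifelse(m$regime == "irrigated", 0.15, -0.15)
  col <- ifelse(m$regime == "irrigated", "dodgerblue3", "firebrick3")
  graphics::plot(range(c(m$ci_lo_cm, m$ci_hi_cm)), c(0.5, length(chroms) + 0.5),
                 type = "n", xlab = "consensus position (cM)",
                 ylab = "", yaxt = "n", ...)
  graphics::axis(2, at = seq_along(chroms), labels = chroms, las = 1)
  graphics::segments(m$ci_lo_cm, y, m$ci_hi_cm, y, col = col, lwd = 3)
  graphics::points(m$peak_cm, y, pch = 19, col = col, cex = 0.7)
  graphics::legend("topright", legend = c("irrigated", "rainfed"),
                   col = c("dodgerblue3", "firebrick3"), lwd = 3, bty = "n")
  invisible(x)
}
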