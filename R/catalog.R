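#' @title QTL catalog: I/O, validation, CI standardization, summaries
#' @name catalog
#' @description Functions for reading collections of published QTL,
#'   screening them against the inclusion criteria of the meta-analysis,
#'   materializing missing 95\% confidence intervals from population design,
#'   and summarizing the catalog.
NULL

# Canonical catalog columns. '.' or '' in a file means missing.
CATALOG_COLUMNS <- c("qtl_id", "study_id", "pop_type", "pop_size", "trait",
                     "regime", "chromosome", "map_id", "peak_cm",
                     "ci_lo_cm", "ci_hi_cm", "lod", "pve")
CATALOG_NUMERIC <- c("pop_size", "peak_cm", "ci_lo_cm", "ci_hi_cm",
                     "lod", "pve")

#' Default catalog file dialect
#'
#' A dialect maps the canonical catalog column names to the header names
#' used by a particular file, and fixes the field separator, so published
#' supplements with differing headers can be ingested without code changes.
#'
#' @param columns named character vector: canonical name -> file header.
#'   Only names to override need to be given.
#' @param sep field separator, default tab.
#' @return A list with elements \code{columns} and \code{sep}.
#' @export
catalog_dialect <- function(columns = character(), sep = "\t") {
  map <- stats::setNames(CATALOG_COLUMNS, CATALOG_COLUMNS)
  if (length(columns)) {
    bad <- setdiff(names(columns), CATALOG_COLUMNS)
    if (length(bad))
      stop("unknown canonical column(s) in dialect: ",
           paste(bad, collapse = ", "))
    map[names(columns)] <- columns
  }
  list(columns = map, sep = sep)
}

#' Read a QTL catalog from delimited text
#'
#' Each well-formed row becomes one catalog record; malformed rows are
#' collected in a rejection table rather than aborting the read. PVE values
#' on the percent scale (> 1, <= 100) are converted to proportions, with the
#' conversion recorded in the rejection/log table as an informational entry.
#'
#' @param path path to a delimited text file.
#' @param dialect a \code{\link{catalog_dialect}}.
#' @return A data.frame of class \code{qtl_catalog} with the canonical
#'   columns, an attribute \code{rejections} (data.frame: \code{qtl_id},
#'   \code{reason_code}, \code{detail}) and an attribute \code{conversions}
#'   logging percent-to-proportion PVE rescaling.
#' @export
read_catalog <- function(path, dialect = catalog_dialect()) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  raw <- utils::read.delim(path, sep = dialect$sep, stringsAsFactors = FALSE,
                           check.names = FALSE, na.strings = c("", ".", "NA"))
  missing_cols <- setdiff(unname(dialect$columns), names(raw))
  # optional CI columns may be absent entirely
  optional <- unname(dialect$columns[c("ci_lo_cm", "ci_hi_cm", "lod")])
  hard_missing <- setdiff(missing_cols, optional)
  if (length(hard_missing))
    stop("catalog is missing mandatory column(s): ",
         paste(hard_missing, collapse = ", "))
  df <- data.frame(matrix(nrow = nrow(raw), ncol = 0))
  for (canon in CATALOG_COLUMNS) {
    hdr <- dialect$columns[[canon]]
    df[[canon]] <- if (hdr %in% names(raw)) raw[[hdr]] else NA
  }
  as_qtl_catalog(df)
}

#' Coerce a data.frame to a validated QTL catalog
#'
#' Applies per-row field validation: numeric parses, PVE scale normalization
#' and range checks, CI ordering, population size and trait vocabulary.
#' Rows that fail become rejection records; row order of survivors is
#' preserved.
#'
#' @param df data.frame with the canonical catalog columns.
#' @return A \code{qtl_catalog} (see \code{\link{read_catalog}}).
#' @export
as_qtl_catalog <- function(df) {
  stopifnot(all(CATALOG_COLUMNS %in% names(df)))
  n <- nrow(df)
  rej <- list()
  conv <- list()
  reject <- function(id, code, detail)
    rej[[length(rej) + 1L]] <<- data.frame(qtl_id = as.character(id),
                                           reason_code = code,
                                           detail = detail,
                                           stringsAsFactors = FALSE)
  keep <- rep(TRUE, n)
  for (col in CATALOG_NUMERIC) {
    val <- df[[col]]
    if (!is.numeric(val)) {
      parsed <- suppressWarnings(as.numeric(as.character(val)))
      bad <- which(!is.na(val) & is.na(parsed) &
                     !(trimws(as.character(val)) %in% c("", ".")))
      for (i in bad) {
        reject(df$qtl_id[i], "unparseable_numeric",
               sprintf("%s = '%s'", col, as.character(val[i])))
        keep[i] <- FALSE
      }
      df[[col]] <- parsed
    }
  }
  for (col in c("qtl_id", "study_id", "pop_type", "trait", "regime",
                "chromosome", "map_id"))
    df[[col]] <- trimws(as.character(df[[col]]))

  # PVE percent -> proportion: scale is detected per file (a supplement is
  # either on the percent or the proportion scale); a stray value > 1 in a
  # proportion-scale file is an invariant violation, not a percent
  pve_obs <- df$pve[keep & !is.na(df$pve)]
  percent_file <- length(pve_obs) > 0 && mean(pve_obs > 1) > 0.5 &&
    all(pve_obs <= 100)
  pct <- if (percent_file) which(!is.na(df$pve)) else integer()
  if (length(pct)) {
    conv[[1L]] <- data.frame(qtl_id = df$qtl_id[pct],
                             detail = sprintf("pve %g%% -> %g",
                                              df$pve[pct], df$pve[pct] / 100),
                             stringsAsFactors = FALSE)
    df$pve[pct] <- df$pve[pct] / 100
  }
  for (i in seq_len(n)) {
    if (!keep[i]) next
    r <- df[i, ]
    fail <- function(code, detail) { reject(r$qtl_id, code, detail); keep[i] <<- FALSE }
    if (!is.na(r$pve) && (r$pve <= 0 || r$pve > 1))
      fail("pve_out_of_range", sprintf("pve = %g", r$pve))
    else if (!is.na(r$pop_size) && r$pop_size < 2)
      fail("pop_size_too_small", sprintf("pop_size = %g", r$pop_size))
    else if (!is.na(r$pop_type) && !(r$pop_type %in% POP_TYPES))
      fail("unknown_pop_type", r$pop_type)
    else if (!is.na(r$trait) && !(r$trait %in% trait_vocabulary()$code))
      fail("unknown_trait", r$trait)
    else if (!is.na(r$regime) && !(r$regime %in% REGIMES))
      fail("unknown_regime", r$regime)
    else if (!is.na(r$ci_lo_cm) && !is.na(r$ci_hi_cm) &&
             r$ci_lo_cm > r$ci_hi_cm)
      fail("ci_reversed", sprintf("[%g, %g]", r$ci_lo_cm, r$ci_hi_cm))
    else if (!is.na(r$peak_cm) && !is.na(r$ci_lo_cm) && !is.na(r$ci_hi_cm) &&
             (r$peak_cm < r$ci_lo_cm || r$peak_cm > r$ci_hi_cm))
      fail("peak_outside_ci", sprintf("peak %g not in [%g, %g]",
                                      r$peak_cm, r$ci_lo_cm, r$ci_hi_cm))
  }
  out <- df[keep, CATALOG_COLUMNS, drop = FALSE]
  out$category <- trait_category(out$trait)
  rownames(out) <- NULL
  structure(out,
            rejections = if (length(rej)) do.call(rbind, rej) else
              data.frame(qtl_id = character(), reason_code = character(),
                         detail = character(), stringsAsFactors = FALSE),
            conversions = if (length(conv)) conv[[1L]] else NULL,
            class = c("qtl_catalog", "data.frame"))
}

#' Write a QTL catalog back to delimited text
#'
#' Inverse of \code{\link{read_catalog}}: well-formed catalogs round-trip
#' with all fields preserved. Missing values are written as \code{'.'}.
#'
#' @param catalog a \code{qtl_catalog}.
#' @param path output path.
#' @param sep field separator.
#' @export
write_catalog <- function(catalog, path, sep = "\t") {
  out <- as.data.frame(catalog)[, CATALOG_COLUMNS, drop = FALSE]
  for (col in names(out)) {
    v <- out[[col]]
    v <- if (is.numeric(v)) ifelse(is.na(v), ".", format(v, digits = 15,
                                                         trim = TRUE,
                                                         scientific = FALSE))
         else ifelse(is.na(v), ".", as.character(v))
    out[[col]] <- v
  }
  utils::write.table(out, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Screen records against the meta-analysis inclusion criteria
#'
#' A record is retained only when its mapping-population design and size are
#' known, a position is available (peak, or a CI from which the peak is
#' imputed as the midpoint), a LOD score is reported and the PVE is
#' reported. Total function: every record gets accept or a reason code.
#'
#' @param catalog a \code{qtl_catalog} (or data.frame with its columns).
#' @return The catalog with columns \code{included} (logical) and
#'   \code{exclusion_reason} (\code{NA} when included); records with CI but
#'   no peak get \code{peak_cm} imputed as the CI midpoint.
#' @export
validate_inclusion <- function(catalog) {
  df <- as.data.frame(catalog)
  reason <- rep(NA_character_, nrow(df))
  no_peak <- is.na(df$peak_cm)
  has_ci <- !is.na(df$ci_lo_cm) & !is.na(df$ci_hi_cm)
  imp <- no_peak & has_ci
  df$peak_cm[imp] <- (df$ci_lo_cm[imp] + df$ci_hi_cm[imp]) / 2
  reason[is.na(df$pve)] <- "no_pve"
  reason[is.na(df$lod)] <- "no_lod"
  reason[is.na(df$peak_cm)] <- "no_position"
  reason[is.na(df$pop_size)] <- "no_pop_size"
  reason[is.na(df$pop_type) | df$pop_type == ""] <- "no_pop_type"
  df$included <- is.na(reason)
  df$exclusion_reason <- reason
  attrs <- attributes(catalog)
  structure(df, rejections = attrs$rejections,
            class = c("qtl_catalog", "data.frame"))
}

# design -> numerator of the CI width formula (cM); F2:3 treated as F2,
# MAGIC as RIL (nearest-design rule). Override via the `constants` argument.
CI_CONSTANTS <- c(BC = 530, F2 = 530, "F2:3" = 530, DH = 287,
                  RIL = 163, MAGIC = 163)

#' Expected 95\% CI width of a QTL from design, size and effect
#'
#' Implements the standard population-specific approximations
#' \eqn{CI = 530/(N R^2)} for BC and F2 (and F2:3), \eqn{287/(N R^2)} for
#' doubled haploids, and \eqn{163/(N R^2)} for RIL (and MAGIC), where
#' \eqn{N} is the population size and \eqn{R^2} the proportion of
#' phenotypic variance explained.
#'
#' @param pop_type population design, one of \code{RIL, DH, F2, F2:3, BC,
#'   MAGIC} (vectorized).
#' @param n population size, \eqn{\ge 2}.
#' @param r2 PVE as a proportion in (0, 1].
#' @param constants named numeric override of the design constants.
#' @return CI width in cM.
#' @examples
#' estimate_ci_width("RIL", 163, 1)     # 1
#' estimate_ci_width("F2", 106, 0.05)   # 100
#' @export
estimate_ci_width <- function(pop_type, n, r2, constants = CI_CONSTANTS) {
  if (any(!(pop_type %in% names(constants))))
    stop("unknown pop_type; permitted: ",
         paste(names(constants), collapse = ", "))
  if (any(n < 2)) stop("population size must be >= 2")
  if (any(r2 <= 0 | r2 > 1)) stop("r2 must be in (0, 1]")
  unname(constants[pop_type]) / (n * r2)
}

#' Materialize missing confidence intervals
#'
#' Records with a reported CI are left untouched (reported CIs always take
#' precedence); otherwise the CI is set symmetrically to
#' peak \eqn{\pm} width/2 with the width from
#' \code{\link{estimate_ci_width}}, clipped at 0 and, when a consensus or
#' source map is supplied, at the chromosome length. Idempotent.
#'
#' @param catalog a validated \code{qtl_catalog} with peaks present.
#' @param map optional \code{genetic_map} used for chromosome-length
#'   clipping (matched on \code{map_id} being irrelevant: lengths are taken
#'   per chromosome).
#' @param constants design-constant override, see
#'   \code{\link{estimate_ci_width}}.
#' @return The catalog with \code{ci_lo_cm}/\code{ci_hi_cm} filled and a
#'   logical column \code{ci_from_formula}.
#' @export
fill_missing_ci <- function(catalog, map = NULL, constants = CI_CONSTANTS) {
  df <- as.data.frame(catalog)
  need <- is.na(df$ci_lo_cm) | is.na(df$ci_hi_cm)
  if (any(need & is.na(df$peak_cm)))
    stop("cannot materialize CI without a peak position")
  if (any(need)) {
    w <- estimate_ci_width(df$pop_type[need], df$pop_size[need],
                           df$pve[need], constants)
    lo <- pmax(0, df$peak_cm[need] - w / 2)
    hi <- df$peak_cm[need] + w / 2
    if (!is.null(map)) {
      len <- chromosome_lengths(map)
      lim <- len[df$chromosome[need]]
      hi <- ifelse(!is.na(lim), pmin(hi, lim), hi)
      lo <- ifelse(!is.na(lim), pmin(lo, hi), lo)
    }
    df$ci_lo_cm[need] <- lo
    df$ci_hi_cm[need] <- hi
  }
  prev <- if ("ci_from_formula" %in% names(df)) df$ci_from_formula else FALSE
  df$ci_from_formula <- prev | need
  structure(df, rejections = attr(catalog, "rejections"),
            class = c("qtl_catalog", "data.frame"))
}

#' Summarize a QTL catalog
#'
#' Counts per chromosome, trait, regime and yield-component category, plus
#' CI-width and PVE distribution summaries. CI statistics are computed over
#' records whose CI is materialized.
#'
#' @param catalog a \code{qtl_catalog}.
#' @return A list of class \code{catalog_summary}.
#' @export
summarize_catalog <- function(catalog) {
  df <- as.data.frame(catalog)
  if (!nrow(df)) stop("empty catalog")
  ciw <- df$ci_hi_cm - df$ci_lo_cm
  ciw <- ciw[!is.na(ciw)]
  pve <- df$pve[!is.na(df$pve)]
  s <- list(
    n = nrow(df),
    by_chromosome = table(factor(df$chromosome, levels = CHROMOSOMES)),
    by_trait = table(factor(df$trait, levels = trait_vocabulary()$code)),
    by_regime = table(factor(df$regime, levels = REGIMES)),
    by_category = table(factor(df$category,
                               levels = c("grain_number", "grain_weight"))),
    ci_width = c(min = min(ciw), mean = mean(ciw), max = max(ciw)),
    pve = c(min = min(pve), mean = mean(pve), max = max(pve)),
    frac_ci_lt_10 = mean(ciw < 10),
    frac_ci_lt_20 = mean(ciw < 20)
  )
  class(s) <- "catalog_summary"
  s
}

#' @export
print.catalog_summary <- function(x, ...) {
  cat(sprintf("QTL catalog: %d records\n", x$n))
  cat(sprintf("  regimes: %s\n",
              paste(sprintf("%s %d", names(x$by_regime), x$by_regime),
                    collapse = ", ")))
  cat(sprintf("  CI width (cM): min %.2f mean %.2f max %.2f\n",
              x$ci_width["min"], x$ci_width["mean"], x$ci_width["max"]))
  cat(sprintf("  PVE: min %.3f mean %.3f max %.3f\n",
              x$pve["min"], x$pve["mean"], x$pve["max"]))
  cat(sprintf("  CI < 10 cM: %.1f%%; CI < 20 cM: %.1f%%\n",
              100 * x$frac_ci_lt_10, 100 * x$frac_ci_lt_20))
  invisible(x)
}
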