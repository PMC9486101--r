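#' Read an MQTL characterization table
#'
#' Delimited text with the standard MQTL-table column semantics: Chr,
#' MQTL, Peak (cM), CI (95\%, width in cM), N QTL, N studies, Traits, Left
#' marker, Right marker. A blank Chr cell inherits the chromosome of the
#' previous row (as in typical published table layouts).
#'
#' @param path file path.
#' @param regime regime label attached to the rows.
#' @param sep separator.
#' @return data.frame with columns \code{chromosome}, \code{mqtl_id},
#'   \code{peak_cm}, \code{ci95_width_cm}, \code{n_qtl}, \code{n_studies},
#'   \code{traits}, \code{left_marker}, \code{right_marker},
#'   \code{regime}.
#' @export
read_mqtl_table <- function(path, regime = NA_character_, sep = "\t") {
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE,
                          na.strings = c("", "."))
  names(df) <- c("chromosome", "mqtl_id", "peak_cm", "ci95_width_cm",
                 "n_qtl", "n_studies", "traits", "left_marker",
                 "right_marker")[seq_along(names(df))]
  # fill blank chromosome cells downward
  for (i in seq_len(nrow(df)))
    if (is.na(df$chromosome[i]) && i > 1L)
      df$chromosome[i] <- df$chromosome[i - 1L]
  df$regime <- regime
  df
}

#' Summary statistics of an MQTL table
#'
#' @param mqtl an MQTL table (from \code{\link{read_mqtl_table}} or a
#'   \code{metaqtl} fit).
#' @return list: \code{n_mqtl}, \code{mean_qtl_per_mqtl},
#'   \code{max_qtl_per_mqtl}, \code{ci_width} (min/mean/max),
#'   \code{n_per_chromosome}.
#' @export
summarize_mqtl_table <- function(mqtl) {
  stopifnot(nrow(mqtl) > 0)
  list(n_mqtl = nrow(mqtl),
       mean_qtl_per_mqtl = mean(mqtl$n_qtl),
       max_qtl_per_mqtl = max(mqtl$n_qtl),
       ci_width = c(min = min(mqtl$ci95_width_cm),
                    mean = mean(mqtl$ci95_width_cm),
                    max = max(mqtl$ci95_width_cm)),
       n_per_chromosome = table(mqtl$chromosome))
}

#' Write the MQTL table of a fit
#'
#' TSV with the standard column semantics (Chr, MQTL, Peak (cM), CI
#' (95\%), N QTL, N studies, Traits, Left marker, Right marker).
#'
#' @param mqtl MQTL table.
#' @param path output path.
#' @export
write_mqtl_table <- function(mqtl, path) {
  out <- data.frame(Chr = mqtl$chromosome, MQTL = mqtl$mqtl_id,
                    `Peak (cM)` = round(mqtl$peak_cm, 2),
                    `CI (95%)` = round(mqtl$ci95_width_cm, 2),
                    `N QTL` = mqtl$n_qtl, `N studies` = mqtl$n_studies,
                    Traits = mqtl$traits, `Left marker` = mqtl$left_marker,
                    `Right marker` = mqtl$right_marker,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
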