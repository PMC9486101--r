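#' Read a genetic linkage map
#'
#' Map files are delimited text with columns \code{marker},
#' \code{chromosome}, \code{pos_cm}. Markers are sorted within chromosome
#' by position then name; the same marker listed twice at conflicting
#' positions is an error, exact duplicates are collapsed.
#'
#' @param path path to a delimited file.
#' @param map_id identifier stored on the returned map; defaults to the
#'   file name without extension.
#' @param sep field separator.
#' @return A data.frame of class \code{genetic_map} with columns
#'   \code{marker}, \code{chromosome}, \code{pos_cm} and attribute
#'   \code{map_id}.
#' @export
read_map <- function(path, map_id = NULL, sep = "\t") {
  if (!file.exists(path)) stop("map file not found: ", path)
  df <- utils::read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("marker", "chromosome", "pos_cm")
  if (!all(need %in% names(df)))
    stop("map file must have columns: ", paste(need, collapse = ", "))
  if (is.null(map_id)) map_id <- sub("\\.[^.]*$", "", basename(path))
  as_genetic_map(df[need], map_id)
}

#' Coerce a data.frame to a genetic map
#'
#' @param df data.frame with columns \code{marker}, \code{chromosome},
#'   \code{pos_cm}.
#' @param map_id map identifier.
#' @return A \code{genetic_map}.
#' @export
as_genetic_map <- function(df, map_id = "map") {
  df$marker <- trimws(as.character(df$marker))
  df$chromosome <- trimws(as.character(df$chromosome))
  df$pos_cm <- as.numeric(df$pos_cm)
  if (any(is.na(df$pos_cm))) stop("non-numeric marker position in map")
  if (any(df$pos_cm < 0)) stop("negative marker position in map")
  df <- unique(df)
  dup <- df$marker[duplicated(df$marker)]
  if (length(dup))
    stop("marker(s) at conflicting positions: ",
         paste(unique(dup), collapse = ", "))
  df <- df[order(df$chromosome, df$pos_cm, df$marker), ]
  rownames(df) <- NULL
  structure(df, map_id = map_id, class = c("genetic_map", "data.frame"))
}

#' Write a genetic map to delimited text
#' @param map a \code{genetic_map}.
#' @param path output path.
#' @param sep field separator.
#' @export
write_map <- function(map, path, sep = "\t") {
  utils::write.table(as.data.frame(map), path, sep = sep, quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Chromosome lengths of a map
#'
#' Length of a chromosome is the position of its last marker.
#'
#' @param map a \code{genetic_map}.
#' @return Named numeric vector, cM per chromosome.
#' @export
chromosome_lengths <- function(map) {
  tapply(map$pos_cm, map$chromosome, max)
}

# markers of one chromosome, sorted (maps are stored sorted)
map_chromosome <- function(map, chromosome) {
  map[map$chromosome == chromosome, , drop = FALSE]
}
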