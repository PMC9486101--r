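# Shared fixture builders and independent oracles.

# minimal well-formed catalog data.frame (3 records, 2 studies)
make_catalog_df <- function() {
  data.frame(
    qtl_id = c("q1", "q2", "q3"),
    study_id = c("s1", "s1", "s2"),
    pop_type = c("RIL", "RIL", "DH"),
    pop_size = c(150, 150, 100),
    trait = c("TGW", "GY", "GNPS"),
    regime = c("rainfed", "irrigated", "rainfed"),
    chromosome = c("1A", "1A", "2B"),
    map_id = c("s1", "s1", "s2"),
    peak_cm = c(50, 80, 30),
    ci_lo_cm = c(45, NA, 25),
    ci_hi_cm = c(55, NA, 35),
    lod = c(3.5, 4.2, 2.8),
    pve = c(0.12, 0.08, 0.2),
    stringsAsFactors = FALSE
  )
}

write_tsv_tmp <- function(df) {
  path <- tempfile(fileext = ".tsv")
  out <- df
  for (col in names(out))
    out[[col]] <- ifelse(is.na(out[[col]]), ".", as.character(out[[col]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  path
}

# a simple linear map: markers every `step` cM
make_map <- function(chrom = "1A", len = 100, step = 10, map_id = "m",
                     prefix = "mk") {
  pos <- seq(0, len, by = step)
  as_genetic_map(data.frame(marker = paste0(prefix, "_", chrom, "_", pos),
                            chromosome = chrom, pos_cm = pos,
                            stringsAsFactors = FALSE), map_id = map_id)
}

# independent oracle: best contiguous-partition classification loglik by
# exhaustive enumeration of cut points (model identical to best_partition)
enumerate_partition_loglik <- function(x, s, k) {
  ord <- order(x)
  xo <- x[ord]; so <- s[ord]
  n <- length(x)
  best <- -Inf
  cuts <- utils::combn(n - 1L, k - 1L)
  for (ci in seq_len(ncol(cuts))) {
    ends <- c(cuts[, ci], n)
    starts <- c(1L, utils::head(ends, -1L) + 1L)
    ll <- 0
    for (b in seq_len(k)) {
      idx <- starts[b]:ends[b]
      w <- 1 / so[idx]^2
      mu <- sum(w * xo[idx]) / sum(w)
      ll <- ll + sum(stats::dnorm(xo[idx], mu, so[idx], log = TRUE)) +
        length(idx) * log(length(idx) / n)
    }
    best <- max(best, ll)
  }
  best
}

table_fixture <- function(name) {
  system.file("extdata", name, package = "wheatmqtl", mustWork = TRUE)
}
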