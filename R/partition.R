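#' Best contiguous partition of ordered QTL into k clusters
#'
#' Small-chromosome path of the meta-analysis (ten or fewer QTL): the
#' position-ordered observations are split into \code{k} contiguous blocks,
#' each modelled as a single Gaussian mean with the members' fixed
#' variances, and the partition maximizing the classification
#' log-likelihood is found by dynamic programming over block boundaries.
#' Block means are precision-weighted; block weights are member fractions.
#'
#' @param x observation positions (cM).
#' @param s per-observation standard deviations (cM).
#' @param k number of blocks, \code{1 <= k <= length(x)}.
#' @return A list of class \code{mqtl_partition}: \code{K}, \code{mu}
#'   (sorted block means), \code{pi} (block fractions), \code{loglik} (=
#'   \code{loglik_c}, classification), \code{assignment} (block index per
#'   observation, original order), \code{blocks} (list of observation
#'   indices), \code{n}, \code{criteria}.
#' @export
best_partition <- function(x, s, k) {
  n <- length(x)
  stopifnot(length(s) == n, all(s > 0))
  if (k < 1 || k > n) stop("k must be in 1..n")
  ord <- order(x)
  xo <- x[ord]; so <- s[ord]
  # block_ll[i, j]: classification loglik of one block spanning i..j,
  # including the log block-weight term added later (depends on partition
  # only through block sizes; weight = size/n)
  gauss_ll <- matrix(-Inf, n, n)
  for (i in seq_len(n)) for (j in i:n) {
    idx <- i:j
    mu <- precision_weighted_mean(xo[idx], so[idx])
    gauss_ll[i, j] <- sum(stats::dnorm(xo[idx], mu, so[idx], log = TRUE)) +
      length(idx) * log(length(idx) / n)
  }
  # DP: best[m, j] = best loglik of splitting 1..j into m blocks
  best <- matrix(-Inf, k, n)
  back <- matrix(0L, k, n)
  best[1L, ] <- gauss_ll[1L, ]
  if (k > 1) for (m in 2:k) for (j in m:n) {
    cand <- best[m - 1L, (m - 1L):(j - 1L)] + gauss_ll[m:j, j]
    b <- which.max(cand)
    best[m, j] <- cand[b]
    back[m, j] <- (m - 1L) + b - 1L   # end index of the previous block
  }
  # trace back block end indices
  ends <- integer(k)
  j <- n
  if (k > 1) for (m in k:2) {
    ends[m] <- j
    j <- back[m, j]
  }
  ends[1L] <- j
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  blocks <- mapply(function(a, b) ord[a:b], starts, ends, SIMPLIFY = FALSE)
  mu <- vapply(blocks, function(idx) precision_weighted_mean(x[idx], s[idx]),
               0)
  pi <- vapply(blocks, length, 0L) / n
  assignment <- integer(n)
  for (b in seq_along(blocks)) assignment[blocks[[b]]] <- b
  ll <- best[k, n]
  out <- list(K = k, mu = mu, pi = pi, loglik = ll, loglik_c = ll,
              assignment = assignment, blocks = blocks, n = n,
              method = "partition")
  out$criteria <- criteria_values(out, n)
  class(out) <- "mqtl_partition"
  out
}

#' Partition-path model choice over candidate block counts
#'
#' Candidate block counts are \code{1..min(n, 4)} plus \code{n} (every
#' observation its own cluster); the winner is chosen by the same
#' five-criterion vote as the mixture path.
#'
#' @param x,s positions and standard deviations.
#' @return A list: \code{model} (the chosen \code{mqtl_partition}),
#'   \code{selection} (see \code{\link{select_model}}), \code{candidates}.
#' @export
partition_path <- function(x, s) {
  n <- length(x)
  ks <- sort(unique(c(seq_len(min(n, 4L)), n)))
  models <- lapply(ks, function(k) best_partition(x, s, k))
  sel <- select_model(models)
  list(model = models[[sel$index]], selection = sel, candidates = models)
}
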