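#' @title Gaussian mixture meta-model with fixed per-observation variances
#' @name mixture
#' @description The meta-analysis treats each projected QTL peak \eqn{x_i}
#'   as a draw from a K-component Gaussian mixture in which the component
#'   means are the unknown meta-QTL positions and the variance of each
#'   observation is fixed at \eqn{s_i^2}, derived from its own 95\% CI.
#'   Only the K means and K-1 mixing weights are estimated (p = 2K-1 free
#'   parameters).
NULL

#' Standard deviation implied by a 95\% confidence-interval width
#'
#' Under the Gaussian convention a 95\% CI spans \eqn{2 \times 1.96}
#' standard deviations, so \eqn{s = width / 3.92}.
#'
#' @param ci_width CI width in cM (positive).
#' @return Standard deviation in cM.
#' @examples
#' sd_from_ci(3.92)  # 1
#' @export
sd_from_ci <- function(ci_width) {
  if (any(ci_width <= 0)) stop("CI width must be positive")
  ci_width / 3.92
}

# log-likelihood pieces -------------------------------------------------

# n x K matrix of log(pi_k) + log phi(x_i; mu_k, s_i^2)
log_component_density <- function(x, s, mu, pi) {
  outer(x, mu, function(xi, m) stats::dnorm(xi, m, rep(s, length.out =
                                                         length(xi)), log = TRUE)) +
    rep(log(pi), each = length(x))
}

logsumexp_rows <- function(m) {
  mx <- apply(m, 1L, max)
  mx + log(rowSums(exp(m - mx)))
}

mixture_loglik <- function(x, s, mu, pi) {
  sum(logsumexp_rows(log_component_density(x, s, mu, pi)))
}

# classification (hard-assignment) log-likelihood given posteriors
classification_loglik <- function(x, s, mu, pi) {
  ld <- log_component_density(x, s, mu, pi)
  sum(ld[cbind(seq_along(x), max.col(ld, ties.method = "first"))])
}

# precision-weighted mean: the K = 1 closed form
precision_weighted_mean <- function(x, s) {
  w <- 1 / s^2
  sum(w * x) / sum(w)
}

#' Fit a K-component mixture by EM
#'
#' Expectation-maximization for the fixed-variance mixture
#' \eqn{x_i \sim \sum_k \pi_k N(\mu_k, s_i^2)}. The M step updates
#' \eqn{\mu_k} as the posterior-precision-weighted mean and \eqn{\pi_k} as
#' the mean responsibility. Runs a deterministic start (K weighted
#' quantiles of x) plus seeded random restarts and keeps the best
#' log-likelihood; the log-likelihood is checked to be non-decreasing
#' across iterations. K = 1 uses the closed-form precision-weighted mean.
#'
#' @param x observation positions (cM).
#' @param s per-observation standard deviations (cM, positive).
#' @param K number of components, \code{1 <= K <= length(x)}.
#' @param seed integer seed for the random restarts.
#' @param n_restarts number of random restarts on top of the
#'   deterministic start.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap per start.
#' @return A list of class \code{mqtl_mixture}: \code{K}, \code{mu}
#'   (sorted), \code{pi}, \code{loglik}, \code{loglik_c} (classification),
#'   \code{posterior} (n x K), \code{assignment}, \code{n}, \code{criteria}
#'   (see \code{\link{criteria_values}}).
#' @export
fit_mixture <- function(x, s, K, seed = 1L, n_restarts = 10L,
                        tol = 1e-8, max_iter = 2000L) {
  n <- length(x)
  stopifnot(length(s) == n, all(s > 0))
  if (K < 1 || K > n) stop("K must be in 1..n")
  if (K == 1) {
    mu <- precision_weighted_mean(x, s)
    fit <- list(mu = mu, pi = 1, loglik = sum(stats::dnorm(x, mu, s,
                                                           log = TRUE)))
  } else {
    starts <- list(weighted_quantile_start(x, s, K))
    rng <- local({ set.seed(as.integer(seed)); function(k)
      sort(sample(x, k, replace = FALSE,
                  prob = (1 / s^2) / sum(1 / s^2))) })
    for (r in seq_len(n_restarts)) starts[[r + 1L]] <- rng(K)
    best <- NULL
    for (mu0 in starts) {
      f <- em_run(x, s, mu0, tol, max_iter)
      # penalize collapsed components (pi_k < 1/(10 n))
      if (any(f$pi < 1 / (10 * n))) f$loglik <- f$loglik - 1e6
      if (is.null(best) || f$loglik > best$loglik) best <- f
    }
    fit <- best
    fit$loglik <- mixture_loglik(x, s, fit$mu, fit$pi)  # undo any penalty
  }
  ord <- order(fit$mu)
  mu <- fit$mu[ord]; pi <- fit$pi[ord]
  ld <- log_component_density(x, s, mu, pi)
  post <- exp(ld - logsumexp_rows(ld))
  out <- list(K = K, mu = mu, pi = pi, loglik = fit$loglik,
              loglik_c = classification_loglik(x, s, mu, pi),
              posterior = post,
              assignment = assign_components(x, post, mu),
              n = n, method = "mixture")
  out$criteria <- criteria_values(out, n)
  class(out) <- "mqtl_mixture"
  out
}

# deterministic start: precision-weighted quantiles of x
weighted_quantile_start <- function(x, s, K) {
  ord <- order(x)
  w <- (1 / s^2)[ord]
  cw <- cumsum(w) / sum(w)
  probs <- (seq_len(K) - 0.5) / K
  sapply(probs, function(p) x[ord][which.max(cw >= p)])
}

em_run <- function(x, s, mu, tol, max_iter) {
  K <- length(mu)
  pi <- rep(1 / K, K)
  w <- 1 / s^2
  ll_old <- -Inf
  for (iter in seq_len(max_iter)) {
    ld <- log_component_density(x, s, mu, pi)
    ll <- sum(logsumexp_rows(ld))
    if (ll < ll_old - 1e-7)
      stop("EM log-likelihood decreased: ", ll_old, " -> ", ll)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) <= tol * (abs(ll_old) + tol)) break
    ll_old <- ll
    post <- exp(ld - logsumexp_rows(ld))
    pw <- post * w
    denom <- colSums(pw)
    mu <- ifelse(denom > 0, colSums(pw * x) / denom, mu)
    pi <- colMeans(post)
    pi <- pmax(pi, .Machine$double.xmin)
    pi <- pi / sum(pi)
  }
  list(mu = mu, pi = pi, loglik = ll)
}

# argmax-posterior assignment; exact ties go to the nearer mean, then the
# lower-index component (deterministic)
assign_components <- function(x, post, mu) {
  n <- nrow(post)
  z <- integer(n)
  for (i in seq_len(n)) {
    m <- max(post[i, ])
    cand <- which(post[i, ] == m)
    if (length(cand) > 1L) {
      d <- abs(x[i] - mu[cand])
      cand <- cand[d == min(d)]
    }
    z[i] <- cand[1L]
  }
  z
}

#' Information criteria of a fitted meta-model
#'
#' With \eqn{p = 2K - 1} free parameters and maximized log-likelihood
#' \eqn{\ln L}: \eqn{AIC = -2\ln L + 2p};
#' \eqn{AICc = AIC + 2p(p+1)/(n-p-1)} (reported as \code{Inf} when
#' \eqn{n - p - 1 \le 0}); \eqn{AIC3 = -2\ln L + 3p};
#' \eqn{BIC = -2\ln L + p\ln n}; and
#' \eqn{AWE = -2\ln L_c + 2p(3/2 + \ln n)} where \eqn{\ln L_c} is the
#' classification (hard-assignment) log-likelihood.
#'
#' @param model a fitted model with elements \code{K}, \code{loglik},
#'   \code{loglik_c}.
#' @param n number of observations.
#' @return Named numeric vector \code{AIC, AICc, AIC3, BIC, AWE}.
#' @export
criteria_values <- function(model, n) {
  p <- 2 * model$K - 1
  m2ll <- -2 * model$loglik
  aic <- m2ll + 2 * p
  aicc <- if (n - p - 1 > 0) aic + 2 * p * (p + 1) / (n - p - 1) else Inf
  c(AIC = aic,
    AICc = aicc,
    AIC3 = m2ll + 3 * p,
    BIC = m2ll + p * log(n),
    AWE = -2 * model$loglik_c + 2 * p * (3 / 2 + log(n)))
}

#' Choose K by majority vote over five criteria
#'
#' The chosen model is the candidate attaining the minimum of at least
#' three of the five criteria (AIC, AICc, AIC3, BIC, AWE). When no
#' candidate gathers three votes, the AICc minimizer is used and the
#' result flagged as a fallback.
#'
#' @param models list of fitted models, each with a \code{criteria}
#'   element.
#' @return A list: \code{index} of the chosen model, \code{K},
#'   \code{votes} per candidate, \code{fallback} logical,
#'   \code{criteria_table} (candidates x criteria).
#' @export
select_model <- function(models) {
  stopifnot(length(models) >= 1)
  tab <- t(vapply(models, function(m) m$criteria, numeric(5)))
  rownames(tab) <- vapply(models, function(m) as.character(m$K), "")
  votes <- integer(length(models))
  for (j in seq_len(ncol(tab))) {
    col <- tab[, j]
    if (all(!is.finite(col))) next
    winners <- which(col == min(col[is.finite(col)]))
    votes[winners[1L]] <- votes[winners[1L]] + 1L  # ties: first (smaller K)
  }
  if (max(votes) >= 3) {
    idx <- which.max(votes)
    fallback <- FALSE
  } else {
    aicc <- tab[, "AICc"]
    if (!any(is.finite(aicc))) aicc <- tab[, "AIC"]  # AICc inadmissible
    idx <- which(aicc == min(aicc[is.finite(aicc)]))[1L]
    fallback <- TRUE
  }
  list(index = idx, K = models[[idx]]$K, votes = votes,
       fallback = fallback, criteria_table = tab)
}
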