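#' @name gmm
#' @title Gaussian mixture model: density, EM fitting, sampling
#' @description
#' An n-branch Gaussian mixture over d-dimensional vectors: density
#' `p(a) = sum_x b_x N(a; mu_x, Sigma_x)` with branch weights `b_x >= 0`
#' summing to one and the standard multivariate normal branch density
#' `(2 pi)^{-d/2} |Sigma_x|^{-1/2} exp(-1/2 (a - mu_x)' Sigma_x^{-1}
#' (a - mu_x))`.  Fitted by expectation--maximization with a diagonal
#' covariance floor, and sampled branch-first; the sampler drives the
#' genetic algorithm's offspring generator.
NULL

GMM_COV_FLOOR <- 1e-6

#' Construct and validate mixture parameters
#'
#' @param weights branch weights, non-negative, summing to 1
#' @param means n x d matrix of branch means (one row per branch)
#' @param covariances list of d x d symmetric positive-definite matrices
#' @return a `gmm_params` object (`n`, `d`, `weights`, `means`, `covariances`)
#' @export
gmm_params <- function(weights, means, covariances) {
  means <- as.matrix(means)
  n <- nrow(means); d <- ncol(means)
  check(length(weights) == n && all(weights >= 0),
        "weights must be non-negative, one per branch")
  check(abs(sum(weights) - 1) <= 1e-12, "branch weights must sum to 1")
  check(is.list(covariances) && length(covariances) == n,
        "need one covariance matrix per branch")
  for (S in covariances) {
    check(is.matrix(S) && all(dim(S) == d), "covariance dimension mismatch")
    check(max(abs(S - t(S))) <= 1e-8, "covariance must be symmetric")
    ok <- tryCatch({ chol(S); TRUE }, error = function(e) FALSE)
    check(ok, "singular (non positive-definite) covariance: below the floor epsilon")
  }
  structure(list(n = n, d = d, weights = as.numeric(weights), means = means,
                 covariances = covariances),
            class = "gmm_params")
}

# Per-branch log densities at rows of A: N_total x n matrix.
gmm_branch_logdens <- function(A, params) {
  A <- as.matrix(A)
  d <- params$d
  out <- matrix(NA_real_, nrow(A), params$n)
  for (x in seq_len(params$n)) {
    R <- chol(params$covariances[[x]])
    dev <- sweep(A, 2, params$means[x, ])
    # whiten: solve R' u = dev'
    u <- forwardsolve(t(R), t(dev))
    q <- colSums(u^2)
    out[, x] <- -0.5 * d * log(2 * pi) - sum(log(diag(R))) - 0.5 * q
  }
  out
}

#' Mixture density
#'
#' @param a a d-vector, or a matrix with one point per row
#' @param params a [gmm_params()]
#' @return strictly positive density value(s)
#' @export
#' @examples
#' p <- gmm_params(1, matrix(0, 1, 1), list(matrix(1, 1, 1)))
#' gmm_pdf(0, p)  # 1/sqrt(2*pi)
gmm_pdf <- function(a, params) {
  check(inherits(params, "gmm_params"), "params must come from gmm_params()")
  A <- if (is.matrix(a)) a else matrix(a, 1)
  check(ncol(A) == params$d, "point dimension mismatch")
  ld <- gmm_branch_logdens(A, params)
  dens <- as.vector(exp(ld) %*% params$weights)
  if (!is.matrix(a)) dens[1] else dens
}

# kmeans++-style seeding: first center uniform, then each next center
# drawn with probability proportional to squared distance to the nearest
# chosen center.  Draws from the current RNG.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  idx <- sample.int(n, 1)
  centers <- X[idx, , drop = FALSE]
  d2 <- rowSums(sweep(X, 2, centers[1, ])^2)
  while (nrow(centers) < k) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = prob)
    centers <- rbind(centers, X[idx, ])
    d2 <- pmin(d2, rowSums(sweep(X, 2, X[idx, ])^2))
  }
  centers
}

#' Fit a Gaussian mixture by expectation--maximization
#'
#' Standard EM with kmeans++-style seeded initialization; every covariance
#' gets `floor * I` added to its diagonal so it stays invertible even on
#' tiny or degenerate sample pools.  Iteration stops when the
#' log-likelihood gain drops below `tol` or at `max_iter`.
#'
#' @param samples N x d matrix (N >= n_components)
#' @param n_components branch count
#' @param seed initialization seed
#' @param tol log-likelihood convergence tolerance
#' @param max_iter iteration budget
#' @param floor diagonal covariance floor epsilon
#' @return a [gmm_params()] with attribute `"loglik"` (per-iteration trace)
#' @export
fit_gmm_em <- function(samples, n_components, seed = NULL, tol = 1e-6,
                       max_iter = 200L, floor = GMM_COV_FLOOR) {
  X <- as.matrix(samples)
  N <- nrow(X); d <- ncol(X)
  check(is_count(n_components), "n_components must be a positive integer")
  check(N >= n_components, "need at least as many samples as components")
  k <- as.integer(n_components)

  mu <- with_seed(seed, kmeanspp_centers(X, k))
  S0 <- stats::cov(X) * (N - 1) / N + diag(floor, d)
  if (N < 2) S0 <- diag(1, d)
  covs <- replicate(k, S0, simplify = FALSE)
  w <- rep(1 / k, k)
  ll_trace <- numeric(0)
  prev_ll <- -Inf

  for (it in seq_len(max_iter)) {
    params <- gmm_params(w, mu, covs)
    ld <- gmm_branch_logdens(X, params)                  # N x k
    lw <- sweep(ld, 2, log(w), "+")
    m <- apply(lw, 1, max)
    lse <- m + log(rowSums(exp(lw - m)))
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(lw - lse)                                # responsibilities
    if (is.finite(prev_ll) && ll - prev_ll < tol) break
    prev_ll <- ll
    nk <- colSums(resp)
    nk[nk < 1e-12] <- 1e-12
    w <- nk / N
    mu <- (t(resp) %*% X) / nk
    for (x in seq_len(k)) {
      dev <- sweep(X, 2, mu[x, ])
      S <- t(dev * resp[, x]) %*% dev / nk[x]
      covs[[x]] <- (S + t(S)) / 2 + diag(floor, d)
    }
  }
  out <- gmm_params(w, mu, covs)
  attr(out, "loglik") <- ll_trace
  out
}

#' Draw samples from a Gaussian mixture
#'
#' Branch chosen by weight, then a Gaussian draw via the Cholesky factor.
#'
#' @param params a [gmm_params()]
#' @param n_draws number of draws (>= 1)
#' @param seed integer seed
#' @return n_draws x d matrix
#' @export
sample_gmm <- function(params, n_draws, seed = NULL) {
  check(inherits(params, "gmm_params"), "params must come from gmm_params()")
  check(is_count(n_draws), "n_draws must be >= 1")
  with_seed(seed, {
    comp <- sample.int(params$n, n_draws, replace = TRUE, prob = params$weights)
    out <- matrix(NA_real_, n_draws, params$d)
    for (x in unique(comp)) {
      idx <- which(comp == x)
      R <- chol(params$covariances[[x]])
      Z <- matrix(rnorm(length(idx) * params$d), length(idx), params$d)
      out[idx, ] <- sweep(Z %*% R, 2, params$means[x, ], "+")
    }
    out
  })
}
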