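# Independent oracles used by the unit and acceptance tests.  These are
# deliberately naive (brute force, enumeration, quadrature) and share no
# code with the package implementation.

# per-pixel averaging oracle for block-score reassembly
oracle_reassemble <- function(grid, scores) {
  h <- grid$source_shape[1]; w <- grid$source_shape[2]
  K <- ncol(scores); b <- grid$block_size
  out <- matrix(NA_integer_, h, w)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    acc <- numeric(K); n <- 0
    for (i in seq_len(nrow(grid$origins))) {
      r0 <- grid$origins[i, 1]; c0 <- grid$origins[i, 2]
      if (r > r0 && r <= r0 + b && c > c0 && c <= c0 + b) {
        acc <- acc + scores[i, ]; n <- n + 1
      }
    }
    m <- acc / n
    out[r, c] <- which(m == max(m))[1] - 1L
  }
  out
}

# exhaustive minimum s-t cut of a small directed network
oracle_min_cut <- function(n_nodes, from, to, cap, source, sink) {
  others <- setdiff(seq_len(n_nodes), c(source, sink))
  best <- Inf
  for (mask in 0:(2^length(others) - 1)) {
    s_side <- c(source, others[bitwAnd(mask, 2^(seq_along(others) - 1)) > 0])
    cut <- sum(cap[from %in% s_side & !(to %in% s_side)])
    best <- min(best, cut)
  }
  best
}

# exhaustive scan of all 256 candidate bin thresholds maximizing the
# between-class variance, computed by a naive loop over the histogram
oracle_otsu <- function(v, bins = 256L) {
  breaks <- seq(0, 1, length.out = bins + 1)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  cnt <- tabulate(pmin(floor(v * bins), bins - 1) + 1L, nbins = bins)
  p <- cnt / sum(cnt)
  best_k <- NA_integer_; best_s <- -Inf
  for (k in seq_len(bins - 1)) {
    w0 <- sum(p[1:k]); w1 <- 1 - w0
    if (w0 <= 0 || w1 <= 0) next
    mu0 <- sum(p[1:k] * mids[1:k]) / w0
    mu1 <- sum(p[(k + 1):bins] * mids[(k + 1):bins]) / w1
    s <- w0 * w1 * (mu0 - mu1)^2
    if (s > best_s) { best_s <- s; best_k <- k }
  }
  breaks[best_k + 1]
}

# central finite-difference gradient of the per-sample squared error
# E = sum((y - t)^2) / 2 through a numeric copy of the forward pass
oracle_fd_gradient <- function(model, x, target, eps = 1e-6) {
  loss_at <- function(m) {
    s <- function(z) 1 / (1 + exp(-z))
    h <- s(as.vector(m$W1 %*% x) + m$b1)
    y <- s(as.vector(m$W2 %*% h) + m$b2)
    sum((y - target)^2) / 2
  }
  out <- list()
  for (p in c("W1", "b1", "W2", "b2")) {
    g <- model[[p]]
    for (i in seq_along(g)) {
      mp <- model; mp[[p]][i] <- mp[[p]][i] + eps
      mm <- model; mm[[p]][i] <- mm[[p]][i] - eps
      g[i] <- (loss_at(mp) - loss_at(mm)) / (2 * eps)
    }
    out[[p]] <- g
  }
  out
}

# brute-force point-in-ellipse pixel count on the integer grid
oracle_ellipse_area <- function(h, w, center, semi_axes) {
  n <- 0
  for (r in seq_len(h)) for (c in seq_len(w)) {
    if (((r - center[1]) / semi_axes[1])^2 +
        ((c - center[2]) / semi_axes[2])^2 <= 1) n <- n + 1
  }
  n
}

# deterministic small phantom sets for pipeline-level tests
tiny_phantom_pairs <- function(n_per_class = 1, size = 96L, noise_sd = 0,
                               seed = 5L) {
  make_phantom_set(n_per_class, seed = seed, size = size, noise_sd = noise_sd)
}

# fast optimizer settings for tests that only need plumbing, not quality
tiny_cfg <- function() {
  cfg <- default_config()
  cfg$ga$population_size <- 8L
  cfg$ga$max_generations <- 3L
  cfg$ga$plateau_window <- 3L
  cfg$bpnn$max_epochs <- 5L
  cfg$bpnn$balance_per_class <- 50L
  cfg$graphcut$lambda_grid <- 1
  cfg
}
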