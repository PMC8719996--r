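#' @name graphcut
#' @title Max-flow/min-cut segmentation refinement
#' @description
#' Maps an image plus a per-pixel foreground-probability map into a
#' source/sink flow network -- terminal link capacities are negative log
#' probabilities, 4-neighbor links carry a Gaussian intensity-similarity
#' capacity `lambda * exp(-(I_p - I_q)^2 / (2 sigma^2))` -- and segments
#' by computing an exact maximum flow; by the max-flow/min-cut theorem the
#' induced minimum cut is the minimum-energy binary labeling.
NULL

#' Build the pixel-lattice flow network
#'
#' Pixels are nodes `1 .. H*W` (column-major, matching R matrix layout);
#' node `H*W + 1` is the source (foreground terminal) and `H*W + 2` the
#' sink.  For foreground probability `p` clamped to `[delta, 1 - delta]`:
#' the source->pixel capacity is `-ln(1 - p)` and the pixel->sink capacity
#' `-ln(p)`, so each terminal link carries the cost of the *opposing*
#' label.  Neighbor links (4-connectivity) are symmetric with capacity
#' `lambda * exp(-(I_p - I_q)^2 / (2 sigma^2))`.
#'
#' @param image numeric matrix of intensities in `[0,1]`
#' @param fg_prob matrix of foreground probabilities, same shape
#' @param lambda_ pairwise smoothness weight (>= 0)
#' @param sigma_ intensity-similarity scale (> 0)
#' @param delta probability clamp
#' @return a `flow_network` list: `n_nodes`, `from`, `to`, `cap`, `source`,
#'   `sink`, `shape`
#' @export
build_flow_network <- function(image, fg_prob, lambda_ = 1.0, sigma_ = 0.1,
                               delta = 1e-6) {
  check(is.matrix(image) && is.matrix(fg_prob), "image and fg_prob must be matrices")
  check(all(dim(image) == dim(fg_prob)), "image and fg_prob shapes must match")
  check(all(fg_prob >= 0 & fg_prob <= 1), "probabilities must lie in [0,1]")
  check(lambda_ >= 0, "lambda_ must be >= 0")
  check(sigma_ > 0, "sigma_ must be > 0")
  h <- nrow(image); w <- ncol(image)
  n_px <- h * w
  source <- n_px + 1L; sink <- n_px + 2L
  p <- clamp(as.vector(fg_prob), delta, 1 - delta)
  id <- matrix(seq_len(n_px), h, w)

  from <- c(rep(source, n_px), seq_len(n_px))
  to <- c(seq_len(n_px), rep(sink, n_px))
  cap <- c(-log(1 - p), -log(p))

  if (lambda_ > 0) {
    # vertical neighbors
    a <- as.vector(id[-h, , drop = FALSE]); b <- as.vector(id[-1, , drop = FALSE])
    wv <- lambda_ * exp(-(as.vector(image)[a] - as.vector(image)[b])^2 / (2 * sigma_^2))
    # horizontal neighbors
    a2 <- as.vector(id[, -w, drop = FALSE]); b2 <- as.vector(id[, -1, drop = FALSE])
    wh <- lambda_ * exp(-(as.vector(image)[a2] - as.vector(image)[b2])^2 / (2 * sigma_^2))
    from <- c(from, a, b, a2, b2)
    to <- c(to, b, a, b2, a2)
    cap <- c(cap, wv, wv, wh, wh)
  }
  structure(list(n_nodes = n_px + 2L, from = as.integer(from),
                 to = as.integer(to), cap = as.numeric(cap),
                 source = source, sink = sink, shape = c(h, w)),
            class = "flow_network")
}

#' Exact maximum flow and minimum cut
#'
#' Dinic's breadth-first shortest-augmenting-path algorithm (compiled).
#' The reported partition is residual-graph reachability from the source,
#' so its crossing capacity equals the flow value (verified in the tests).
#'
#' @param net a `flow_network` (from [build_flow_network()]) or a list with
#'   fields `n_nodes`, `from`, `to`, `cap`, `source`, `sink`
#' @return a `cut_result`: `max_flow_value` and `source_side` (1-based node
#'   indices on the source side of the cut, including the source itself)
#' @export
max_flow <- function(net) {
  check(all(c("n_nodes", "from", "to", "cap", "source", "sink") %in% names(net)),
        "net must carry n_nodes, from, to, cap, source, sink")
  check(all(net$cap >= 0), "capacities must be non-negative")
  res <- maxflow_dinic(net$n_nodes, as.integer(net$from), as.integer(net$to),
                       as.numeric(net$cap), as.integer(net$source),
                       as.integer(net$sink))
  structure(list(max_flow_value = res$flow, source_side = res$source_side),
            class = "cut_result")
}

# binary foreground mask from one cut
cut_to_mask <- function(net, cut) {
  h <- net$shape[1]; w <- net$shape[2]
  m <- matrix(0L, h, w)
  px <- cut$source_side[cut$source_side <= h * w]
  m[px] <- 1L
  m
}

#' Graph-cut refinement of a per-pixel class-probability map
#'
#' For two classes a single cut on the probability of the higher label;
#' for K > 2, one-vs-rest cuts per class in decreasing label order (the
#' rarer structures first: an ascending order would let the huge
#' background class absorb the boundary bands) -- a pixel takes the first
#' class whose cut places it on the foreground (source) side, with
#' per-pixel argmax as the fallback for pixels no cut claims.
#' Probabilities that do not sum to one per pixel are renormalized with a
#' warning.
#'
#' @param image numeric intensity matrix
#' @param class_probs `H x W x K` array of per-pixel class probabilities
#'   (columns ordered by label `0 .. K-1`)
#' @param lambda_,sigma_ energy parameters, see [build_flow_network()]
#' @return integer label mask (`0 .. K-1`)
#' @export
graphcut_refine <- function(image, class_probs, lambda_ = 1.0, sigma_ = 0.1) {
  check(length(dim(class_probs)) == 3, "class_probs must be H x W x K")
  K <- dim(class_probs)[3]
  check(K >= 2, "need at least two classes")
  check(all(dim(class_probs)[1:2] == dim(image)), "shape mismatch with image")
  tot <- apply(class_probs, c(1, 2), sum)
  if (max(abs(tot - 1)) > 1e-6) {
    warning("class probabilities do not sum to 1 per pixel; renormalizing")
    for (k in seq_len(K)) class_probs[, , k] <- class_probs[, , k] / tot
  }
  if (K == 2) {
    net <- build_flow_network(image, class_probs[, , 2], lambda_, sigma_)
    return(cut_to_mask(net, max_flow(net)))
  }
  h <- dim(image)[1]; w <- dim(image)[2]
  out <- matrix(NA_integer_, h, w)
  for (k in rev(seq_len(K))) {
    net <- build_flow_network(image, class_probs[, , k], lambda_, sigma_)
    fg <- cut_to_mask(net, max_flow(net)) == 1L
    take <- fg & is.na(out)
    out[take] <- k - 1L
  }
  rest <- is.na(out)
  if (any(rest)) {
    am <- probs_argmax(class_probs)
    out[rest] <- am[rest]
  }
  out
}
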