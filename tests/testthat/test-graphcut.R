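test_that("terminal capacities are the negative log of the opposing label", {
  img <- matrix(c(0.5, 0.5), 2, 1)
  d <- 1e-6
  net <- build_flow_network(img, matrix(c(1 - d, d), 2, 1), lambda_ = 0.5)
  # first 2 arcs: source->pixel (-ln(1-p)); next 2: pixel->sink (-ln p)
  expect_equal(net$cap[1:2], -log(1 - c(1 - d, d)), tolerance = 1e-9)
  expect_equal(net$cap[3:4], -log(c(1 - d, d)), tolerance = 1e-9)
  cut <- max_flow(net)
  px_side <- intersect(cut$source_side, 1:2)
  expect_equal(px_side, 1L)  # p ~ 1 forced to source, p ~ 0 to sink
})

test_that("uniform images couple neighbors with capacity lambda exactly", {
  img <- matrix(0.7, 3, 3)
  net <- build_flow_network(img, matrix(0.5, 3, 3), lambda_ = 2.5)
  nbr <- net$cap[-(1:18)]  # after the 2*9 terminal links
  expect_true(all(nbr == 2.5))
  expect_error(build_flow_network(img, matrix(0.5, 2, 2)),
               class = "obstruseg_validation_error")
  expect_error(build_flow_network(img, matrix(2, 3, 3)),
               class = "obstruseg_validation_error")
})

test_that("the classic 4-node network has max flow 5", {
  # nodes: 1=a, 2=b, 3=source, 4=sink
  net <- list(n_nodes = 4, from = c(3, 3, 1, 1, 2), to = c(1, 2, 2, 4, 4),
              cap = c(3, 2, 1, 2, 3), source = 3, sink = 4)
  res <- max_flow(net)
  expect_equal(res$max_flow_value, 5)
  expect_error(max_flow(list(n_nodes = 3, from = 1, to = 2, cap = -1,
                             source = 1, sink = 2)),
               class = "obstruseg_validation_error")
})

test_that("zero capacities give zero flow and an empty source side", {
  net <- list(n_nodes = 4, from = c(3, 1, 2), to = c(1, 2, 4),
              cap = c(0, 0, 0), source = 3, sink = 4)
  res <- max_flow(net)
  expect_equal(res$max_flow_value, 0)
  expect_equal(res$source_side, 3L)  # all pixels on the sink side
})

test_that("flow equals the exhaustive minimum cut on random networks", {
  set.seed(13)
  for (rep in 1:30) {
    n <- sample(4:8, 1)
    n_edges <- sample(5:14, 1)
    from <- sample(n, n_edges, replace = TRUE)
    to <- sample(n, n_edges, replace = TRUE)
    keep <- from != to & from != n & to != n - 1  # sink no out, source no in
    from <- from[keep]; to <- to[keep]
    if (length(from) == 0) next
    cap <- sample(0:7, length(from), replace = TRUE)
    res <- max_flow(list(n_nodes = n, from = from, to = to, cap = cap,
                         source = n - 1, sink = n))
    expect_equal(res$max_flow_value,
                 oracle_min_cut(n, from, to, cap, n - 1, n))
    # max-flow/min-cut equality on the reported partition
    s_side <- res$source_side
    crossing <- sum(cap[from %in% s_side & !(to %in% s_side)])
    expect_equal(res$max_flow_value, crossing)
  }
})

test_that("refinement with lambda 0 reduces to the per-pixel argmax", {
  set.seed(14)
  img <- matrix(runif(64), 8, 8)
  probs <- array(runif(64 * 3), c(8, 8, 3))
  tot <- probs[, , 1] + probs[, , 2] + probs[, , 3]
  for (k in 1:3) probs[, , k] <- probs[, , k] / tot
  m <- graphcut_refine(img, probs, lambda_ = 0)
  expect_identical(m, obstruseg:::probs_argmax(probs))
  expect_true(all(m %in% 0:2))
  # crisp binary probabilities, lambda 0: exact argmax map
  pb <- array(0, c(8, 8, 2))
  pb[, , 2] <- matrix(rbinom(64, 1, 0.5), 8, 8)
  pb[, , 1] <- 1 - pb[, , 2]
  expect_identical(graphcut_refine(img, pb, lambda_ = 0),
                   matrix(as.integer(pb[, , 2]), 8, 8))
})

test_that("a lone flipped pixel is restored by strong smoothing", {
  img <- matrix(0.5, 9, 9)
  probs <- array(0, c(9, 9, 2))
  probs[, , 2] <- 0.9; probs[5, 5, 2] <- 0.1
  probs[, , 1] <- 1 - probs[, , 2]
  m <- graphcut_refine(img, probs, lambda_ = 5)
  expect_true(all(m == 1L))
  # and without smoothing the flip survives
  m0 <- graphcut_refine(img, probs, lambda_ = 0)
  expect_equal(m0[5, 5], 0L)
})

test_that("label boundaries never increase with lambda on the 9x9 fixture", {
  set.seed(15)
  img <- matrix(0.5, 9, 9); img[, 5:9] <- 0.9
  probs <- array(0, c(9, 9, 2))
  probs[, , 2] <- pmin(pmax(as.numeric(img > 0.7) + rnorm(81, 0, 0.25), 0.02), 0.98)
  probs[, , 1] <- 1 - probs[, , 2]
  n_bound <- function(m)
    sum(m[-1, ] != m[-nrow(m), ]) + sum(m[, -1] != m[, -ncol(m)])
  counts <- vapply(c(0, 0.5, 1, 2, 5, 10),
                   function(l) n_bound(graphcut_refine(img, probs, lambda_ = l)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("non-normalized probabilities are renormalized with a warning", {
  img <- matrix(0.5, 4, 4)
  probs <- array(0.8, c(4, 4, 2))
  expect_warning(m <- graphcut_refine(img, probs, lambda_ = 0), "renormaliz")
  expect_true(all(m %in% 0:1))
})
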