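#' @name blocks
#' @title Overlapping-block decomposition and label-map reassembly
#' @description
#' Cuts an image into overlapping square blocks at a fixed sliding stride
#' (the "overlap step"), and reassembles per-block class scores into a
#' per-pixel label map.  Block origins enumerate every stride position
#' plus, when the last stride under-shoots, a final origin flush with the
#' image edge, so every pixel is covered by at least one block.
NULL

# 0-based origins along one axis of length len for block size b, stride s.
axis_origins <- function(len, b, s) {
  pos <- seq(0L, len - b, by = s)
  if (pos[length(pos)] != len - b) pos <- c(pos, len - b)
  as.integer(pos)
}

#' Extract overlapping blocks from an image
#'
#' @param image a [gray_image()] or numeric matrix
#' @param block_size square block edge length b, pixels
#' @param overlap_step sliding stride s, pixels (`1 <= s <= b`)
#' @return a `block_grid` list: `block_size`, `overlap_step`, `origins`
#'   (n x 2 integer matrix of 0-based `(row, col)` top-left corners in
#'   row-major order), `blocks` (list of b x b matrices), `source_shape`
#' @export
#' @examples
#' g <- extract_blocks(matrix(0, 64, 64), 32, 16)
#' nrow(g$origins)  # 9
extract_blocks <- function(image, block_size, overlap_step) {
  check(is.matrix(image), "image must be a matrix")
  h <- nrow(image); w <- ncol(image)
  check(is_count(block_size), "block_size must be a positive integer")
  check(is_count(overlap_step), "overlap_step must be a positive integer")
  check(overlap_step <= block_size, "overlap_step must be <= block_size")
  check(block_size <= min(h, w), "block_size must not exceed the image")
  b <- as.integer(block_size)
  ro <- axis_origins(h, b, as.integer(overlap_step))
  co <- axis_origins(w, b, as.integer(overlap_step))
  origins <- cbind(row = rep(ro, each = length(co)), col = rep(co, length(ro)))
  blocks <- vector("list", nrow(origins))
  for (i in seq_len(nrow(origins))) {
    r <- origins[i, 1]; c <- origins[i, 2]
    blocks[[i]] <- unclass(image)[(r + 1):(r + b), (c + 1):(c + b), drop = FALSE]
  }
  structure(list(block_size = b, overlap_step = as.integer(overlap_step),
                 origins = origins, blocks = blocks, source_shape = c(h, w)),
            class = "block_grid")
}

#' Average per-block class scores into a per-pixel probability map
#'
#' Each pixel's class-score vector is the mean of the score vectors of all
#' blocks covering it (the fusion rule for overlapping predictions; a
#' majority-vote alternative is available in [reassemble_mask()]).
#'
#' @param grid a `block_grid`
#' @param block_scores n_blocks x K matrix of class scores
#' @return `height x width x K` array of averaged scores
#' @export
reassemble_probs <- function(grid, block_scores) {
  check(inherits(grid, "block_grid"), "grid must be a block_grid")
  block_scores <- as.matrix(block_scores)
  check(nrow(block_scores) == nrow(grid$origins),
        sprintf("need one score vector per block (%d blocks, %d scores)",
                nrow(grid$origins), nrow(block_scores)))
  h <- grid$source_shape[1]; w <- grid$source_shape[2]
  K <- ncol(block_scores); b <- grid$block_size
  acc <- array(0, c(h, w, K))
  cover <- matrix(0, h, w)
  for (i in seq_len(nrow(grid$origins))) {
    rr <- (grid$origins[i, 1] + 1):(grid$origins[i, 1] + b)
    cc <- (grid$origins[i, 2] + 1):(grid$origins[i, 2] + b)
    for (k in seq_len(K)) acc[rr, cc, k] <- acc[rr, cc, k] + block_scores[i, k]
    cover[rr, cc] <- cover[rr, cc] + 1
  }
  for (k in seq_len(K)) acc[, , k] <- acc[, , k] / cover
  acc
}

#' Reassemble per-block class scores into a label mask
#'
#' With `aggregate = "mean"`, each pixel's label is the argmax over classes
#' of the mean score of its covering blocks; with `"vote"`, the majority of
#' the covering blocks' argmax labels.  Ties break toward the lower class
#' index.  Labels are `0 .. K-1` in score-column order.
#'
#' @inheritParams reassemble_probs
#' @param aggregate `"mean"` or `"vote"`
#' @return integer label matrix of shape `source_shape`
#' @export
reassemble_mask <- function(grid, block_scores, aggregate = c("mean", "vote")) {
  aggregate <- match.arg(aggregate)
  block_scores <- as.matrix(block_scores)
  if (aggregate == "vote") {
    K <- ncol(block_scores)
    onehot <- matrix(0, nrow(block_scores), K)
    onehot[cbind(seq_len(nrow(block_scores)), max.col(block_scores, "first"))] <- 1
    block_scores <- onehot
  }
  probs <- reassemble_probs(grid, block_scores)
  probs_argmax(probs)
}

# argmax over the 3rd dimension, ties to the lower index; labels 0..K-1
probs_argmax <- function(probs) {
  h <- dim(probs)[1]; w <- dim(probs)[2]; K <- dim(probs)[3]
  flat <- matrix(probs, h * w, K)
  matrix(max.col(flat, "first") - 1L, h, w)
}
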