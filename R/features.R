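#' @name features
#' @title Block texture and intensity features
#' @description
#' Maps each image block to a fixed 6-dimensional feature vector -- mean,
#' variance, histogram entropy, gradient energy, co-occurrence contrast and
#' co-occurrence homogeneity -- the per-sample input of the block
#' classifier.  Entropy and co-occurrence statistics are computed on the
#' block's own intensity range, so every feature except the mean is
#' invariant to adding a constant to all intensities.
NULL

FEATURE_NAMES <- c("mean", "variance", "entropy", "gradient_energy",
                   "glcm_contrast", "glcm_homogeneity")

# Quantize a block to integer levels 0..(levels-1) over its own range;
# a constant block maps to a single level.
quantize_block <- function(block, levels) {
  rng <- range(block)
  if (rng[2] <= rng[1]) return(matrix(0L, nrow(block), ncol(block)))
  q <- floor((block - rng[1]) / (rng[2] - rng[1]) * levels)
  matrix(pmin(as.integer(q), levels - 1L), nrow(block), ncol(block))
}

# Symmetric normalized gray-level co-occurrence matrix, offset (0,1)
# (horizontal neighbor pairs within each row).
glcm <- function(qblock, levels) {
  a <- as.vector(qblock[, -ncol(qblock), drop = FALSE])
  b <- as.vector(qblock[, -1, drop = FALSE])
  cnt <- tabulate(a * levels + b + 1L, nbins = levels * levels)
  P <- matrix(cnt, levels, levels, byrow = TRUE)
  P <- P + t(P)
  P / sum(P)
}

#' Compute the 6-feature descriptor of one block
#'
#' Entropy uses a `hist_bins`-bin histogram over the block's intensity
#' range, in bits.  Gradient energy is the mean squared forward difference
#' over rows and columns.  Co-occurrence statistics use a `glcm_levels`
#' quantization with offset (0,1), symmetrized and normalized: contrast
#' `sum P (i-j)^2`, homogeneity `sum P / (1 + (i-j)^2)`.
#'
#' @param block numeric matrix with intensities in `[0,1]`
#' @param hist_bins entropy histogram bins
#' @param glcm_levels co-occurrence quantization levels
#' @return named numeric vector of length 6
#' @export
#' @examples
#' block_features(matrix(0.5, 8, 8))  # degenerate texture: all but mean zero
block_features <- function(block, hist_bins = 32L, glcm_levels = 8L) {
  check(is.matrix(block) && length(block) > 0, "block must be a non-empty matrix")
  check(all(is.finite(block)) && all(block >= 0 & block <= 1),
        "block intensities must lie in [0,1]")
  m <- mean(block)
  v <- mean((block - m)^2)  # population variance

  qh <- quantize_block(block, as.integer(hist_bins))
  p <- tabulate(as.vector(qh) + 1L, nbins = hist_bins) / length(qh)
  p <- p[p > 0]
  ent <- -sum(p * log2(p))

  ge <- 0; n_terms <- 0
  if (ncol(block) > 1) {
    dx <- block[, -1, drop = FALSE] - block[, -ncol(block), drop = FALSE]
    ge <- ge + sum(dx^2); n_terms <- n_terms + length(dx)
  }
  if (nrow(block) > 1) {
    dy <- block[-1, , drop = FALSE] - block[-nrow(block), , drop = FALSE]
    ge <- ge + sum(dy^2); n_terms <- n_terms + length(dy)
  }
  ge <- if (n_terms > 0) ge / n_terms else 0

  if (ncol(block) > 1) {
    lv <- as.integer(glcm_levels)
    P <- glcm(quantize_block(block, lv), lv)
    d2 <- outer(0:(lv - 1), 0:(lv - 1), function(i, j) (i - j)^2)
    contrast <- sum(P * d2)
    homogeneity <- sum(P / (1 + d2))
  } else {
    contrast <- 0; homogeneity <- 1
  }

  c(mean = m, variance = v, entropy = ent, gradient_energy = ge,
    glcm_contrast = contrast, glcm_homogeneity = homogeneity)
}

#' Feature matrix for every block in a grid
#'
#' @param grid a `block_grid` from [extract_blocks()]
#' @inheritParams block_features
#' @return n_blocks x 6 matrix, row order matching `grid$origins`
#' @export
grid_features <- function(grid, hist_bins = 32L, glcm_levels = 8L) {
  check(inherits(grid, "block_grid"), "grid must be a block_grid")
  t(vapply(grid$blocks, block_features, numeric(6),
           hist_bins = hist_bins, glcm_levels = glcm_levels))
}

#' Fit / apply a per-dimension z-score scaler
#'
#' Dimensions with zero spread pass through unchanged (scale 1).
#'
#' @param samples numeric matrix, one row per feature vector (>= 2 rows)
#' @return a `feature_scaler` with `center` and `scale` vectors
#' @export
fit_scaler <- function(samples) {
  samples <- as.matrix(samples)
  check(nrow(samples) >= 2, "need at least 2 samples to fit a scaler")
  center <- colMeans(samples)
  # population sd, so a two-point sample {a, b} scales to exactly {-1, +1}
  scale <- sqrt(colMeans(sweep(samples, 2, center)^2))
  scale[!is.finite(scale) | scale <= 0] <- 1
  structure(list(center = center, scale = scale), class = "feature_scaler")
}

#' @rdname fit_scaler
#' @param scaler a `feature_scaler`
#' @param v feature vector or matrix of rows to transform
#' @export
apply_scaler <- function(scaler, v) {
  check(inherits(scaler, "feature_scaler"), "scaler must come from fit_scaler()")
  if (is.matrix(v)) {
    check(ncol(v) == length(scaler$center), "dimension mismatch")
    sweep(sweep(v, 2, scaler$center), 2, scaler$scale, "/")
  } else {
    check(length(v) == length(scaler$center), "dimension mismatch")
    (v - scaler$center) / scaler$scale
  }
}

#' Export a labeled block feature table as CSV
#'
#' @param grid a `block_grid`
#' @param features n_blocks x 6 feature matrix
#' @param labels optional per-block labels
#' @param path CSV output path
#' @export
write_feature_csv <- function(grid, features, labels = NULL, path) {
  df <- data.frame(origin_row = grid$origins[, 1], origin_col = grid$origins[, 2])
  df <- cbind(df, as.data.frame(features))
  if (!is.null(labels)) df$label <- labels
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
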