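#' @name baselines
#' @title Threshold and edge-detection baseline segmenters
#' @description
#' The two classical comparison segmenters: global thresholding (Otsu's
#' between-class-variance criterion over a 256-bin histogram, or a fixed
#' threshold) and gradient edge detection with hysteresis linking plus
#' optional interior filling.  Both are deterministic.
NULL

#' Otsu's threshold on a 256-bin histogram
#'
#' Returns the threshold value maximizing the between-class variance
#' `w0 w1 (mu0 - mu1)^2`; ties take the lowest candidate.
#'
#' @param image numeric matrix with intensities in `[0,1]`
#' @param bins histogram resolution
#' @return threshold in `(0, 1)`, or `NA` for a constant image
#' @export
otsu_threshold <- function(image, bins = 256L) {
  v <- as.vector(image)
  if (max(v) <= min(v)) return(NA_real_)
  breaks <- seq(0, 1, length.out = bins + 1)
  cnt <- tabulate(pmin(floor(v * bins), bins - 1) + 1L, nbins = bins)
  p <- cnt / sum(cnt)
  mids <- (breaks[-1] + breaks[-(bins + 1)]) / 2
  w0 <- cumsum(p)
  mu_cum <- cumsum(p * mids)
  mu_tot <- mu_cum[bins]
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sigma_b2 <- rep(-Inf, bins)
  sigma_b2[valid] <- (mu_tot * w0[valid] - mu_cum[valid])^2 / (w0[valid] * w1[valid])
  k <- which.max(sigma_b2)      # classes: bins <= k vs > k
  breaks[k + 1]                 # upper edge of the optimal bin
}

#' Threshold segmentation baseline
#'
#' @param image numeric matrix in `[0,1]`
#' @param method `"otsu"` or `"fixed"`
#' @param fixed_t threshold in `(0,1)` when `method = "fixed"`
#' @return binary integer mask (`image >= t` -> 1).  A constant image under
#'   Otsu yields an all-zero mask with a warning.
#' @export
threshold_segment <- function(image, method = c("otsu", "fixed"), fixed_t = NULL) {
  method <- match.arg(method)
  check(is.matrix(image) && all(image >= 0 & image <= 1),
        "image must be a matrix with intensities in [0,1]")
  if (method == "fixed") {
    check(!is.null(fixed_t) && fixed_t > 0 && fixed_t < 1,
          "fixed_t must lie in (0,1)")
    t <- fixed_t
  } else {
    t <- otsu_threshold(image)
    if (is.na(t)) {
      warning("constant image: Otsu threshold undefined, returning all-zero mask")
      return(matrix(0L, nrow(image), ncol(image)))
    }
  }
  matrix(as.integer(image >= t), nrow(image), ncol(image))
}

# grow a logical seed mask inside a logical support by 4-neighbor
# propagation until a fixed point (vectorized flood fill)
propagate <- function(seed, support) {
  repeat {
    h <- nrow(seed); w <- ncol(seed)
    grown <- seed |
      rbind(FALSE, seed[-h, , drop = FALSE]) |
      rbind(seed[-1, , drop = FALSE], FALSE) |
      cbind(FALSE, seed[, -w, drop = FALSE]) |
      cbind(seed[, -1, drop = FALSE], FALSE)
    grown <- grown & support
    if (identical(grown, seed)) return(seed)
    seed <- grown
  }
}

# non-maximum suppression: keep a pixel only when its gradient magnitude
# is maximal along the (4-sector quantized) gradient direction; ties break
# toward the forward neighbor so a two-pixel step ridge thins to one pixel
nms_thin <- function(g, gx, gy) {
  h <- nrow(g); w <- ncol(g)
  shift <- function(m, dr, dc) {
    out <- matrix(0, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  ang <- atan2(gy, gx) %% pi
  sector <- ifelse(ang < pi / 8 | ang >= 7 * pi / 8, 0L,
                   ifelse(ang < 3 * pi / 8, 1L, ifelse(ang < 5 * pi / 8, 2L, 3L)))
  fwd_d <- list(`0` = c(0, 1), `1` = c(1, 1), `2` = c(1, 0), `3` = c(1, -1))
  keep <- matrix(FALSE, h, w)
  for (s in 0:3) {
    d <- fwd_d[[as.character(s)]]
    fwd <- shift(g, -d[1], -d[2])   # value of the forward neighbor
    back <- shift(g, d[1], d[2])
    keep <- keep | (sector == s & g > fwd & g >= back)
  }
  keep
}

#' Edge-detection segmentation baseline
#'
#' Sobel gradient magnitude, non-maximum suppression along the gradient
#' direction (thins step responses to one pixel), double-threshold
#' hysteresis (thresholds are fractions of the maximum gradient
#' magnitude: strong edges at `>= high`, weak edges at `>= low` kept only
#' when 4-connected to a strong edge), and optional filling of regions
#' enclosed by edges.
#'
#' @param image numeric matrix in `[0,1]`
#' @param low,high hysteresis thresholds, `0 <= low < high <= 1`
#' @param fill if `TRUE`, interior pixels of closed contours are labeled 1
#' @return binary integer mask (edges, plus interiors when `fill`)
#' @export
edge_segment <- function(image, low = 0.1, high = 0.3, fill = TRUE) {
  check(is.matrix(image), "image must be a matrix")
  check(low >= 0 && low < high && high <= 1, "need 0 <= low < high <= 1")
  img <- unclass(image)
  h <- nrow(img); w <- ncol(img)
  pad <- rbind(img[1, , drop = FALSE], img, img[h, , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, w, drop = FALSE])
  sh <- function(dr, dc) pad[(2 + dr):(h + 1 + dr), (2 + dc):(w + 1 + dc)]
  gx <- (sh(-1, 1) + 2 * sh(0, 1) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(0, -1) + sh(1, -1))
  gy <- (sh(1, -1) + 2 * sh(1, 0) + sh(1, 1)) -
        (sh(-1, -1) + 2 * sh(-1, 0) + sh(-1, 1))
  g <- sqrt(gx^2 + gy^2)
  gmax <- max(g)
  if (gmax <= 0) return(matrix(0L, nrow(image), ncol(image)))
  g <- g / gmax
  thin <- nms_thin(g, gx, gy)
  strong <- thin & g >= high
  weak <- thin & g >= low
  edges <- propagate(strong, weak)
  if (!fill) return(matrix(as.integer(edges), nrow(image), ncol(image)))
  # outside = non-edge pixels reachable from the border; interior = the rest
  border <- matrix(FALSE, nrow(image), ncol(image))
  border[1, ] <- TRUE; border[nrow(image), ] <- TRUE
  border[, 1] <- TRUE; border[, ncol(image)] <- TRUE
  outside <- propagate(border & !edges, !edges)
  matrix(as.integer(edges | !outside), nrow(image), ncol(image))
}
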