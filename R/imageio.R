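#' @name imageio
#' @title Grayscale image and label-mask I/O
#' @description
#' Reads 2-D grayscale PNG images and single-slice NIfTI-1 volumes into
#' plain numeric matrices with intensities min--max normalized to `[0,1]`,
#' and writes images and integer label masks back out.  A constant image
#' normalizes to all zeros (documented edge case: with `max == min` there
#' is no contrast to preserve).
NULL

#' Construct a grayscale image from a matrix
#'
#' @param pixels numeric matrix
#' @param normalize if `TRUE`, min--max rescale to `[0,1]`
#' @return numeric matrix of class `gray_image`
#' @export
gray_image <- function(pixels, normalize = FALSE) {
  check(is.matrix(pixels) && nrow(pixels) >= 1 && ncol(pixels) >= 1,
        "pixels must be a non-empty matrix")
  check(all(is.finite(pixels)), "pixel intensities must be finite")
  if (normalize) {
    rng <- range(pixels)
    pixels <- if (rng[2] > rng[1]) (pixels - rng[1]) / (rng[2] - rng[1])
              else matrix(0, nrow(pixels), ncol(pixels))
  }
  check(all(pixels >= 0 & pixels <= 1), "intensities must lie in [0,1]")
  structure(pixels, class = c("gray_image", "matrix", "array"))
}

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)

#' Load a grayscale image
#'
#' Supports 8/16-bit grayscale PNG and single-slice NIfTI-1 (`.nii`,
#' `.nii.gz`).  Intensities are min--max normalized to `[0,1]`.
#'
#' @param path file path
#' @param slice for a 3-D NIfTI volume, which slice to take; a volume with
#'   more than one slice and no `slice` argument is an error
#' @return a [gray_image()]
#' @export
load_image <- function(path, slice = NULL) {
  check(file.exists(path), sprintf("file not found: %s", path))
  if (is_nifti_path(path)) {
    vol <- read_nifti(path)
    d <- dim(vol)
    if (length(d) == 3) {
      if (d[3] == 1) vol <- vol[, , 1]
      else if (!is.null(slice)) {
        check(is_count(slice) && slice <= d[3],
              sprintf("slice must be in 1..%d", d[3]))
        vol <- vol[, , slice]
      } else abort_validation(sprintf(
        "NIfTI volume has %d slices; pass slice = <k> to pick one", d[3]))
    }
    check(length(dim(vol)) == 2, "only 2-D (single-slice) NIfTI input is supported")
    return(gray_image(vol, normalize = TRUE))
  }
  if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    abort_validation("TIFF input is not supported by this build; convert to PNG or NIfTI")
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) {
    if (dim(px)[3] == 1) px <- px[, , 1]
    else abort_validation("multi-channel color PNG input is unsupported; provide grayscale")
  }
  gray_image(px, normalize = TRUE)
}

#' Save a grayscale image as PNG or NIfTI
#'
#' PNG output is 8-bit; use `.nii`/`.nii.gz` output for full float
#' precision.
#'
#' @param image a [gray_image()] or numeric matrix in `[0,1]`
#' @param path output path (`.png`, `.nii` or `.nii.gz`)
#' @export
save_image <- function(image, path) {
  check(is.matrix(image) && all(image >= 0 & image <= 1),
        "image must be a matrix with intensities in [0,1]")
  if (is_nifti_path(path)) write_nifti(unclass(image), path)
  else png::writePNG(unclass(image), path)
  invisible(path)
}

#' Save / load an integer label mask as an 8-bit PNG
#'
#' Labels are stored directly as gray levels, so masks with labels up to
#' 255 round-trip exactly.
#'
#' @param mask integer matrix of labels in `0..255`
#' @param path PNG path
#' @export
save_mask <- function(mask, path) {
  check(is.matrix(mask) && all(mask >= 0 & mask <= 255 & mask == round(mask)),
        "mask must be an integer matrix with labels in 0..255")
  png::writePNG(unclass(mask) / 255, path)
  invisible(path)
}

#' @rdname save_mask
#' @return `load_mask` returns an integer matrix
#' @export
load_mask <- function(path) {
  check(file.exists(path), sprintf("file not found: %s", path))
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) px <- px[, , 1]
  matrix(as.integer(round(px * 255)), nrow(px), ncol(px))
}

# --- minimal NIfTI-1 single-file support ------------------------------------
# Only what a single-slice grayscale carrier needs: dim, datatype, bitpix,
# vox_offset, scl_slope/inter.  Gzipped files are handled via gzfile().

nifti_dtypes <- list(`2` = list(what = "integer", size = 1, signed = FALSE),
                     `4` = list(what = "integer", size = 2, signed = TRUE),
                     `8` = list(what = "integer", size = 4, signed = TRUE),
                     `16` = list(what = "double", size = 4, signed = TRUE),
                     `64` = list(what = "double", size = 8, signed = TRUE),
                     `512` = list(what = "integer", size = 2, signed = FALSE))

read_nifti <- function(path) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 348)
  rd <- function(off, what, n, size, endian, signed = TRUE)
    readBin(hdr[(off + 1):length(hdr)], what, n = n, size = size,
            endian = endian, signed = signed)
  endian <- "little"
  if (rd(0, "integer", 1, 4, "little") != 348L) {
    check(rd(0, "integer", 1, 4, "big") == 348L, "not a NIfTI-1 file (bad sizeof_hdr)")
    endian <- "big"
  }
  magic <- rawToChar(hdr[345:347])
  check(magic %in% c("n+1", "ni1"), "not a NIfTI-1 file (bad magic)")
  dims <- rd(40, "integer", 8, 2, endian)
  ndim <- dims[1]
  check(ndim >= 2, "NIfTI volume must be at least 2-D")
  shape <- dims[2:(ndim + 1)]
  shape <- shape[shape > 1 | seq_along(shape) <= 2]
  datatype <- rd(70, "integer", 1, 2, endian)
  dt <- nifti_dtypes[[as.character(datatype)]]
  check(!is.null(dt), sprintf("unsupported NIfTI datatype code %d", datatype))
  vox_offset <- rd(108, "double", 1, 4, endian)
  scl_slope <- rd(112, "double", 1, 4, endian)
  scl_inter <- rd(116, "double", 1, 4, endian)
  n <- prod(shape)
  skip <- max(vox_offset, 348) - 348
  if (skip > 0) readBin(con, "raw", skip)
  vals <- readBin(con, dt$what, n = n, size = dt$size, endian = endian,
                  signed = if (dt$size >= 4) TRUE else dt$signed)
  if (scl_slope != 0 && !(scl_slope == 1 && scl_inter == 0))
    vals <- vals * scl_slope + scl_inter
  array(as.numeric(vals), dim = shape)
}

write_nifti <- function(data, path) {
  check(is.numeric(data) && length(dim(data) %||% dim(as.matrix(data))) >= 2,
        "data must be a matrix or array")
  if (is.null(dim(data))) data <- as.matrix(data)
  shape <- dim(data)
  ndim <- length(shape)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  dims <- integer(8)
  dims[1] <- ndim
  dims[2:(ndim + 1)] <- shape
  dims[(ndim + 2):8][dims[(ndim + 2):8] == 0] <- 1L
  hdr <- raw(348)
  put <- function(off, x, size, what = "integer") {
    b <- writeBin(if (what == "integer") as.integer(x) else as.numeric(x),
                  raw(), size = size, endian = "little")
    hdr[(off + 1):(off + length(b))] <<- b
  }
  put(0, 348L, 4)                      # sizeof_hdr
  put(40, dims, 2)                     # dim
  put(70, 16L, 2)                      # datatype: float32
  put(72, 32L, 2)                      # bitpix
  put(76, c(as.numeric(ndim), rep(1, 7)), 4, "double")  # pixdim
  put(108, 352, 4, "double")           # vox_offset
  put(112, 1, 4, "double")             # scl_slope
  put(116, 0, 4, "double")             # scl_inter
  hdr[345:348] <- as.raw(c(utf8ToInt("n"), utf8ToInt("+"), utf8ToInt("1"), 0))
  writeBin(hdr, con)
  writeBin(raw(4), con)                # extension flag
  writeBin(as.numeric(data), con, size = 4, endian = "little")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
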