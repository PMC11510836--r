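#' Grayscale image utilities
#'
#' A grayscale image is represented throughout the package as a plain
#' numeric matrix of integer-valued intensities in `{0, ..., 255}`
#' (`L = 256` levels), with rows indexing image height and columns width.
#' These helpers validate, read, write, convert and resize such matrices.
#'
#' @name gray_image
NULL

GRAY_LEVELS <- 256L

#' Validate a grayscale image matrix
#'
#' @param image Numeric matrix of intensities in `[0, 255]`.
#' @param arg Name used in error messages.
#' @return The validated matrix (invisibly unchanged).
#' @export
validate_gray_image <- function(image, arg = "image") {
  if (!is.matrix(image) || !is.numeric(image)) {
    stop(sprintf("`%s` must be a numeric matrix", arg), call. = FALSE)
  }
  if (nrow(image) < 1L || ncol(image) < 1L) {
    stop(sprintf("`%s` must have at least one row and one column", arg),
         call. = FALSE)
  }
  if (anyNA(image)) {
    stop(sprintf("`%s` contains missing values", arg), call. = FALSE)
  }
  rng <- range(image)
  if (rng[1] < 0 || rng[2] > GRAY_LEVELS - 1L) {
    stop(sprintf("`%s` has intensities outside [0, %d]", arg, GRAY_LEVELS - 1L),
         call. = FALSE)
  }
  invisible(image)
}

# round-half-up, the documented rounding rule for intensity reconstruction
# (base round() rounds half to even)
round_half_up <- function(x) floor(x + 0.5)

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Read a grayscale image from PNG or JPEG
#'
#' PNG files are read with \pkg{png}. JPEG files require the optional
#' \pkg{EBImage} package. Color images are converted to luminance
#' (Rec. 601 weights 0.299/0.587/0.114) with a warning; an alpha channel,
#' if present, is dropped.
#'
#' @param path Path to a `.png`, `.jpg` or `.jpeg` file.
#' @return An intensity matrix in `[0, 255]`.
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    arr <- png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG input requires the EBImage package; convert to PNG instead",
           call. = FALSE)
    }
    img <- EBImage::readImage(path)
    arr <- EBImage::imageData(img) # EBImage stores x (width) first
    arr <- if (length(dim(arr)) == 3L) aperm(arr, c(2L, 1L, 3L)) else t(arr)
  } else {
    stop("unsupported image format: .", ext, call. = FALSE)
  }
  if (length(dim(arr)) == 3L) {
    if (dim(arr)[3] >= 3L) {
      warning("color image converted to luminance: ", path, call. = FALSE)
      arr <- 0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]
    } else {
      arr <- arr[, , 1]
    }
  }
  out <- round_half_up(arr * (GRAY_LEVELS - 1L))
  validate_gray_image(out, "decoded image")
  out
}

#' Write a grayscale image to PNG
#'
#' @param image Intensity matrix in `[0, 255]`.
#' @param path Output `.png` path; parent directories are created.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(image, path) {
  validate_gray_image(image)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(image / (GRAY_LEVELS - 1L), target = path)
  invisible(path)
}

#' Bilinear resize of a grayscale image
#'
#' Resamples on the pixel-center grid (the convention used by most image
#' libraries): output pixel centers are placed uniformly over the source
#' extent and interpolated bilinearly from the four surrounding source
#' pixels. Returns integer intensities (round half up).
#'
#' @param image Intensity matrix in `[0, 255]`.
#' @param height,width Target dimensions (positive integers).
#' @return The resized intensity matrix.
#' @export
resize_gray_image <- function(image, height, width) {
  validate_gray_image(image)
  stopifnot(height >= 1L, width >= 1L)
  M <- nrow(image); N <- ncol(image)
  if (height == M && width == N) return(image)
  # source coordinates of target pixel centers
  sy <- (seq_len(height) - 0.5) * M / height + 0.5
  sx <- (seq_len(width) - 0.5) * N / width + 0.5
  y0 <- clamp(floor(sy), 1, M); y1 <- clamp(y0 + 1, 1, M)
  x0 <- clamp(floor(sx), 1, N); x1 <- clamp(x0 + 1, 1, N)
  wy <- clamp(sy - y0, 0, 1); wx <- clamp(sx - x0, 0, 1)
  top <- image[y0, x0, drop = FALSE] * outer(1 - wy, 1 - wx) +
    image[y0, x1, drop = FALSE] * outer(1 - wy, wx)
  bot <- image[y1, x0, drop = FALSE] * outer(wy, 1 - wx) +
    image[y1, x1, drop = FALSE] * outer(wy, wx)
  clamp(round_half_up(top + bot), 0, GRAY_LEVELS - 1L)
}
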