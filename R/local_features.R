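#' Sliding-window specification
#'
#' Odd-sized rectangular neighbourhood `W` centred on each pixel. Borders
#' are handled by symmetric reflection (edge row/column included), so
#' every window is full-size and feature maps keep the image dimensions.
#'
#' @param height,width Odd positive integers (default 3).
#' @return An object of class `window_spec`.
#' @export
window_spec <- function(height = 3L, width = 3L) {
  height <- as.integer(height); width <- as.integer(width)
  if (is.na(height) || is.na(width) || height < 1L || width < 1L ||
      height %% 2L == 0L || width %% 2L == 0L) {
    stop("window height and width must be odd positive integers", call. = FALSE)
  }
  structure(list(height = height, width = width), class = "window_spec")
}

# symmetric reflection of out-of-range indices onto 1..n (edge included):
# ..., 2, 1 | 1, 2, ..., n | n, n-1, ...
reflect_index <- function(i, n) {
  j <- ((i - 1L) %% (2L * n) + 2L * n) %% (2L * n) # 0 .. 2n-1
  ifelse(j < n, j + 1L, 2L * n - j)
}

# list of n*m shifted copies of `mat`, one per window offset, each the
# size of the image; element [k][x, y] is the k-th window member at (x, y)
window_stack <- function(mat, win) {
  rh <- (win$height - 1L) %/% 2L
  rw <- (win$width - 1L) %/% 2L
  M <- nrow(mat); N <- ncol(mat)
  pad <- mat[reflect_index((1L - rh):(M + rh), M),
             reflect_index((1L - rw):(N + rw), N), drop = FALSE]
  out <- vector("list", win$height * win$width)
  k <- 0L
  for (dx in -rw:rw) {
    for (dy in -rh:rh) {
      k <- k + 1L
      out[[k]] <- pad[(1L + rh + dy):(M + rh + dy),
                      (1L + rw + dx):(N + rw + dx), drop = FALSE]
    }
  }
  out
}

# per-layer occurrence counts: counts[[k]][x,y] = how many window members
# at (x,y) share the intensity of member k (the window histogram value of
# that member's gray level)
window_counts <- function(stack) {
  lapply(stack, function(layer) {
    Reduce(`+`, lapply(stack, function(other) (other == layer) * 1))
  })
}

check_feature_inputs <- function(image, win, mu = NULL) {
  validate_gray_image(image)
  if (!inherits(win, "window_spec")) stop("`win` must be a window_spec", call. = FALSE)
  if (!is.null(mu)) {
    if (!is.matrix(mu) || !identical(dim(mu), dim(image)) ||
        anyNA(mu) || min(mu) < 0 || max(mu) > 1) {
      stop("`mu` must be a membership matrix aligned with `image`", call. = FALSE)
    }
  }
  invisible(NULL)
}

#' Local contrast map
#'
#' Per pixel, the normalized intensity range of the window:
#' `C(x, y) = (C_max - C_min) / 255`, where `C_max`/`C_min` are the
#' maximum and minimum brightness in the neighbourhood. Values lie in
#' `[0, 1]`; homogeneous windows give 0.
#'
#' @param image Intensity matrix in `[0, 255]`.
#' @param win A [window_spec()].
#' @return Matrix of local contrast values in `[0, 1]`.
#' @export
local_contrast_map <- function(image, win = window_spec()) {
  check_feature_inputs(image, win)
  st <- window_stack(image, win)
  (Reduce(pmax, st) - Reduce(pmin, st)) / (GRAY_LEVELS - 1L)
}

#' Membership-weighted (global) contrast map
#'
#' Per pixel, twice the membership-weighted root-mean-square deviation of
#' the window's intensities from the window mean, normalized by 255:
#' `2 * sqrt(sum_j (f_j - M)^2 mu_j / sum_j mu_j) / 255`, with `M` the
#' window's arithmetic mean brightness. Windows whose memberships sum to
#' zero map to 0 by convention.
#'
#' @param image Intensity matrix in `[0, 255]`.
#' @param mu Membership matrix aligned with `image`.
#' @param win A [window_spec()].
#' @return Matrix of contrast values in `[0, 1]` (clamped).
#' @export
global_contrast_map <- function(image, mu, win = window_spec()) {
  check_feature_inputs(image, win, mu)
  w <- weighted_window_dispersion(image, mu, win)
  out <- 2 * sqrt(w$ratio) / (GRAY_LEVELS - 1L)
  clamp(out, 0, 1)
}

# shared core of the weighted second-moment features: returns
# ratio = sum_j (f_j - M)^2 mu_j / sum_j mu_j (0 where sum mu_j = 0)
weighted_window_dispersion <- function(image, mu, win) {
  fst <- window_stack(image, win)
  mst <- window_stack(mu, win)
  m_loc <- Reduce(`+`, fst) / length(fst)
  wss <- Reduce(`+`, Map(function(f, m) (f - m_loc)^2 * m, fst, mst))
  musum <- Reduce(`+`, mst)
  ratio <- wss / musum
  ratio[musum == 0] <- 0
  list(ratio = ratio, local_mean = m_loc)
}

#' Histogram spread map
#'
#' Per pixel, the window's intensity range divided by the maximum bin
#' count of the window's 256-level intensity histogram:
#' `h_F(x, y) = (f_max - f_min) / h_max`. Minimal (0) in homogeneous
#' windows, maximal in binary windows where the two extreme levels split
#' the histogram.
#'
#' @param image Intensity matrix in `[0, 255]`.
#' @param win A [window_spec()].
#' @return Matrix of nonnegative spread values.
#' @export
histogram_spread_map <- function(image, win = window_spec()) {
  check_feature_inputs(image, win)
  st <- window_stack(image, win)
  spread <- Reduce(pmax, st) - Reduce(pmin, st)
  hmax <- Reduce(pmax, window_counts(st))
  spread / hmax
}

#' Fuzzy entropy map
#'
#' Shannon-type entropy of the per-pixel window memberships
#' `mu(f_i) = (count of f_i in the window) / (n m)`:
#' `eps = -a * sum_i [mu_i ln mu_i + (1 - mu_i) ln(1 - mu_i)] / ln(n m)`,
#' summed over the window's `n m` pixels with the convention
#' `0 ln 0 = 0`. Natural logarithms are used for both the terms and the
#' normalizer. Constant windows give 0.
#'
#' @param image Intensity matrix in `[0, 255]`.
#' @param win A [window_spec()] with `n * m >= 2` (a 1x1 window has an
#'   undefined normalizer and is rejected).
#' @param a_coeff Positive scale coefficient `a` (default 1).
#' @return Matrix of nonnegative entropy values.
#' @export
fuzzy_entropy_map <- function(image, win = window_spec(), a_coeff = 1) {
  check_feature_inputs(image, win)
  nm <- win$height * win$width
  if (nm < 2L) stop("fuzzy entropy needs a window of at least 2 pixels", call. = FALSE)
  st <- window_stack(image, win)
  entropy_from_counts(window_counts(st), nm, a_coeff)
}

# x * log(x) with 0 log 0 := 0, elementwise
xlogx <- function(x) {
  out <- x * log(x)
  out[x == 0] <- 0
  out
}

entropy_from_counts <- function(counts, nm, a_coeff) {
  term <- Reduce(`+`, lapply(counts, function(cnt) {
    p <- cnt / nm
    xlogx(p) + xlogx(1 - p)
  }))
  -a_coeff * term / log(nm)
}

#' Fuzzy standard deviation map
#'
#' Per pixel, the membership-weighted dispersion of window intensities
#' around the window's arithmetic mean brightness `M`:
#' `sigma = sqrt( (1 / (n m)) * sum_j (f_j - M)^2 mu_j / sum_j mu_j )`.
#' Zero in homogeneous neighbourhoods and growing with heterogeneity;
#' windows whose memberships sum to zero map to 0 by convention.
#'
#' @param image Intensity matrix in `[0, 255]`.
#' @param mu Membership matrix aligned with `image`.
#' @param win A [window_spec()].
#' @return Matrix of nonnegative dispersion values (intensity units).
#' @export
fuzzy_std_map <- function(image, mu, win = window_spec()) {
  check_feature_inputs(image, win, mu)
  w <- weighted_window_dispersion(image, mu, win)
  sqrt(w$ratio / (win$height * win$width))
}
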