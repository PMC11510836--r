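#' Fuzzifier configuration
#'
#' Parameters of the pixel-wise membership function. Each cluster center
#' `c_i` lives on the normalized intensity scale `[0, 1]`; `sigma_f`
#' controls the width of the Cauchy-type membership bell
#' `mu = 1 / (1 + ((u - c_i) / sigma_f)^2)`. With more than one center the
#' per-center memberships are aggregated by the fuzzy union (pointwise
#' maximum).
#'
#' @param centers Numeric vector of cluster centers in `[0, 1]`
#'   (default a single center at 0.5, i.e. mid-gray).
#' @param sigma_f Positive spread parameter (default 0.25).
#' @return An object of class `fuzzifier_config`.
#' @export
fuzzifier_config <- function(centers = 0.5, sigma_f = 0.25) {
  if (length(centers) < 1L || anyNA(centers) ||
      any(centers < 0) || any(centers > 1)) {
    stop("`centers` must be one or more values in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(sigma_f) || length(sigma_f) != 1L || sigma_f <= 0) {
    stop("`sigma_f` must be a single positive number", call. = FALSE)
  }
  structure(list(centers = as.numeric(centers), sigma_f = as.numeric(sigma_f)),
            class = "fuzzifier_config")
}

#' Min-max normalization of a grayscale image
#'
#' Maps intensities to `u = (f - f_min) / (f_max - f_min)` in `[0, 1]`.
#' A constant image (where `f_max = f_min`) maps to all zeros by
#' convention, so degenerate inputs flow through the pipeline unchanged.
#'
#' @param image Intensity matrix in `[0, 255]`.
#' @return A list of class `normalized_image` with elements `values`
#'   (matrix in `[0, 1]`), `source_min` and `source_max`.
#' @export
normalize_image <- function(image) {
  validate_gray_image(image)
  f_min <- min(image)
  f_max <- max(image)
  values <- if (f_max > f_min) (image - f_min) / (f_max - f_min)
            else array(0, dim(image))
  structure(list(values = values, source_min = f_min, source_max = f_max),
            class = "normalized_image")
}

#' Fuzzification: normalized intensities to membership degrees
#'
#' Applies the Cauchy-type membership function
#' `mu_i = 1 / (1 + ((u - c_i) / sigma_f)^2)` per center and aggregates
#' across centers by the pointwise maximum. Output lies in `(0, 1]` and is
#' maximal (exactly 1) where `u` equals a center.
#'
#' @param u A `normalized_image` or a numeric matrix with values in `[0, 1]`.
#' @param cfg A [fuzzifier_config()].
#' @return Membership matrix in `(0, 1]`.
#' @export
fuzzify <- function(u, cfg = fuzzifier_config()) {
  if (inherits(u, "normalized_image")) u <- u$values
  if (!is.matrix(u) || anyNA(u) || min(u) < 0 || max(u) > 1) {
    stop("`u` must be a matrix of values in [0, 1]", call. = FALSE)
  }
  if (!inherits(cfg, "fuzzifier_config")) {
    stop("`cfg` must be a fuzzifier_config", call. = FALSE)
  }
  mu <- array(0, dim(u))
  for (ci in cfg$centers) {
    mu <- pmax(mu, 1 / (1 + ((u - ci) / cfg$sigma_f)^2))
  }
  mu
}

#' Membership intensification (INT operator)
#'
#' The classical contrast intensification of a fuzzy set:
#' `mu' = 2 mu^2` for `mu <= 1/2` and `mu' = 1 - 2 (1 - mu)^2` otherwise.
#' Memberships below one half are pushed toward 0 and those above toward
#' 1; the fixed points are exactly `{0, 1/2, 1}` and the map is monotone
#' nondecreasing.
#'
#' @param mu Membership matrix (values in `[0, 1]`).
#' @return Refined membership matrix in `[0, 1]`.
#' @export
refine_membership <- function(mu) {
  if (!is.numeric(mu) || anyNA(mu) || min(mu) < 0 || max(mu) > 1) {
    stop("`mu` must be numeric with values in [0, 1]", call. = FALSE)
  }
  ifelse(mu <= 0.5, 2 * mu^2, 1 - 2 * (1 - mu)^2)
}

#' Defuzzification: membership degrees back to gray levels
#'
#' Linearly rescales memberships onto the original intensity range and
#' rounds half up: `f' = round(source_min + mu * (source_max - source_min))`.
#'
#' @param mu Membership matrix in `[0, 1]`.
#' @param source_min,source_max Intensity bounds of the target range,
#'   `0 <= source_min <= source_max <= 255`.
#' @return Intensity matrix in `[source_min, source_max]`.
#' @export
defuzzify <- function(mu, source_min = 0, source_max = 255) {
  if (!is.numeric(mu) || anyNA(mu) || min(mu) < 0 || max(mu) > 1) {
    stop("`mu` must be numeric with values in [0, 1]", call. = FALSE)
  }
  if (source_min > source_max) {
    stop("`source_min` must not exceed `source_max`", call. = FALSE)
  }
  out <- round_half_up(source_min + mu * (source_max - source_min))
  clamp(out, 0, GRAY_LEVELS - 1L)
}
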