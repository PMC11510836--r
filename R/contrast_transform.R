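#' Enhancement-exponent configuration
#'
#' Bounds and shape parameters for the per-pixel enhancement exponent
#' `alpha`, the exponent (`alpha < 1`) of the nonlinear local-contrast
#' stretch. All three feature-to-alpha maps clamp their output to
#' `[alpha_min, alpha_max]`.
#'
#' @param alpha_min,alpha_max Exponent bounds with
#'   `0 < alpha_min <= alpha_max <= 1` (defaults 0.4 and 0.9).
#' @param s Positive shape exponent (default 1).
#' @param hist_center Center `a` of the histogram-spread bell: the spread
#'   value at which `alpha` attains `alpha_max` (default 0).
#' @param hist_scale Positive width of the bell (default `pi`, matching a
#'   `2 pi^2` Gaussian denominator).
#' @return An object of class `alpha_config`.
#' @export
alpha_config <- function(alpha_min = 0.4, alpha_max = 0.9, s = 1,
                         hist_center = 0, hist_scale = pi) {
  if (!(alpha_min > 0 && alpha_min <= alpha_max && alpha_max <= 1)) {
    stop("need 0 < alpha_min <= alpha_max <= 1", call. = FALSE)
  }
  if (s <= 0) stop("`s` must be positive", call. = FALSE)
  if (hist_scale <= 0) stop("`hist_scale` must be positive", call. = FALSE)
  structure(list(alpha_min = alpha_min, alpha_max = alpha_max, s = s,
                 hist_center = hist_center, hist_scale = hist_scale),
            class = "alpha_config")
}

#' Contrast-transform configuration
#'
#' Constants of the nonlinear local-contrast transform: `R` is the
#' highest feasible local contrast (1 for contrast on the `[0, 1]`
#' scale), `A0`/`B0` are constant bias coefficients, and `c_hat_mode`
#' selects how the pivot `C_hat` (the approximation of the expected local
#' contrast) is computed from the local-contrast map.
#'
#' @param R Maximum contrast (default 1).
#' @param A0 Bias with `0 <= A0 < R/2` (default 0).
#' @param B0 Nonnegative bias on the lower branch (default 0; the
#'   transform is continuous at the pivot only when `B0 = 0`).
#' @param c_hat_mode `"mean"` (default) or `"median"`.
#' @return An object of class `contrast_transform_config`.
#' @export
contrast_transform_config <- function(R = 1, A0 = 0, B0 = 0,
                                      c_hat_mode = c("mean", "median")) {
  c_hat_mode <- match.arg(c_hat_mode)
  if (R <= 0) stop("`R` must be positive", call. = FALSE)
  if (A0 < 0 || A0 >= R / 2) stop("need 0 <= A0 < R/2", call. = FALSE)
  if (B0 < 0) stop("`B0` must be nonnegative", call. = FALSE)
  structure(list(R = R, A0 = A0, B0 = B0, c_hat_mode = c_hat_mode),
            class = "contrast_transform_config")
}

clamp_alpha <- function(alpha, cfg) clamp(alpha, cfg$alpha_min, cfg$alpha_max)

#' Enhancement exponent from histogram spread
#'
#' Peak-shaped map attaining `alpha_max` where the histogram spread
#' equals `hist_center` and decaying toward `alpha_min` away from it:
#' `alpha = alpha_max - (alpha_max - alpha_min) *
#' (1 - exp(-(h_F - a)^2 / (2 scale^2)))^s`.
#'
#' @param h_f Histogram-spread feature matrix (see
#'   [histogram_spread_map()]).
#' @param cfg An [alpha_config()].
#' @return Matrix of exponents in `[alpha_min, alpha_max]`.
#' @export
alpha_from_histogram <- function(h_f, cfg = alpha_config()) {
  stopifnot(inherits(cfg, "alpha_config"))
  bell <- exp(-(h_f - cfg$hist_center)^2 / (2 * cfg$hist_scale^2))
  alpha <- cfg$alpha_max - (cfg$alpha_max - cfg$alpha_min) * (1 - bell)^cfg$s
  clamp_alpha(alpha, cfg)
}

#' Enhancement exponent from fuzzy entropy
#'
#' Min-max rescaling of the entropy map into the exponent band:
#' `alpha = alpha_min + (alpha_max - alpha_min) *
#' ((eps - eps_min) / (eps_max - eps_min))^s`, with `eps_min`/`eps_max`
#' taken over the supplied map. A constant entropy map gives `alpha_min`
#' everywhere by convention.
#'
#' @param eps Fuzzy-entropy feature matrix (see [fuzzy_entropy_map()]).
#' @param cfg An [alpha_config()].
#' @return Matrix of exponents in `[alpha_min, alpha_max]`.
#' @export
alpha_from_entropy <- function(eps, cfg = alpha_config()) {
  stopifnot(inherits(cfg, "alpha_config"))
  e_min <- min(eps); e_max <- max(eps)
  if (e_max <= e_min) {
    return(array(cfg$alpha_min, dim(eps)))
  }
  ratio <- (eps - e_min) / (e_max - e_min)
  clamp_alpha(cfg$alpha_min + (cfg$alpha_max - cfg$alpha_min) * ratio^cfg$s, cfg)
}

#' Enhancement exponent from fuzzy standard deviation
#'
#' The dispersion map is normalized by its maximum to `sigma_hat` in
#' `[0, 1]` (all zeros if the map is identically zero), then
#' `alpha = alpha_min * sigma_hat + alpha_max * (1 - sigma_hat^s)`,
#' clamped to the exponent band; decreasing in `sigma_hat` for `s = 1`.
#'
#' @param sigma Fuzzy-standard-deviation feature matrix (see
#'   [fuzzy_std_map()]).
#' @param cfg An [alpha_config()].
#' @return Matrix of exponents in `[alpha_min, alpha_max]`.
#' @export
alpha_from_std <- function(sigma, cfg = alpha_config()) {
  stopifnot(inherits(cfg, "alpha_config"))
  s_max <- max(sigma)
  sigma_hat <- if (s_max > 0) sigma / s_max else array(0, dim(sigma))
  alpha <- cfg$alpha_min * sigma_hat + cfg$alpha_max * (1 - sigma_hat^cfg$s)
  clamp_alpha(alpha, cfg)
}

#' Nonlinear local-contrast transform
#'
#' Stretches local contrast about the pivot `C_hat` (mean or median of
#' the map, per the configuration): for `C <= C_hat`,
#' `C* = B0 + (R/2 - A0) * ((C - C_min) / (C_hat - C_min))^alpha`; for
#' `C > C_hat`,
#' `C* = R - A0 - (R/2 - A0) * ((C_max - C) / (C_max - C_hat))^alpha`.
#' `C_min`/`C_max` are taken over the map and the result is clamped to
#' `[0, R]`. If the map is degenerate (no strict ordering
#' `C_min < C_hat < C_max`), `C` is returned unchanged.
#'
#' @param C Local-contrast matrix (see [local_contrast_map()]).
#' @param alpha Exponent matrix aligned with `C` (or a scalar).
#' @param cfg A [contrast_transform_config()].
#' @return Matrix of enhanced contrast values in `[0, R]`.
#' @export
enhance_local_contrast <- function(C, alpha, cfg = contrast_transform_config()) {
  stopifnot(inherits(cfg, "contrast_transform_config"))
  if (length(alpha) == 1L) alpha <- array(alpha, dim(C))
  stopifnot(identical(dim(alpha), dim(C)))
  c_min <- min(C); c_max <- max(C)
  c_hat <- if (cfg$c_hat_mode == "mean") mean(C) else stats::median(C)
  if (!(c_min < c_hat && c_hat < c_max)) {
    return(C)
  }
  lo <- B0_lower(C, alpha, cfg, c_min, c_hat)
  hi <- cfg$R - cfg$A0 -
    (cfg$R / 2 - cfg$A0) * ((c_max - C) / (c_max - c_hat))^alpha
  out <- ifelse(C <= c_hat, lo, hi)
  clamp(out, 0, cfg$R)
}

B0_lower <- function(C, alpha, cfg, c_min, c_hat) {
  cfg$B0 + (cfg$R / 2 - cfg$A0) * ((C - c_min) / (c_hat - c_min))^alpha
}

#' Reconstruct an image from enhanced local contrast
#'
#' Applies a mean-anchored multiplicative gain per pixel:
#' `f' = M_W + (f - M_W) * (C* / C)`, where `M_W` is the arithmetic mean
#' of the sliding window. Pixels whose original local contrast is below
#' `1e-6` are left unchanged (unit gain). The result is rounded half up
#' and clamped to `[0, 255]`. This gain exactly realizes the target
#' contrast `C*` for the window's extreme pixels under the range-based
#' local-contrast definition.
#'
#' @param image Intensity matrix in `[0, 255]`.
#' @param C Original local-contrast matrix.
#' @param C_star Enhanced local-contrast matrix.
#' @param win The [window_spec()] used to compute the contrast maps.
#' @return The reconstructed intensity matrix.
#' @export
reconstruct_image <- function(image, C, C_star, win = window_spec()) {
  check_feature_inputs(image, win)
  stopifnot(identical(dim(C), dim(image)), identical(dim(C_star), dim(image)))
  st <- window_stack(image, win)
  m_w <- Reduce(`+`, st) / length(st)
  gain <- ifelse(C < 1e-6, 1, C_star / C)
  clamp(round_half_up(m_w + (image - m_w) * gain), 0, GRAY_LEVELS - 1L)
}
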