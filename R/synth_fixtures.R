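#' Synthetic chest-X-ray fixture parameters
#'
#' Controls the seeded generator of chest-X-ray-like grayscale images
#' used for offline testing: a dark background, two brighter ellipsoidal
#' lung fields, low-contrast horizontal rib bands, Gaussian pixel noise,
#' and (for the pneumonia class) bright Gaussian-profile opacity blobs
#' inside the lung fields. Each image's randomness is derived from
#' `(seed, class, index)`, so any subset regenerates identically
#' regardless of generation order.
#'
#' @param size `c(height, width)` (default `c(128, 128)`; 32x32 keeps
#'   large runs fast, 512x512 matches the classifier's working size).
#' @param n_normal,n_pneumonia Image counts per class.
#' @param seed Integer master seed.
#' @param noise_sd Gaussian noise standard deviation in intensity units
#'   (default 8).
#' @param opacity_count Number of pneumonia opacity blobs per image
#'   (default 3).
#' @param opacity_intensity Peak added intensity of each blob
#'   (default 40).
#' @return An object of class `fixture_params`.
#' @export
fixture_params <- function(size = c(128L, 128L), n_normal = 10L,
                           n_pneumonia = 10L, seed = 1L, noise_sd = 8,
                           opacity_count = 3L, opacity_intensity = 40) {
  size <- as.integer(size)
  if (length(size) != 2L || any(size < 1L)) {
    stop("`size` must be two positive integers", call. = FALSE)
  }
  if (n_normal < 0L || n_pneumonia < 0L) {
    stop("class counts must be nonnegative", call. = FALSE)
  }
  if (noise_sd < 0 || opacity_count < 0L || opacity_intensity < 0) {
    stop("noise and opacity parameters must be nonnegative", call. = FALSE)
  }
  structure(list(size = size, n_normal = as.integer(n_normal),
                 n_pneumonia = as.integer(n_pneumonia),
                 seed = as.integer(seed), noise_sd = noise_sd,
                 opacity_count = as.integer(opacity_count),
                 opacity_intensity = opacity_intensity),
            class = "fixture_params")
}

# counter-based stream split: every image draws from its own sub-seed
mix_seed <- function(seed, class_code, index) {
  s <- ((seed %% 65011L) * 31L + class_code * 499979L + index * 7919L) %%
    2147483629L
  s + 1L
}

#' Binary mask of the two synthetic lung fields
#'
#' @param size `c(height, width)`.
#' @return Logical matrix, `TRUE` inside either elliptical lung field.
#' @export
lung_field_mask <- function(size) {
  M <- size[1]; N <- size[2]
  yy <- matrix((seq_len(M) - 0.5) / M, M, N)
  xx <- matrix((seq_len(N) - 0.5) / N, M, N, byrow = TRUE)
  left <- ((xx - 0.33) / 0.17)^2 + ((yy - 0.55) / 0.30)^2 <= 1
  right <- ((xx - 0.67) / 0.17)^2 + ((yy - 0.55) / 0.30)^2 <= 1
  left | right
}

#' Generate one synthetic chest-X-ray-like image
#'
#' @param params A [fixture_params()].
#' @param class_label `"Normal"` or `"Pneumonia"`.
#' @param index 1-based image index within its class.
#' @return An intensity matrix in `[0, 255]`.
#' @export
generate_fixture_image <- function(params, class_label, index) {
  stopifnot(inherits(params, "fixture_params"))
  class_label <- match.arg(class_label, c("Normal", "Pneumonia"))
  M <- params$size[1]; N <- params$size[2]
  yy <- matrix((seq_len(M) - 0.5) / M, M, N)
  xx <- matrix((seq_len(N) - 0.5) / N, M, N, byrow = TRUE)
  lungs <- lung_field_mask(params$size)

  img <- 25 + 15 * yy            # dark mediastinal background, mild gradient
  img[lungs] <- img[lungs] + 60  # radiolucent lung fields
  ribs <- 8 * sin(2 * pi * 6 * yy)
  img[lungs] <- img[lungs] + ribs[lungs]

  code <- if (class_label == "Pneumonia") 2L else 1L
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(mix_seed(params$seed, code, index))

  if (class_label == "Pneumonia" && params$opacity_count > 0L) {
    # pick blob centers inside one of the lung fields
    for (b in seq_len(params$opacity_count)) {
      cx <- if (stats::runif(1) < 0.5) 0.33 else 0.67
      bx <- cx + stats::runif(1, -0.10, 0.10)
      by <- 0.55 + stats::runif(1, -0.20, 0.20)
      amp <- params$opacity_intensity * stats::runif(1, 0.7, 1.2)
      w <- stats::runif(1, 0.04, 0.09)
      blob <- amp * exp(-(((xx - bx)^2 + (yy - by)^2)) / (2 * w^2))
      blob[!lungs] <- 0 # opacities are consolidation inside the lung fields
      img <- img + blob
    }
  }
  if (params$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(M * N, sd = params$noise_sd), M, N)
  }
  clamp(round_half_up(img), 0, GRAY_LEVELS - 1L)
}

#' Generate a labeled synthetic fixture dataset
#'
#' Writes `n_normal` + `n_pneumonia` PNGs into `Normal/` and
#' `Pneumonia/` subfolders of `out_root` (the same layout the dataset
#' builder consumes) and returns a small manifest of counts and paths.
#'
#' @param params A [fixture_params()].
#' @param out_root Output folder (created if needed).
#' @return List with `root`, `counts` (named per class) and `paths`.
#' @export
generate_fixture_dataset <- function(params, out_root) {
  stopifnot(inherits(params, "fixture_params"))
  counts <- c(Normal = params$n_normal, Pneumonia = params$n_pneumonia)
  paths <- character(0)
  for (class_label in names(counts)) {
    dir.create(file.path(out_root, class_label), recursive = TRUE,
               showWarnings = FALSE)
    n <- counts[[class_label]]
    for (i in seq_len(n)) {
      img <- generate_fixture_image(params, class_label, i)
      p <- file.path(out_root, class_label,
                     sprintf("%s_%05d.png", tolower(class_label), i))
      write_gray_image(img, p)
      paths <- c(paths, p)
    }
  }
  list(root = out_root, counts = counts, paths = paths)
}
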