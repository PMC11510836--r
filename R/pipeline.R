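#' Enhancement configuration
#'
#' Bundles every tunable of the twelve-step enhancement: fuzzifier,
#' sliding window, exponent map, contrast transform, the entropy scale
#' coefficient, the working image size used by the dataset builder, and
#' which local feature drives the exponent (`variant`).
#'
#' @param fuzzifier A [fuzzifier_config()].
#' @param window A [window_spec()].
#' @param alpha An [alpha_config()].
#' @param transform A [contrast_transform_config()].
#' @param entropy_coeff Positive scale `a` of the fuzzy entropy
#'   (default 1).
#' @param variant One of `"histogram"`, `"entropy"`, `"std"`: the local
#'   feature that selects the enhancement exponent.
#' @param size Working `c(height, width)` to which the dataset builder
#'   resizes inputs before enhancement (default `c(512, 512)`), or `NULL`
#'   to keep native sizes. [enhance_image()] itself never resizes.
#' @return An object of class `enhancement_config`.
#' @export
enhancement_config <- function(fuzzifier = fuzzifier_config(),
                               window = window_spec(),
                               alpha = alpha_config(),
                               transform = contrast_transform_config(),
                               entropy_coeff = 1,
                               variant = c("histogram", "entropy", "std"),
                               size = c(512L, 512L)) {
  variant <- match.arg(variant)
  stopifnot(inherits(fuzzifier, "fuzzifier_config"),
            inherits(window, "window_spec"),
            inherits(alpha, "alpha_config"),
            inherits(transform, "contrast_transform_config"))
  if (entropy_coeff <= 0) stop("`entropy_coeff` must be positive", call. = FALSE)
  if (!is.null(size)) {
    size <- as.integer(size)
    stopifnot(length(size) == 2L, all(size >= 1L))
  }
  structure(list(fuzzifier = fuzzifier, window = window, alpha = alpha,
                 transform = transform, entropy_coeff = entropy_coeff,
                 variant = variant, size = size),
            class = "enhancement_config")
}

ENHANCEMENT_VARIANTS <- c("histogram", "entropy", "std")

# shared state of one enhancement run: everything the three variants
# have in common (fuzzified image, window stacks, local-contrast map)
enhancement_context <- function(image, cfg) {
  u <- normalize_image(image)
  mu <- refine_membership(fuzzify(u, cfg$fuzzifier))
  st <- window_stack(image, cfg$window)
  nm <- cfg$window$height * cfg$window$width
  C <- (Reduce(pmax, st) - Reduce(pmin, st)) / (GRAY_LEVELS - 1L)
  m_w <- Reduce(`+`, st) / nm
  list(image = image, cfg = cfg, mu = mu, stack = st, nm = nm,
       C = C, local_mean = m_w, counts = NULL)
}

context_counts <- function(ctx) {
  if (is.null(ctx$counts)) ctx$counts <- window_counts(ctx$stack)
  ctx
}

enhance_with_context <- function(ctx, variant) {
  cfg <- ctx$cfg
  alpha <- switch(variant,
    histogram = {
      ctx <- context_counts(ctx)
      spread <- (Reduce(pmax, ctx$stack) - Reduce(pmin, ctx$stack)) /
        Reduce(pmax, ctx$counts)
      alpha_from_histogram(spread, cfg$alpha)
    },
    entropy = {
      if (ctx$nm < 2L) stop("entropy variant needs a window of at least 2 pixels",
                            call. = FALSE)
      ctx <- context_counts(ctx)
      eps <- entropy_from_counts(ctx$counts, ctx$nm, cfg$entropy_coeff)
      alpha_from_entropy(eps, cfg$alpha)
    },
    std = {
      sigma <- fuzzy_std_map(ctx$image, ctx$mu, cfg$window)
      alpha_from_std(sigma, cfg$alpha)
    },
    stop("unknown variant: ", variant, call. = FALSE)
  )
  c_star <- enhance_local_contrast(ctx$C, alpha, cfg$transform)
  gain <- ifelse(ctx$C < 1e-6, 1, c_star / ctx$C)
  out <- clamp(round_half_up(ctx$local_mean + (ctx$image - ctx$local_mean) * gain),
               0, GRAY_LEVELS - 1L)
  list(image = out, ctx = ctx)
}

#' Enhance a grayscale image with the fuzzy contrast pipeline
#'
#' Runs the full enhancement chain: min-max normalization,
#' fuzzification, INT membership refinement, the variant's local feature
#' map, the feature-driven exponent map, the local-contrast map, the
#' nonlinear contrast transform, and mean-anchored reconstruction.
#' Constant images pass through unchanged (all contrast features vanish).
#'
#' @param image Intensity matrix in `[0, 255]`.
#' @param cfg An [enhancement_config()]; `cfg$variant` selects the
#'   driving feature.
#' @return The enhanced intensity matrix, same dimensions as the input.
#' @export
enhance_image <- function(image, cfg = enhancement_config()) {
  stopifnot(inherits(cfg, "enhancement_config"))
  validate_gray_image(image)
  enhance_with_context(enhancement_context(image, cfg), cfg$variant)$image
}

#' Enhance an image with all three feature variants
#'
#' Produces the three enhanced images in the fixed order histogram,
#' entropy, std (matching the three classifier input branches). Shared
#' stages (fuzzification, window statistics, local contrast) are computed
#' once.
#'
#' @inheritParams enhance_image
#' @return Named list `list(histogram = , entropy = , std = )` of
#'   enhanced intensity matrices.
#' @export
enhance_all_variants <- function(image, cfg = enhancement_config()) {
  stopifnot(inherits(cfg, "enhancement_config"))
  validate_gray_image(image)
  ctx <- enhancement_context(image, cfg)
  out <- vector("list", length(ENHANCEMENT_VARIANTS))
  names(out) <- ENHANCEMENT_VARIANTS
  for (v in ENHANCEMENT_VARIANTS) {
    res <- enhance_with_context(ctx, v)
    ctx <- res$ctx # reuse lazily computed window counts
    out[[v]] <- res$image
  }
  out
}

#' Build a tripled, split, enhanced image dataset
#'
#' Reads a class-labeled image folder (`<input_root>/<Class>/*.png|jpg`),
#' enhances every image with all three variants, and writes the results
#' under `<output_root>/<split>/<Class>/<stem>__<variant>.png`. The
#' train/test/validation split (75/15/10) is assigned at source-image
#' level, stratified by class, so the three variants of one source never
#' straddle splits; per class, validation and test sizes are
#' `floor(0.10 N)` and `floor(0.15 N)` with the remainder to train.
#' Unreadable images are skipped with a warning and excluded from the
#' manifest.
#'
#' @param input_root Folder containing one subfolder per class.
#' @param output_root Output folder (created if needed).
#' @param cfg An [enhancement_config()]; if `cfg$size` is non-`NULL`,
#'   inputs are resized (bilinear) to that working size first.
#' @param split_seed Integer seed for the stratified split.
#' @return An object of class `dataset_manifest`: list with `records` (a
#'   data frame with columns `source_path`, `class_label`, `variant`,
#'   `output_path`, `split`) and `summary` (counts per class, variant and
#'   split). A `manifest.csv` and `summary.json` are written under
#'   `output_root`.
#' @export
build_dataset <- function(input_root, output_root,
                          cfg = enhancement_config(), split_seed = 1L) {
  stopifnot(inherits(cfg, "enhancement_config"))
  classes <- list.dirs(input_root, recursive = FALSE)
  if (length(classes) == 0L) {
    stop("no class subfolders found under ", input_root, call. = FALSE)
  }
  records <- list()
  for (class_dir in classes) {
    class_label <- basename(class_dir)
    files <- list.files(class_dir, pattern = "\\.(png|jpg|jpeg)$",
                        ignore.case = TRUE, full.names = TRUE)
    if (length(files) == 0L) {
      stop("class folder contains no images: ", class_dir, call. = FALSE)
    }
    files <- sort(files)
    splits <- assign_splits(length(files), split_seed, class_label)
    for (i in seq_along(files)) {
      img <- tryCatch(read_gray_image(files[i]), error = function(e) {
        warning("skipping unreadable image ", files[i], ": ",
                conditionMessage(e), call. = FALSE)
        NULL
      })
      if (is.null(img)) next
      if (!is.null(cfg$size)) {
        img <- resize_gray_image(img, cfg$size[1], cfg$size[2])
      }
      enhanced <- enhance_all_variants(img, cfg)
      stem <- tools::file_path_sans_ext(basename(files[i]))
      for (v in ENHANCEMENT_VARIANTS) {
        out_path <- file.path(output_root, splits[i], class_label,
                              paste0(stem, "__", v, ".png"))
        write_gray_image(enhanced[[v]], out_path)
        records[[length(records) + 1L]] <- data.frame(
          source_path = files[i], class_label = class_label, variant = v,
          output_path = out_path, split = splits[i],
          stringsAsFactors = FALSE)
      }
    }
  }
  records <- do.call(rbind, records)
  manifest <- new_dataset_manifest(records)
  utils::write.csv(records, file.path(output_root, "manifest.csv"),
                   row.names = FALSE)
  jsonlite::write_json(manifest$summary,
                       file.path(output_root, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

# stratified split assignment for one class of n source images:
# floor(0.10 n) validation, floor(0.15 n) test, remainder train; the
# class label perturbs the seed so classes draw independent permutations
assign_splits <- function(n, split_seed, class_label) {
  n_val <- floor(0.10 * n)
  n_test <- floor(0.15 * n)
  seed <- (as.integer(split_seed) %% 100000L) * 7919L +
    sum(utf8ToInt(class_label)) %% 7919L
  perm <- local({
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    sample.int(n)
  })
  splits <- rep("train", n)
  if (n_val > 0L) splits[perm[seq_len(n_val)]] <- "validation"
  if (n_test > 0L) splits[perm[n_val + seq_len(n_test)]] <- "test"
  splits
}

new_dataset_manifest <- function(records) {
  counts <- as.data.frame(table(class = records$class_label,
                                variant = records$variant,
                                split = records$split),
                          stringsAsFactors = FALSE)
  names(counts)[names(counts) == "Freq"] <- "n"
  summary <- list(
    total_enhanced = nrow(records),
    per_class = as.list(table(records$class_label)),
    per_variant = as.list(table(records$variant)),
    per_split = as.list(table(records$split)),
    counts = counts)
  structure(list(records = records, summary = summary),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat("Dataset manifest:", nrow(x$records), "enhanced images\n")
  cat("  per class:  ",
      paste(names(x$summary$per_class), unlist(x$summary$per_class),
            sep = "=", collapse = ", "), "\n")
  cat("  per split:  ",
      paste(names(x$summary$per_split), unlist(x$summary$per_split),
            sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' No-reference quality report over a built dataset
#'
#' Scores every enhanced image in a manifest with a user-supplied
#' no-reference quality function (for example an external BRISQUE
#' implementation, where lower scores indicate better perceived quality)
#' and reports the mean score per variant and class.
#'
#' @param manifest A `dataset_manifest` from [build_dataset()].
#' @param scorer Function taking an intensity matrix and returning a
#'   single numeric score. Scores are averaged as-is; for BRISQUE-like
#'   scorers lower is better (noted in the output attribute
#'   `orientation`).
#' @return Data frame with columns `variant`, `class_label`,
#'   `mean_score`, `n`.
#' @export
quality_report <- function(manifest, scorer) {
  if (!inherits(manifest, "dataset_manifest") || nrow(manifest$records) == 0L) {
    stop("`manifest` must be a non-empty dataset_manifest", call. = FALSE)
  }
  if (missing(scorer) || !is.function(scorer)) {
    stop("scorer not installed: supply a function(image) -> numeric score",
         call. = FALSE)
  }
  rec <- manifest$records
  scores <- vapply(rec$output_path,
                   function(p) as.numeric(scorer(read_gray_image(p))),
                   numeric(1))
  agg <- stats::aggregate(scores,
                          by = list(variant = rec$variant,
                                    class_label = rec$class_label),
                          FUN = mean)
  n <- stats::aggregate(scores,
                        by = list(variant = rec$variant,
                                  class_label = rec$class_label),
                        FUN = length)
  out <- data.frame(variant = agg$variant, class_label = agg$class_label,
                    mean_score = agg$x, n = n$x, stringsAsFactors = FALSE)
  attr(out, "orientation") <- "lower scores indicate better quality for BRISQUE-like scorers"
  out
}
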