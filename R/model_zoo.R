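#' Layer specification helper
#'
#' @param kind One of `"conv"`, `"maxpool"`, `"concat"`, `"flatten"`,
#'   `"dense"`, `"dropout"`, `"output"`.
#' @param filters Filter count (conv layers).
#' @param units Unit count (dense/output layers).
#' @param kernel Convolution kernel, default `c(3, 3)`.
#' @param pool Pooling window, default `c(2, 2)`.
#' @param stride Pooling stride, default 2.
#' @param activation `"relu"` or `"softmax"` where applicable.
#' @param rate Dropout rate in `[0, 1)`.
#' @param name Layer name.
#' @return A `layer_spec` list.
#' @export
layer_spec <- function(kind, filters = NULL, units = NULL, kernel = c(3L, 3L),
                       pool = c(2L, 2L), stride = 2L, activation = NULL,
                       rate = NULL, name = kind) {
  kind <- match.arg(kind, c("conv", "maxpool", "concat", "flatten",
                            "dense", "dropout", "output"))
  if (kind == "conv" && (is.null(filters) || filters < 1L)) {
    stop("conv layers need a positive `filters`", call. = FALSE)
  }
  if (kind %in% c("dense", "output") && (is.null(units) || units < 1L)) {
    stop(kind, " layers need a positive `units`", call. = FALSE)
  }
  if (kind == "dropout" && (is.null(rate) || rate < 0 || rate >= 1)) {
    stop("dropout layers need a `rate` in [0, 1)", call. = FALSE)
  }
  structure(list(kind = kind, filters = filters, units = units,
                 kernel = kernel, pool = pool, stride = stride,
                 activation = activation, rate = rate, name = name),
            class = "layer_spec")
}

conv <- function(filters, name) layer_spec("conv", filters = filters,
                                           activation = "relu", name = name)
maxpool <- function(name) layer_spec("maxpool", name = name)

#' Three-branch concatenated CNN architecture
#'
#' The pneumonia-detection CCNN: three structurally identical
#' convolutional branches (one per enhancement variant, in the order
#' histogram, entropy, std), each conv(64)-pool-conv(128)-pool-
#' conv(256)-pool, merged by channel concatenation, followed by
#' conv(512)-pool-conv(1024)-pool-flatten-dense(1024)-dropout(0.5)-
#' dense(512)-dropout(0.5) and a 2-unit softmax output. All convolutions
#' use 3x3 kernels with ReLU; pools are 2x2 stride 2.
#'
#' @param input_size `c(height, width, channels)` of each branch input
#'   (default `c(512, 512, 1)`).
#' @return An object of class `architecture_spec`.
#' @export
ccnn_spec <- function(input_size = c(512L, 512L, 1L)) {
  branch <- list(conv(64L, "conv1"), maxpool("pool1"),
                 conv(128L, "conv2"), maxpool("pool2"),
                 conv(256L, "conv3"), maxpool("pool3"))
  trunk <- list(layer_spec("concat", name = "concat"),
                conv(512L, "conv4"), maxpool("pool4"),
                conv(1024L, "conv5"), maxpool("pool5"),
                layer_spec("flatten", name = "flatten"),
                layer_spec("dense", units = 1024L, activation = "relu",
                           name = "dense1"),
                layer_spec("dropout", rate = 0.5, name = "dropout1"),
                layer_spec("dense", units = 512L, activation = "relu",
                           name = "dense2"),
                layer_spec("dropout", rate = 0.5, name = "dropout2"),
                layer_spec("output", units = 2L, activation = "softmax",
                           name = "output"))
  structure(list(name = "ccnn", input_size = as.integer(input_size),
                 branches = list(branch, branch, branch), trunk = trunk),
            class = "architecture_spec")
}

#' Single-branch CNN architecture
#'
#' The lighter single-input model: conv(32)-pool-conv(64)-pool-
#' conv(128)-pool-flatten-dense(256)-dense(128) and a 2-unit softmax
#' output, under the same same-padding/2x2-pool convention as the CCNN.
#'
#' @inheritParams ccnn_spec
#' @return An object of class `architecture_spec`.
#' @export
cnn_spec <- function(input_size = c(512L, 512L, 1L)) {
  branch <- list(conv(32L, "conv1"), maxpool("pool1"),
                 conv(64L, "conv2"), maxpool("pool2"),
                 conv(128L, "conv3"), maxpool("pool3"))
  trunk <- list(layer_spec("flatten", name = "flatten"),
                layer_spec("dense", units = 256L, activation = "relu",
                           name = "dense1"),
                layer_spec("dense", units = 128L, activation = "relu",
                           name = "dense2"),
                layer_spec("output", units = 2L, activation = "softmax",
                           name = "output"))
  structure(list(name = "cnn", input_size = as.integer(input_size),
                 branches = list(branch), trunk = trunk),
            class = "architecture_spec")
}

#' Training preset
#'
#' The default training parameters: Adam with learning rate 0.001, batch
#' size 32, 50 epochs, early stopping on validation loss with patience
#' 10, and binary cross-entropy realized as categorical cross-entropy
#' over the 2-unit softmax.
#'
#' @param learning_rate,batch_size,epochs,early_stopping_patience
#'   Overrides of the defaults.
#' @return A `training_preset` list.
#' @export
training_preset <- function(learning_rate = 0.001, batch_size = 32L,
                            epochs = 50L, early_stopping_patience = 10L) {
  structure(list(optimizer = "adam", learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 loss = "binary_crossentropy"),
            class = "training_preset")
}

pool_dims <- function(h, w, layer_name) {
  h2 <- h %/% 2L
  w2 <- w %/% 2L
  if (h2 < 1L || w2 < 1L) {
    stop("architecture error: pooling at `", layer_name,
         "` underflows spatial dimensions", call. = FALSE)
  }
  c(h2, w2)
}

#' Shape trace of an architecture
#'
#' Pure shape calculus, no deep-learning backend needed: same-padding
#' convolutions preserve spatial size and set the channel count to the
#' filter count; each 2x2/stride-2 pool halves each spatial side
#' (floor); concatenation sums the branch channels; flatten yields
#' `H * W * C` units. Branches are required to be structurally identical
#' and are traced once.
#'
#' @param spec An `architecture_spec` from [ccnn_spec()] or [cnn_spec()].
#' @param input_size `c(height, width, channels)`; defaults to the
#'   spec's own input size.
#' @return Data frame with columns `layer`, `height`, `width`,
#'   `channels`, `units` (spatial columns are `NA` for flat layers and
#'   vice versa).
#' @export
shape_trace <- function(spec, input_size = spec$input_size) {
  stopifnot(inherits(spec, "architecture_spec"))
  input_size <- as.integer(input_size)
  stopifnot(length(input_size) == 3L, all(input_size >= 1L))
  for (b in spec$branches[-1]) {
    if (!identical(b, spec$branches[[1]])) {
      stop("architecture error: branches are not structurally identical",
           call. = FALSE)
    }
  }
  rows <- list()
  add <- function(name, h = NA, w = NA, c = NA, u = NA) {
    rows[[length(rows) + 1L]] <<- data.frame(
      layer = name, height = h, width = w, channels = c, units = u,
      stringsAsFactors = FALSE)
  }
  h <- input_size[1]; w <- input_size[2]; ch <- input_size[3]
  add("input", h, w, ch)
  for (ly in spec$branches[[1]]) {
    if (ly$kind == "conv") {
      ch <- ly$filters
    } else if (ly$kind == "maxpool") {
      hw <- pool_dims(h, w, ly$name); h <- hw[1]; w <- hw[2]
    } else stop("unsupported branch layer: ", ly$kind, call. = FALSE)
    add(paste0("branch_", ly$name), h, w, ch)
  }
  units <- NA
  for (ly in spec$trunk) {
    if (ly$kind == "concat") {
      ch <- ch * length(spec$branches)
      add(ly$name, h, w, ch)
    } else if (ly$kind == "conv") {
      ch <- ly$filters
      add(ly$name, h, w, ch)
    } else if (ly$kind == "maxpool") {
      hw <- pool_dims(h, w, ly$name); h <- hw[1]; w <- hw[2]
      add(ly$name, h, w, ch)
    } else if (ly$kind == "flatten") {
      units <- h * w * ch
      add(ly$name, u = units)
    } else if (ly$kind %in% c("dense", "output")) {
      units <- ly$units
      add(ly$name, u = units)
    } else if (ly$kind == "dropout") {
      add(ly$name, u = units)
    } else stop("unsupported trunk layer: ", ly$kind, call. = FALSE)
  }
  do.call(rbind, rows)
}

#' Build a trainable model from an architecture spec
#'
#' Requires a deep-learning backend (the \pkg{keras} or \pkg{torch} R
#' package). Without one this function raises an explicit capability
#' error of class `fuzzycontrast_backend_error`; [shape_trace()] is pure
#' arithmetic and always available.
#'
#' @param spec An `architecture_spec`.
#' @param preset A [training_preset()].
#' @return A compiled model handle (backend-specific).
#' @export
build_model <- function(spec, preset = training_preset()) {
  stopifnot(inherits(spec, "architecture_spec"))
  has_backend <- requireNamespace("keras", quietly = TRUE) ||
    requireNamespace("torch", quietly = TRUE)
  if (!has_backend) {
    stop(structure(class = c("fuzzycontrast_backend_error", "error", "condition"),
                   list(message = paste(
                     "no deep-learning backend installed:",
                     "build_model() needs the keras or torch package;",
                     "shape_trace() works without one"),
                     call = sys.call(-1))))
  }
  stop("backend construction for '", spec$name,
       "' is not implemented for the detected backend", call. = FALSE)
}

#' Binary classification metrics
#'
#' Standard binary metrics with the pneumonia class as positive:
#' accuracy, precision, recall and F1 at a 0.5 probability threshold,
#' and AUC by the rank (Mann-Whitney) statistic with ties receiving 0.5
#' credit. With a single-class truth vector the AUC is undefined and
#' reported as `NA` with a warning.
#'
#' @param y_true Vector of true labels; either the character labels
#'   `"Normal"`/`"Pneumonia"` or 0/1 with 1 = pneumonia.
#' @param y_prob Predicted probabilities of the positive (pneumonia)
#'   class, in `[0, 1]`.
#' @param positive Label treated as positive (default `"Pneumonia"`).
#' @return Named list with `accuracy`, `precision`, `recall`, `f1`,
#'   `auc`.
#' @export
classification_metrics <- function(y_true, y_prob, positive = "Pneumonia") {
  if (length(y_true) != length(y_prob)) {
    stop("`y_true` and `y_prob` must have equal length", call. = FALSE)
  }
  if (anyNA(y_prob) || min(y_prob) < 0 || max(y_prob) > 1) {
    stop("`y_prob` must lie in [0, 1]", call. = FALSE)
  }
  pos <- if (is.numeric(y_true)) y_true == 1 else y_true == positive
  pred <- y_prob >= 0.5
  tp <- sum(pos & pred); fp <- sum(!pos & pred)
  fn <- sum(pos & !pred); tn <- sum(!pos & !pred)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  f1 <- if (!is.na(precision) && !is.na(recall) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else NA_real_
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0L || n_neg == 0L) {
    warning("AUC undefined: y_true contains a single class", call. = FALSE)
    auc <- NA_real_
  } else {
    r <- rank(y_prob) # mean ranks give ties 0.5 credit
    auc <- (sum(r[pos]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  }
  list(accuracy = (tp + tn) / length(pos), precision = precision,
       recall = recall, f1 = f1, auc = auc)
}
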