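#' Load an enhancement configuration from YAML or JSON
#'
#' Reads a config file whose top-level keys mirror the arguments of
#' [enhancement_config()] (`fuzzifier`, `window`, `alpha`, `transform`,
#' `entropy_coeff`, `variant`, `size`); missing keys fall back to the
#' built-in defaults, and `overrides` (a named list in the same shape,
#' e.g. from command-line flags) takes precedence over the file.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file, or `NULL` for
#'   defaults only.
#' @param overrides Named list merged on top of the file values.
#' @return An [enhancement_config()].
#' @export
load_enhancement_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    ext <- tolower(tools::file_ext(path))
    vals <- if (ext %in% c("yaml", "yml")) {
      yaml::read_yaml(path)
    } else if (ext == "json") {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      stop("config must be YAML or JSON: ", path, call. = FALSE)
    }
    if (is.null(vals)) vals <- list()
  }
  vals <- modify_list(vals, overrides)
  enhancement_config(
    fuzzifier = do.call(fuzzifier_config, vals$fuzzifier %||% list()),
    window = do.call(window_spec, vals$window %||% list()),
    alpha = do.call(alpha_config, vals$alpha %||% list()),
    transform = do.call(contrast_transform_config, vals$transform %||% list()),
    entropy_coeff = vals$entropy_coeff %||% 1,
    variant = vals$variant %||% "histogram",
    size = if ("size" %in% names(vals)) vals$size else c(512L, 512L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# recursive utils::modifyList that tolerates non-list leaves
modify_list <- function(base, new) {
  if (length(new) == 0L) return(base)
  for (nm in names(new)) {
    if (is.list(new[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list(base[[nm]], new[[nm]])
    } else {
      base[nm] <- new[nm]
    }
  }
  base
}

#' Serialize a resolved enhancement configuration to a plain list
#'
#' Used to echo the fully resolved configuration beside run outputs.
#'
#' @param cfg An [enhancement_config()].
#' @return A nested plain list suitable for [jsonlite::write_json()].
#' @export
config_as_list <- function(cfg) {
  stopifnot(inherits(cfg, "enhancement_config"))
  lapply(cfg, function(x) if (is.list(x)) unclass(x) else x)
}
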