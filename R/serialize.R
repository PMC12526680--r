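MODEL_FORMAT <- "agripinn_model"
MODEL_FORMAT_VERSION <- 1L

#' Save a fitted model to a single versioned file
#'
#' Bundles the model with a format header, the package version, the class
#' order and the knowledge-base hash, so loads can validate provenance.
#' The container is an RDS file (runtime artifact).
#'
#' @param model a fitted `crop_pinn`, `crop_stacking`, `crop_forest` or
#'   `crop_gbt`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_crop_model <- function(model, path) {
  bundle <- list(format = MODEL_FORMAT,
                 format_version = MODEL_FORMAT_VERSION,
                 package_version = as.character(utils::packageVersion("agripinn")),
                 model_class = class(model)[1],
                 class_order = model$class_order,
                 kb_hash = if (is.null(model$kb_hash)) NA_character_
                           else model$kb_hash,
                 model = model)
  saveRDS(bundle, path)
  invisible(path)
}

#' Load a model saved by [save_crop_model]
#'
#' @param path file path.
#' @return the fitted model, with a `provenance` attribute holding the bundle
#'   header.
#' @export
load_crop_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  bundle <- readRDS(path)
  if (!identical(bundle$format, MODEL_FORMAT)) {
    stop("not an agripinn model file: ", path, call. = FALSE)
  }
  if (bundle$format_version > MODEL_FORMAT_VERSION) {
    stop("model file has format version ", bundle$format_version,
         "; this package reads up to ", MODEL_FORMAT_VERSION, call. = FALSE)
  }
  model <- bundle$model
  attr(model, "provenance") <- bundle[setdiff(names(bundle), "model")]
  model
}
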