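#' Gaussian agronomic suitability score
#'
#' Scores how close a measured growing condition is to a crop's optimum using
#' an (unnormalised) Gaussian membership function
#' \deqn{s(x) = \exp\left(-\frac{(x - \mu)^2}{2\sigma^2}\right),}
#' so the score is 1 exactly at the optimum \eqn{\mu} and decays smoothly with
#' the squared distance, with decay rate set by \eqn{\sigma}. The score is
#' always computed on raw physical units (°C, pH), never on scaled features.
#'
#' @param value numeric vector of measurements (physical units).
#' @param mu optimum (mean of the ideal range), same units as `value`.
#' @param sigma spread of the ideal range; must be strictly positive.
#' @return numeric vector of suitability scores in (0, 1].
#' @examples
#' gaussian_score(25, mu = 25, sigma = 3)        # 1 at the optimum
#' gaussian_score(28, mu = 25, sigma = 3)        # exp(-1/2)
#' @export
gaussian_score <- function(value, mu, sigma) {
  if (any(!is.finite(sigma)) || any(sigma <= 0)) {
    stop("`sigma` must be strictly positive", call. = FALSE)
  }
  exp(-((value - mu)^2) / (2 * sigma^2))
}

new_crop_kb <- function(entries, class_order) {
  structure(list(entries = entries, class_order = class_order),
            class = "crop_kb")
}

validate_kb_entries <- function(entries) {
  required <- c("label", "mu_temp", "sigma_temp", "mu_ph", "sigma_ph")
  missing <- setdiff(required, names(entries))
  if (length(missing) > 0) {
    stop("knowledge base is missing field(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  entries$label <- as.character(entries$label)
  for (col in setdiff(required, "label")) {
    entries[[col]] <- as.numeric(entries[[col]])
    bad <- which(!is.finite(entries[[col]]))
    if (length(bad) > 0) {
      stop("non-finite ", col, " for crop '", entries$label[bad[1]], "'",
           call. = FALSE)
    }
  }
  if (any(!nzchar(entries$label))) stop("empty crop label", call. = FALSE)
  dup <- entries$label[duplicated(entries$label)]
  if (length(dup) > 0) {
    stop("duplicate crop label(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad_sigma <- entries$label[entries$sigma_temp <= 0 | entries$sigma_ph <= 0]
  if (length(bad_sigma) > 0) {
    stop("non-positive sigma for crop(s): ",
         paste(bad_sigma, collapse = ", "), call. = FALSE)
  }
  bad_ph <- entries$label[entries$mu_ph < 0 | entries$mu_ph > 14]
  if (length(bad_ph) > 0) {
    stop("mu_ph outside [0, 14] for crop(s): ",
         paste(bad_ph, collapse = ", "), call. = FALSE)
  }
  entries
}

#' Construct a crop physics knowledge base
#'
#' The knowledge base holds, for every crop, the mean and standard deviation
#' of its ideal temperature (°C) and ideal soil pH. These four parameters
#' define the Gaussian suitability scores used by the physics-informed loss.
#'
#' @param entries data.frame with columns `label`, `mu_temp`, `sigma_temp`,
#'   `mu_ph`, `sigma_ph` (one row per crop).
#' @param class_order optional explicit label ordering; defaults to sorted
#'   labels. Must be a permutation of `entries$label`.
#' @return an object of class `crop_kb`.
#' @export
crop_kb <- function(entries, class_order = NULL) {
  entries <- validate_kb_entries(as.data.frame(entries,
                                               stringsAsFactors = FALSE))
  if (is.null(class_order)) {
    class_order <- sort(entries$label)
  } else {
    class_order <- as.character(class_order)
    if (!setequal(class_order, entries$label) ||
        length(class_order) != nrow(entries)) {
      stop("`class_order` must be a permutation of the entry labels",
           call. = FALSE)
    }
  }
  entries <- entries[match(class_order, entries$label), , drop = FALSE]
  rownames(entries) <- NULL
  new_crop_kb(entries, class_order)
}

#' @export
print.crop_kb <- function(x, ...) {
  cat("Crop physics knowledge base:", nrow(x$entries), "crops\n")
  cat("  temperature optima:",
      sprintf("%.1f-%.1f degC", min(x$entries$mu_temp),
              max(x$entries$mu_temp)), "\n")
  cat("  pH optima:",
      sprintf("%.2f-%.2f", min(x$entries$mu_ph), max(x$entries$mu_ph)), "\n")
  invisible(x)
}

#' Load a knowledge base from JSON or CSV
#'
#' JSON format: `{"crops": [{"label": ..., "mu_temp": ..., "sigma_temp": ...,
#' "mu_ph": ..., "sigma_ph": ...}, ...]}`. CSV format: the same five columns
#' with a header row. Validation errors name the offending crop.
#'
#' @param source path to a `.json` or `.csv` file.
#' @param class_order optional explicit label ordering (default: sorted).
#' @return a [crop_kb] object.
#' @export
load_knowledge_base <- function(source, class_order = NULL) {
  if (!file.exists(source)) {
    stop("knowledge base file not found: ", source, call. = FALSE)
  }
  ext <- tolower(tools::file_ext(source))
  entries <- if (ext == "json") {
    parsed <- jsonlite::fromJSON(source)
    if (is.null(parsed$crops)) {
      stop("knowledge base JSON must contain a top-level \"crops\" array",
           call. = FALSE)
    }
    as.data.frame(parsed$crops, stringsAsFactors = FALSE)
  } else if (ext %in% c("csv", "tsv")) {
    utils::read.csv(source, stringsAsFactors = FALSE)
  } else {
    stop("unsupported knowledge base format: '", ext,
         "' (expected json or csv)", call. = FALSE)
  }
  crop_kb(entries, class_order = class_order)
}

#' Path to the illustrative default 22-crop knowledge base
#'
#' The shipped table covers the 22 crop classes of the standard
#' crop-recommendation schema with illustrative optimum temperature/pH values
#' drawn from general agronomic ranges. It is a working default, not a
#' validated agronomic reference; supply your own table for real analyses.
#'
#' @return path to the installed JSON file.
#' @export
default_kb_path <- function() {
  system.file("extdata", "default_crop_kb.json", package = "agripinn",
              mustWork = TRUE)
}

#' Temperature and pH suitability for one crop
#'
#' @param temp temperature in °C (vectorised).
#' @param ph soil pH (vectorised).
#' @param entry one-row data.frame (or list) with `mu_temp`, `sigma_temp`,
#'   `mu_ph`, `sigma_ph`.
#' @return list with numeric `temp_score` and `ph_score`, each in (0, 1].
#' @export
physics_scores <- function(temp, ph, entry) {
  list(temp_score = gaussian_score(temp, entry$mu_temp, entry$sigma_temp),
       ph_score = gaussian_score(ph, entry$mu_ph, entry$sigma_ph))
}

#' Joint suitability matrix for a batch of samples
#'
#' Computes `temp_score * ph_score` for every (sample, crop) pair, the
#' quantity multiplying the predicted class probability inside the physics
#' penalty.
#'
#' @param kb a [crop_kb].
#' @param temp,ph numeric vectors of equal length (raw physical units).
#' @return numeric matrix, `length(temp)` rows by `length(kb$class_order)`
#'   columns, in crop order `kb$class_order`.
#' @export
kb_suitability <- function(kb, temp, ph) {
  stopifnot(inherits(kb, "crop_kb"), length(temp) == length(ph))
  e <- kb$entries
  ts <- exp(-outer(temp, e$mu_temp, "-")^2 /
              rep(2 * e$sigma_temp^2, each = length(temp)))
  ps <- exp(-outer(ph, e$mu_ph, "-")^2 /
              rep(2 * e$sigma_ph^2, each = length(ph)))
  s <- ts * ps
  colnames(s) <- kb$class_order
  s
}

#' Write a knowledge base to JSON (the format read by [load_knowledge_base])
#' @param kb a [crop_kb].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_knowledge_base <- function(kb, path) {
  jsonlite::write_json(list(crops = kb$entries), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Check knowledge-base coverage of a label set
#'
#' Report-only comparison of the crops present in a dataset against the crops
#' covered by the knowledge base. Training a physics-informed model with
#' uncovered labels is refused unless a neutral-score fallback is explicitly
#' enabled (see [fit_pinn]).
#'
#' @param kb a [crop_kb].
#' @param labels character vector of crop labels observed in data.
#' @return list with `uncovered` (labels in data but not in kb), `unused`
#'   (kb crops absent from data) and logical `ok` (no uncovered labels).
#' @export
validate_coverage <- function(kb, labels) {
  labels <- unique(as.character(labels))
  uncovered <- setdiff(labels, kb$class_order)
  unused <- setdiff(kb$class_order, labels)
  list(uncovered = uncovered, unused = unused, ok = length(uncovered) == 0)
}

#' Hash of a knowledge base (for run provenance)
#' @param kb a [crop_kb].
#' @return character scalar hash of the entry table.
#' @export
kb_hash <- function(kb) {
  rlang::hash(kb$entries)
}
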