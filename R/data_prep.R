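# Canonical feature schema: seven agronomic measurements plus the crop label.
CROP_FEATURES <- c("N", "P", "K", "temperature", "humidity", "ph", "rainfall")

new_crop_dataset <- function(df, class_order) {
  structure(list(df = df, class_order = class_order),
            class = "crop_dataset")
}

validate_samples <- function(df) {
  checks <- list(
    ph = function(x) x >= 0 & x <= 14,
    humidity = function(x) x >= 0 & x <= 100,
    rainfall = function(x) x >= 0,
    N = function(x) x >= 0, P = function(x) x >= 0, K = function(x) x >= 0
  )
  for (col in names(checks)) {
    bad <- which(!checks[[col]](df[[col]]))
    if (length(bad) > 0) {
      stop("invalid ", col, " value (", df[[col]][bad[1]], ") at row ",
           bad[1], call. = FALSE)
    }
  }
  invisible(df)
}

#' Construct a crop dataset
#'
#' @param df data.frame with the seven feature columns `N, P, K, temperature,
#'   humidity, ph, rainfall` plus a `label` column.
#' @param class_order optional canonical label ordering; defaults to sorted
#'   unique labels. Every observed label must appear in it.
#' @return an object of class `crop_dataset`.
#' @export
crop_dataset <- function(df, class_order = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing <- setdiff(c(CROP_FEATURES, "label"), names(df))
  if (length(missing) > 0) {
    stop("dataset is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(df) == 0) stop("dataset is empty", call. = FALSE)
  df$label <- as.character(df$label)
  for (col in CROP_FEATURES) {
    x <- df[[col]]
    if (!is.numeric(x)) {
      suppressWarnings(x <- as.numeric(x))
    }
    bad <- which(!is.finite(x))
    if (length(bad) > 0) {
      stop("non-numeric or missing value in column '", col, "' at row ",
           bad[1], call. = FALSE)
    }
    df[[col]] <- x
  }
  validate_samples(df)
  if (is.null(class_order)) {
    class_order <- sort(unique(df$label))
  } else {
    class_order <- as.character(class_order)
    extra <- setdiff(df$label, class_order)
    if (length(extra) > 0) {
      stop("label(s) not in class_order: ", paste(extra, collapse = ", "),
           call. = FALSE)
    }
  }
  df <- df[, c(CROP_FEATURES, "label")]
  rownames(df) <- NULL
  new_crop_dataset(df, class_order)
}

#' @export
print.crop_dataset <- function(x, ...) {
  cat("Crop dataset:", nrow(x$df), "samples,",
      length(x$class_order), "classes\n")
  invisible(x)
}

#' Number of samples in a crop dataset
#' @param x a `crop_dataset`.
#' @return integer row count.
#' @export
n_samples <- function(x) nrow(x$df)

#' Subset a crop dataset by row index, keeping the class order
#' @param data a `crop_dataset`.
#' @param idx integer row indices.
#' @return a `crop_dataset` over the selected rows.
#' @export
subset_dataset <- function(data, idx) {
  df <- data$df[idx, , drop = FALSE]
  rownames(df) <- NULL
  new_crop_dataset(df, data$class_order)
}

#' Integer-encode dataset labels against the canonical class order
#' @param data a `crop_dataset`.
#' @return integer vector in `1..length(class_order)`.
#' @export
encode_labels <- function(data) {
  match(data$df$label, data$class_order)
}

#' Read crop samples from CSV
#'
#' Expects a header with columns `N, P, K, temperature, humidity, ph,
#' rainfall, label` (case-insensitive). Row order is preserved;
#' `class_order` is the sorted set of unique labels.
#'
#' @param path CSV file path (comma-separated, UTF-8, decimal point).
#' @return a [crop_dataset].
#' @export
read_samples <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0) stop("empty CSV: ", path, call. = FALSE)
  want <- c(CROP_FEATURES, "label")
  hit <- match(tolower(want), tolower(names(df)))
  if (anyNA(hit)) {
    stop("CSV is missing column(s): ",
         paste(want[is.na(hit)], collapse = ", "), call. = FALSE)
  }
  df <- df[, hit]
  names(df) <- want
  crop_dataset(df)
}

#' Write a crop dataset to CSV (the dialect read by [read_samples])
#' @param data a `crop_dataset`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_samples <- function(data, path) {
  utils::write.csv(data$df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- MinMax scaling (fit on training partitions only) ----------------------

#' Fit a MinMax scaler on a training partition
#'
#' Learns per-feature minima and maxima from the supplied data only; applying
#' the scaler maps the training partition into `[0, 1]^d` exactly, while
#' held-out values may fall outside that range (no leakage). Constant features
#' transform to 0 by convention.
#'
#' @param train a `crop_dataset` or numeric feature matrix.
#' @return an object of class `minmax_scaler`.
#' @export
fit_scaler <- function(train) {
  X <- if (inherits(train, "crop_dataset")) {
    as.matrix(train$df[, CROP_FEATURES])
  } else {
    as.matrix(train)
  }
  if (nrow(X) == 0) stop("cannot fit a scaler on an empty dataset",
                         call. = FALSE)
  structure(list(min = apply(X, 2, min), max = apply(X, 2, max),
                 features = colnames(X)),
            class = "minmax_scaler")
}

#' Apply a fitted MinMax scaler
#'
#' Returns the scaled feature matrix for model input together with the raw
#' (untouched) temperature and pH columns, which the physics penalty consumes
#' in physical units.
#'
#' @param scaler a `minmax_scaler` from [fit_scaler].
#' @param data a `crop_dataset` or numeric feature matrix with the same
#'   feature columns the scaler was fitted on.
#' @return list with `X` (scaled matrix), `raw_temp`, `raw_ph`, and (when
#'   `data` is a dataset) `y` integer labels plus `labels`.
#' @export
apply_scaler <- function(scaler, data) {
  is_ds <- inherits(data, "crop_dataset")
  X <- if (is_ds) as.matrix(data$df[, CROP_FEATURES]) else as.matrix(data)
  if (ncol(X) != length(scaler$min)) {
    stop("feature count mismatch: scaler has ", length(scaler$min),
         ", data has ", ncol(X), call. = FALSE)
  }
  rng <- scaler$max - scaler$min
  Xs <- sweep(X, 2, scaler$min)
  nonconst <- rng > 0
  Xs[, nonconst] <- sweep(Xs[, nonconst, drop = FALSE], 2, rng[nonconst], "/")
  Xs[, !nonconst] <- 0
  has <- function(col) !is.null(colnames(X)) && col %in% colnames(X)
  out <- list(X = Xs,
              raw_temp = if (has("temperature")) X[, "temperature"],
              raw_ph = if (has("ph")) X[, "ph"])
  if (is_ds) {
    out$y <- encode_labels(data)
    out$labels <- data$df$label
  }
  out
}

## ---- Splits and folds ------------------------------------------------------

# Stratified assignment helper: returns, per class, a seeded shuffle of its
# row indices so callers can slice deterministically.
shuffled_class_indices <- function(labels, seed) {
  set.seed(seed)
  lapply(split(seq_along(labels), labels), function(idx) {
    if (length(idx) == 1) idx else sample(idx)
  })
}

#' Stratified train/test split
#'
#' @param data a `crop_dataset`.
#' @param test_fraction held-out fraction per class (default 0.2).
#' @param seed RNG seed (default 42).
#' @return list with `train` and `test` crop datasets and the index vectors
#'   `train_idx`, `test_idx`.
#' @export
split_train_test <- function(data, test_fraction = 0.2, seed = 42) {
  stopifnot(test_fraction > 0, test_fraction < 1)
  by_class <- shuffled_class_indices(data$df$label, seed)
  test_idx <- integer(0)
  for (cls in names(by_class)) {
    idx <- by_class[[cls]]
    if (length(idx) == 1) {
      warning("class '", cls, "' has a single sample; assigned to train")
      next
    }
    n_test <- round(length(idx) * test_fraction)
    n_test <- max(min(n_test, length(idx) - 1), 0)
    if (n_test > 0) test_idx <- c(test_idx, idx[seq_len(n_test)])
  }
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(nrow(data$df)), test_idx)
  list(train = subset_dataset(data, train_idx),
       test = subset_dataset(data, test_idx),
       train_idx = train_idx, test_idx = test_idx)
}

#' Stratified k-fold plan
#'
#' Deals each class's (seed-shuffled) indices round-robin into `k` folds, so
#' per-class counts across folds differ by at most one.
#'
#' @param labels character vector of class labels.
#' @param k number of folds (default 5).
#' @param seed RNG seed (default 42).
#' @return object of class `fold_plan`: list with `k`, `seed`, and `folds`,
#'   a list of `k` lists each holding `train` and `validation` index vectors.
#' @export
make_folds <- function(labels, k = 5, seed = 42) {
  n <- length(labels)
  if (k < 2) stop("k must be at least 2", call. = FALSE)
  if (k > n) stop("k (", k, ") exceeds the number of samples (", n, ")",
                  call. = FALSE)
  small <- table(labels) < k
  if (any(small)) {
    warning("class(es) with fewer than k samples: ",
            paste(names(small)[small], collapse = ", "),
            "; folds will be as even as possible")
  }
  by_class <- shuffled_class_indices(labels, seed)
  assignment <- integer(n)
  offset <- 0L
  for (cls in names(by_class)) {
    idx <- by_class[[cls]]
    # rotate the starting fold across classes so small classes do not all
    # pile into fold 1
    assignment[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- (offset + length(idx)) %% k
  }
  folds <- lapply(seq_len(k), function(f) {
    val <- which(assignment == f)
    list(train = setdiff(seq_len(n), val), validation = val)
  })
  structure(list(k = k, seed = seed, folds = folds, n = n),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  sizes <- vapply(x$folds, function(f) length(f$validation), integer(1))
  cat("Stratified fold plan: k =", x$k, ", seed =", x$seed,
      ", validation sizes:", paste(sizes, collapse = "/"), "\n")
  invisible(x)
}
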