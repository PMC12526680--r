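#' Confusion matrix over a fixed class order
#'
#' Rows are true classes, columns predicted classes, both in `class_order`.
#'
#' @param y_true,y_pred character label vectors of equal length.
#' @param class_order canonical label ordering.
#' @return integer C x C matrix with dimnames, class `crop_confusion`.
#' @export
confusion <- function(y_true, y_pred, class_order) {
  if (length(y_true) != length(y_pred)) {
    stop("label vectors differ in length", call. = FALSE)
  }
  unknown <- setdiff(unique(c(y_true, y_pred)), class_order)
  if (length(unknown) > 0) {
    stop("label(s) not in class_order: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  t_f <- factor(y_true, levels = class_order)
  p_f <- factor(y_pred, levels = class_order)
  cm <- table(true = t_f, predicted = p_f)
  structure(matrix(as.integer(cm), nrow = length(class_order),
                   dimnames = list(true = class_order,
                                   predicted = class_order)),
            class = c("crop_confusion", "matrix"))
}

#' Accuracy, precision and recall from a confusion matrix
#'
#' Per-class TP/FP/FN are taken one-vs-rest from the confusion matrix;
#' precision (`TP / (TP + FP)`) and recall (`TP / (TP + FN)`) are computed per
#' class and then averaged — equally weighted (`macro`, the default) or
#' weighted by class support (`weighted`). Accuracy is trace/total. Classes
#' with a zero denominator contribute 0 with a warning.
#'
#' @param cm a confusion matrix from [confusion] (or any square count matrix).
#' @param average `"macro"` or `"weighted"`.
#' @return list with `accuracy`, `precision`, `recall`, each in \[0, 1\].
#' @export
metrics <- function(cm, average = c("macro", "weighted")) {
  average <- match.arg(average)
  cm <- unclass(cm)
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  prec_den <- tp + fp
  rec_den <- tp + fn
  if (any(prec_den == 0) || any(rec_den == 0)) {
    warning("class(es) with zero predicted or true positives contribute 0")
  }
  prec <- ifelse(prec_den == 0, 0, tp / prec_den)
  rec <- ifelse(rec_den == 0, 0, tp / rec_den)
  w <- if (average == "macro") {
    rep(1 / nrow(cm), nrow(cm))
  } else {
    rowSums(cm) / total
  }
  list(accuracy = sum(tp) / total,
       precision = sum(w * prec),
       recall = sum(w * rec))
}

#' Stratified cross-validated evaluation
#'
#' For each fold the model factory is trained on the fold's training part
#' (any scaler fitting happens inside the factory's model, so no leakage) and
#' evaluated on its validation part. Metrics are summarised as mean and
#' population standard deviation (ddof = 0) over folds.
#'
#' @param model_factory `function(train, kb, seed)` returning a fitted model
#'   whose `predict(., data, type = "label")` yields labels.
#' @param data a `crop_dataset`.
#' @param kb a [crop_kb] or `NULL`, forwarded to the factory.
#' @param folds a `fold_plan` over `data`; defaults to 5 stratified folds
#'   under seed 42.
#' @param average metric averaging convention (see [metrics]).
#' @return object of class `cv_report`: per-fold metrics data.frame, `mean`
#'   and `sd` per metric, and provenance (k, seed, kb hash).
#' @export
cross_validate <- function(model_factory, data, kb = NULL, folds = NULL,
                           average = "macro") {
  if (is.null(folds)) folds <- make_folds(data$df$label, k = 5, seed = 42)
  if (folds$n != n_samples(data)) {
    stop("fold plan does not match the dataset size", call. = FALSE)
  }
  rows <- vector("list", folds$k)
  for (f in seq_len(folds$k)) {
    fold <- folds$folds[[f]]
    tr <- subset_dataset(data, fold$train)
    va <- subset_dataset(data, fold$validation)
    fold_seed <- (folds$seed %% 2000000L) * 1000L + f
    model <- tryCatch(model_factory(tr, kb, fold_seed),
                      error = function(e) {
                        stop("fold ", f, " failed: ", conditionMessage(e),
                             call. = FALSE)
                      })
    pred <- predict(model, va, type = "label")
    m <- metrics(confusion(va$df$label, pred, data$class_order),
                 average = average)
    rows[[f]] <- data.frame(fold = f, accuracy = m$accuracy,
                            precision = m$precision, recall = m$recall)
  }
  per_fold <- do.call(rbind, rows)
  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  summarise <- function(fun) {
    list(accuracy = fun(per_fold$accuracy),
         precision = fun(per_fold$precision),
         recall = fun(per_fold$recall))
  }
  structure(list(folds = per_fold,
                 mean = summarise(mean),
                 sd = summarise(pop_sd),
                 provenance = list(k = folds$k, seed = folds$seed,
                                   average = average,
                                   sd_convention = "population (ddof = 0)",
                                   kb_hash = if (is.null(kb)) NA_character_
                                             else kb_hash(kb))),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%d-fold CV (seed %d):\n", x$provenance$k, x$provenance$seed))
  for (m in c("accuracy", "precision", "recall")) {
    cat(sprintf("  %-9s %.4f +/- %.4f\n", m, x$mean[[m]], x$sd[[m]]))
  }
  invisible(x)
}

#' Serialise a CV report to JSON
#' @param report a `cv_report`.
#' @param path optional output path; when `NULL` the JSON string is returned.
#' @return the JSON string (invisibly when written to `path`).
#' @export
cv_report_json <- function(report, path = NULL) {
  payload <- list(folds = report$folds, mean = report$mean, sd = report$sd,
                  provenance = report$provenance)
  js <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, na = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write a confusion matrix as CSV (labels in class order)
#' @param cm a `crop_confusion`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_confusion_csv <- function(cm, path) {
  utils::write.csv(as.data.frame(unclass(cm)), path, row.names = TRUE)
  invisible(path)
}
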