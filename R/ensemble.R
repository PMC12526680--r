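BASE_KINDS <- c("random_forest", "extra_trees", "gradient_boosted_trees",
                "pinn")

#' Base-learner specification for the stacking ensemble
#'
#' @param kind one of `"random_forest"`, `"extra_trees"`,
#'   `"gradient_boosted_trees"`, `"pinn"`.
#' @param ... hyperparameters forwarded to the corresponding fit function
#'   ([fit_random_forest], [fit_extra_trees], [fit_gbt], [fit_pinn] via
#'   [pinn_config]).
#' @return object of class `base_spec`.
#' @export
base_spec <- function(kind, ...) {
  kind <- match.arg(kind, BASE_KINDS)
  structure(list(kind = kind, params = list(...)), class = "base_spec")
}

#' The four default base learners of the physics-informed stacking model
#'
#' Random forest, extra-trees and gradient-boosted trees at their tuned
#' defaults plus the physics-informed network. Pass overrides per learner to
#' shrink the fit for quick experiments.
#'
#' @param lambda_physics physics-penalty weight of the PINN base.
#' @param pinn,rf,et,gbt named lists of hyperparameter overrides.
#' @return list of four [base_spec] objects.
#' @export
default_base_specs <- function(lambda_physics = 0.1, pinn = list(),
                               rf = list(), et = list(), gbt = list()) {
  list(
    do.call(base_spec, c(list(kind = "random_forest"), rf)),
    do.call(base_spec, c(list(kind = "extra_trees"), et)),
    do.call(base_spec, c(list(kind = "gradient_boosted_trees"), gbt)),
    do.call(base_spec, c(list(kind = "pinn",
                              lambda_physics = lambda_physics), pinn))
  )
}

#' Fit one base learner
#'
#' @param spec a [base_spec].
#' @param train a `crop_dataset`.
#' @param kb a [crop_kb]; required only for `kind = "pinn"` with a positive
#'   `lambda_physics`.
#' @param seed integer RNG seed (overrides any seed in the spec).
#' @return a fitted model exposing `predict(., data, type = "prob")` over the
#'   training class order.
#' @export
fit_base <- function(spec, train, kb = NULL, seed = 42) {
  stopifnot(inherits(spec, "base_spec"))
  p <- spec$params
  switch(spec$kind,
    random_forest = do.call(fit_random_forest,
                            c(list(train = train, seed = seed), p)),
    extra_trees = do.call(fit_extra_trees,
                          c(list(train = train, seed = seed), p)),
    gradient_boosted_trees = do.call(fit_gbt,
                                     c(list(train = train, seed = seed), p)),
    pinn = {
      cfg <- do.call(pinn_config,
                     c(list(n_classes = length(train$class_order),
                            seed = seed), p))
      fit_pinn(train, kb = kb, config = cfg)
    },
    stop("unknown base learner kind: ", spec$kind, call. = FALSE))
}

#' Out-of-fold meta-feature matrix for stacking
#'
#' For each fold of `folds`, every base learner is fitted on the fold's
#' training part and predicts class probabilities on its validation part, so
#' each training row receives exactly one out-of-fold probability vector per
#' base (no base ever predicts a row it was trained on). The matrix is
#' assembled in original row order with one block of C columns per base.
#'
#' @param specs list of [base_spec] objects.
#' @param train a `crop_dataset`.
#' @param kb a [crop_kb] (needed for pinn bases).
#' @param folds a `fold_plan` over `train`'s rows.
#' @param seed base RNG seed; per-fold fits use `seed * 100 + fold`.
#' @return numeric matrix `n x (B*C)` with a `provenance` attribute recording
#'   the fold plan and base kinds.
#' @export
build_meta_features <- function(specs, train, kb = NULL, folds, seed = 42) {
  stopifnot(length(specs) >= 1, inherits(folds, "fold_plan"))
  if (folds$n != n_samples(train)) {
    stop("fold plan covers ", folds$n, " rows but the dataset has ",
         n_samples(train), call. = FALSE)
  }
  C <- length(train$class_order)
  B <- length(specs)
  M <- matrix(NA_real_, n_samples(train), B * C)
  for (f in seq_len(folds$k)) {
    fold <- folds$folds[[f]]
    tr <- subset_dataset(train, fold$train)
    va <- subset_dataset(train, fold$validation)
    fold_seed <- (seed %% 20000000L) * 100L + f
    for (b in seq_along(specs)) {
      fit <- fit_base(specs[[b]], tr, kb = kb, seed = fold_seed)
      P <- predict(fit, va, type = "prob")
      M[fold$validation, ((b - 1) * C + 1):(b * C)] <- P
    }
  }
  colnames(M) <- unlist(lapply(seq_along(specs), function(b) {
    paste(specs[[b]]$kind, train$class_order, sep = ".")
  }))
  attr(M, "provenance") <- list(k = folds$k, fold_seed = folds$seed,
                                bases = vapply(specs, `[[`, "", "kind"),
                                seed = seed)
  M
}

#' Fit the stacking ensemble
#'
#' Base learners produce out-of-fold class-probability meta-features (see
#' [build_meta_features]); a multinomial logistic regression with L2
#' regularisation (glmnet, `alpha = 0`) is fitted on those against the true
#' labels; finally each base is refitted on the full training set for
#' inference.
#'
#' @param specs list of [base_spec] objects (the four defaults:
#'   [default_base_specs]).
#' @param train a `crop_dataset`.
#' @param kb a [crop_kb] (needed for pinn bases).
#' @param folds a `fold_plan`; defaults to 5 stratified folds under seed 42.
#' @param seed integer RNG seed.
#' @param hard_labels if `TRUE`, meta-features are one-hot argmax labels
#'   instead of probabilities (ablation switch).
#' @param meta_lambda ridge penalty of the meta-learner.
#' @return object of class `crop_stacking`.
#' @export
fit_stacking <- function(specs, train, kb = NULL, folds = NULL, seed = 42,
                         hard_labels = FALSE, meta_lambda = 0.002) {
  if (is.null(folds)) folds <- make_folds(train$df$label, k = 5, seed = 42)
  C <- length(train$class_order)
  M <- build_meta_features(specs, train, kb = kb, folds = folds, seed = seed)
  if (hard_labels) M <- harden_blocks(M, C)
  yf <- factor(train$df$label, levels = train$class_order)
  meta <- glmnet::glmnet(M, yf, family = "multinomial", alpha = 0,
                         lambda = c(0.05, 0.01, meta_lambda),
                         standardize = FALSE)
  bases <- lapply(specs, fit_base, train = train, kb = kb, seed = seed)
  structure(list(bases = bases, specs = specs, meta = meta,
                 meta_lambda = meta_lambda, hard_labels = hard_labels,
                 class_order = train$class_order, fold_plan = folds,
                 kb_hash = if (is.null(kb)) NA_character_ else kb_hash(kb),
                 meta_features = M),
            class = "crop_stacking")
}

harden_blocks <- function(M, C) {
  B <- ncol(M) / C
  for (b in seq_len(B)) {
    cols <- ((b - 1) * C + 1):(b * C)
    block <- M[, cols, drop = FALSE]
    hard <- matrix(0, nrow(M), C)
    hard[cbind(seq_len(nrow(M)), max.col(block, "first"))] <- 1
    M[, cols] <- hard
  }
  M
}

stack_features <- function(object, newdata) {
  C <- length(object$class_order)
  blocks <- lapply(object$bases, predict, newdata = newdata, type = "prob")
  M <- do.call(cbind, blocks)
  if (object$hard_labels) M <- harden_blocks(M, C)
  M
}

#' Predict from a stacking ensemble
#'
#' @param object a `crop_stacking`.
#' @param newdata a `crop_dataset` (or feature matrix).
#' @param type `"label"` (default), `"prob"`, or `"both"`.
#' @param ... unused.
#' @return labels, a probability matrix, or a list with both.
#' @export
predict.crop_stacking <- function(object, newdata,
                                  type = c("label", "prob", "both"), ...) {
  type <- match.arg(type)
  M <- stack_features(object, newdata)
  P <- stats::predict(object$meta, newx = M, s = object$meta_lambda,
                      type = "response")[, , 1]
  if (is.null(dim(P))) P <- matrix(P, nrow = 1,
                                   dimnames = list(NULL, names(P)))
  P <- P[, object$class_order, drop = FALSE]
  labels <- object$class_order[max.col(P, "first")]
  switch(type, label = labels, prob = P,
         both = list(label = labels, prob = P))
}

#' @export
print.crop_stacking <- function(x, ...) {
  cat("Stacking ensemble:", length(x$bases), "base learners (",
      paste(vapply(x$specs, `[[`, "", "kind"), collapse = ", "),
      ") + multinomial logistic meta-learner\n")
  invisible(x)
}
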