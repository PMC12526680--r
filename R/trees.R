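dataset_xy <- function(data) {
  list(X = as.matrix(data$df[, CROP_FEATURES]),
       y0 = encode_labels(data) - 1L,      # 0-based for the C++ core
       class_order = data$class_order)
}

tree_depth_arg <- function(max_depth) {
  if (is.null(max_depth) || !is.finite(max_depth)) 30L else as.integer(max_depth)
}

#' Random-forest crop classifier
#'
#' Bagged CART trees (gini splits, per-node random feature subset). Defaults
#' follow the tuned values reported for this task (116 trees, depth 16,
#' min_samples_split 10); `mtry` defaults to `floor(sqrt(p))`.
#'
#' @param train a `crop_dataset`.
#' @param n_estimators number of trees.
#' @param max_depth maximum tree depth (`NULL` = effectively unlimited).
#' @param min_samples_split minimum node size eligible for splitting.
#' @param mtry features considered per node.
#' @param seed integer RNG seed.
#' @return object of class `crop_forest`.
#' @export
fit_random_forest <- function(train, n_estimators = 116, max_depth = 16,
                              min_samples_split = 10, mtry = NULL,
                              seed = 42) {
  d <- dataset_xy(train)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(d$X))))
  forest <- cpp_fit_forest(d$X, d$y0, length(d$class_order),
                           as.integer(n_estimators), as.integer(mtry),
                           tree_depth_arg(max_depth),
                           as.integer(min_samples_split),
                           TRUE, FALSE, as.integer(seed))
  structure(list(forest = forest, class_order = d$class_order,
                 kind = "random_forest"),
            class = c("crop_forest", "crop_base_model"))
}

#' Extra-trees crop classifier
#'
#' Like the random forest but with no bootstrap and one uniformly random
#' split threshold per candidate feature (extremely randomised trees).
#' Defaults follow the tuned values reported for this task (441 trees,
#' depth 16, min_samples_split 5).
#'
#' @inheritParams fit_random_forest
#' @return object of class `crop_forest`.
#' @export
fit_extra_trees <- function(train, n_estimators = 441, max_depth = 16,
                            min_samples_split = 5, mtry = NULL, seed = 42) {
  d <- dataset_xy(train)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(d$X))))
  forest <- cpp_fit_forest(d$X, d$y0, length(d$class_order),
                           as.integer(n_estimators), as.integer(mtry),
                           tree_depth_arg(max_depth),
                           as.integer(min_samples_split),
                           FALSE, TRUE, as.integer(seed))
  structure(list(forest = forest, class_order = d$class_order,
                 kind = "extra_trees"),
            class = c("crop_forest", "crop_base_model"))
}

#' @export
predict.crop_forest <- function(object, newdata, type = c("prob", "label"),
                                ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "crop_dataset")) {
    as.matrix(newdata$df[, CROP_FEATURES])
  } else as.matrix(newdata)
  P <- cpp_forest_proba(object$forest, X, length(object$class_order))
  colnames(P) <- object$class_order
  if (type == "prob") P else object$class_order[max.col(P, "first")]
}

#' Gradient-boosted-tree crop classifier
#'
#' Second-order boosting with a softmax objective: each round fits one
#' regression tree per class to the gradient/hessian of the multiclass
#' log-loss (leaf value `-G/(H + reg_lambda)`, scaled by the learning rate).
#' Defaults follow the tuned values reported for this task (465 rounds,
#' learning rate 0.064, depth 7).
#'
#' @inheritParams fit_random_forest
#' @param n_estimators boosting rounds.
#' @param learning_rate shrinkage per round.
#' @param subsample fraction of rows sampled (without replacement) per round.
#' @param reg_lambda L2 regularisation on leaf weights.
#' @return object of class `crop_gbt`.
#' @export
fit_gbt <- function(train, n_estimators = 465, learning_rate = 0.064,
                    max_depth = 7, subsample = 1.0, min_samples_split = 2,
                    reg_lambda = 1.0, seed = 42) {
  d <- dataset_xy(train)
  rounds <- cpp_fit_gbt(d$X, d$y0, length(d$class_order),
                        as.integer(n_estimators), learning_rate,
                        tree_depth_arg(max_depth),
                        as.integer(min_samples_split), subsample, reg_lambda,
                        as.integer(seed))
  structure(list(rounds = rounds, class_order = d$class_order,
                 kind = "gradient_boosted_trees"),
            class = c("crop_gbt", "crop_base_model"))
}

#' @export
predict.crop_gbt <- function(object, newdata, type = c("prob", "label"),
                             ...) {
  type <- match.arg(type)
  X <- if (inherits(newdata, "crop_dataset")) {
    as.matrix(newdata$df[, CROP_FEATURES])
  } else as.matrix(newdata)
  P <- cpp_gbt_proba(object$rounds, X, length(object$class_order))
  colnames(P) <- object$class_order
  if (type == "prob") P else object$class_order[max.col(P, "first")]
}
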