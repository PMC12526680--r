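#' PINN network configuration
#'
#' A three-linear-layer ReLU classifier (input -> hidden1 -> hidden2 ->
#' n_classes, softmax output) trained by mini-batch Adam on the composite
#' objective `total = data + lambda_physics * physics`, where `data` is
#' multiclass cross-entropy and `physics` the Gaussian agronomic-suitability
#' penalty (see [physics_loss]).
#'
#' @param n_classes number of crop classes (output width).
#' @param n_features input width (default 7).
#' @param hidden two positive integers, the hidden-layer widths.
#' @param epochs training epochs.
#' @param learning_rate Adam step size.
#' @param batch_size mini-batch size.
#' @param lambda_physics non-negative weight of the physics penalty.
#' @param physics_mode `"all_crops"` (mean penalty over every crop, the
#'   default) or `"true_class"` (penalise only the true crop's probability).
#' @param seed integer seed controlling initialisation and shuffling.
#' @return object of class `pinn_config`.
#' @export
pinn_config <- function(n_classes, n_features = 7, hidden = c(64, 64),
                        epochs = 200, learning_rate = 1e-3, batch_size = 32,
                        lambda_physics = 0.1,
                        physics_mode = c("all_crops", "true_class"),
                        seed = 42) {
  physics_mode <- match.arg(physics_mode)
  if (length(hidden) != 2 || any(hidden < 1)) {
    stop("`hidden` must be two positive integers", call. = FALSE)
  }
  stopifnot(n_classes >= 2, n_features >= 1, epochs >= 1,
            learning_rate > 0, batch_size >= 1, lambda_physics >= 0)
  structure(list(n_features = as.integer(n_features),
                 n_classes = as.integer(n_classes),
                 hidden = as.integer(hidden),
                 epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 lambda_physics = lambda_physics,
                 physics_mode = physics_mode,
                 seed = as.integer(seed)),
            class = "pinn_config")
}

#' Initialise network weights
#'
#' He-scaled Gaussian initialisation (`sd = sqrt(2 / fan_in)`), zero biases;
#' deterministic under `config$seed`.
#'
#' @param config a [pinn_config].
#' @return list with weight matrices `W` and bias vectors `b` per layer.
#' @export
init_pinn <- function(config) {
  dims <- c(config$n_features, config$hidden, config$n_classes)
  set.seed(config$seed)
  W <- vector("list", 3)
  b <- vector("list", 3)
  for (l in 1:3) {
    W[[l]] <- matrix(stats::rnorm(dims[l] * dims[l + 1],
                                  sd = sqrt(2 / dims[l])),
                     nrow = dims[l], ncol = dims[l + 1])
    b[[l]] <- numeric(dims[l + 1])
  }
  list(W = W, b = b)
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

add_bias <- function(Z, b) sweep(Z, 2, b, "+")

pinn_forward_full <- function(state, X) {
  Z1 <- add_bias(X %*% state$W[[1]], state$b[[1]]); A1 <- pmax(Z1, 0)
  Z2 <- add_bias(A1 %*% state$W[[2]], state$b[[2]]); A2 <- pmax(Z2, 0)
  Z3 <- add_bias(A2 %*% state$W[[3]], state$b[[3]])
  list(Z1 = Z1, A1 = A1, Z2 = Z2, A2 = A2, Z3 = Z3, P = softmax_rows(Z3))
}

#' Forward pass: class probabilities per row
#' @param state a weight list from [init_pinn] (or a fitted model's weights).
#' @param X numeric matrix of scaled features, one sample per row.
#' @return matrix of class probabilities (rows sum to 1).
#' @export
pinn_forward <- function(state, X) {
  X <- as.matrix(X)
  if (ncol(X) != nrow(state$W[[1]])) {
    stop("feature width mismatch: network expects ", nrow(state$W[[1]]),
         ", got ", ncol(X), call. = FALSE)
  }
  pinn_forward_full(state, X)$P
}

#' Cross-entropy data loss
#'
#' `-(1/N) sum_i sum_c y_ic log(p_ic)` with probabilities clipped to
#' `[1e-12, 1]` before the log.
#'
#' @param probs matrix of predicted class probabilities (N x C).
#' @param y integer class indices in `1..C`, or an N x C one-hot matrix.
#' @return non-negative scalar.
#' @export
cross_entropy_loss <- function(probs, y) {
  probs <- as.matrix(probs)
  if (is.matrix(y)) {
    if (!all(dim(y) == dim(probs))) {
      stop("probability and label batches have different shapes",
           call. = FALSE)
    }
    p_true <- rowSums(probs * y)
  } else {
    if (length(y) != nrow(probs)) {
      stop("probability and label batches have different sizes",
           call. = FALSE)
    }
    p_true <- probs[cbind(seq_len(nrow(probs)), y)]
  }
  -mean(log(pmax(p_true, 1e-12)))
}

#' Physics-informed penalty
#'
#' For sample i and crop c the per-pair penalty is
#' `1 - p_ic * temp_score_c(temp_i) * ph_score_c(ph_i)`: the model is
#' penalised for withholding probability from crops whose temperature/pH
#' optima match the sample. In `"all_crops"` mode the loss is the mean of the
#' penalty over all samples and crops (bounded in \[0, 1\]); in
#' `"true_class"` mode only the true crop's penalty enters, averaged over
#' samples. Scores are computed on raw physical units.
#'
#' @param probs N x C matrix of class probabilities, columns in `class_order`.
#' @param raw_temp,raw_ph numeric vectors of length N (physical units).
#' @param kb a [crop_kb] covering `class_order`.
#' @param class_order the label ordering of the probability columns.
#' @param mode `"all_crops"` or `"true_class"`.
#' @param y integer true-class indices (required for `"true_class"`).
#' @param suitability optional precomputed N x C score matrix (overrides kb).
#' @return scalar in \[0, 1\].
#' @export
physics_loss <- function(probs, raw_temp, raw_ph, kb,
                         class_order = colnames(probs),
                         mode = "all_crops", y = NULL, suitability = NULL) {
  probs <- as.matrix(probs)
  if (is.null(suitability)) {
    cov <- validate_coverage(kb, class_order)
    if (!cov$ok) {
      stop("knowledge base does not cover: ",
           paste(cov$uncovered, collapse = ", "), call. = FALSE)
    }
    S <- kb_suitability(kb, raw_temp, raw_ph)[, class_order, drop = FALSE]
  } else {
    S <- suitability
  }
  if (!all(dim(S) == dim(probs))) {
    stop("suitability and probability shapes differ", call. = FALSE)
  }
  if (mode == "all_crops") {
    mean(1 - probs * S)
  } else {
    if (is.null(y)) stop("`y` required for true_class mode", call. = FALSE)
    mean(1 - probs[cbind(seq_len(nrow(probs)), y)] *
           S[cbind(seq_len(nrow(S)), y)])
  }
}

#' Compose the total training loss
#' @param data_loss cross-entropy term.
#' @param physics_loss physics penalty term.
#' @param lambda_physics non-negative weight.
#' @return object of class `loss_breakdown` with fields `data_loss`,
#'   `physics_loss`, `lambda_physics`, `total_loss`.
#' @export
total_loss <- function(data_loss, physics_loss, lambda_physics) {
  stopifnot(lambda_physics >= 0)
  structure(list(data_loss = data_loss, physics_loss = physics_loss,
                 lambda_physics = lambda_physics,
                 total_loss = data_loss + lambda_physics * physics_loss),
            class = "loss_breakdown")
}

adam_new <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(param, grad, st, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^t)
  vhat <- st$v / (1 - beta2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = st)
}

#' Train the physics-informed classifier
#'
#' Fits its own MinMax scaler on `train` (network inputs are scaled; the
#' physics penalty always consumes raw temperature/pH), then minimises
#' `cross-entropy + lambda_physics * physics` by mini-batch Adam.
#' Deterministic for a fixed `config$seed` (fixed initialisation and shuffle
#' order). With `kb = NULL` the model is a plain cross-entropy network that
#' consumes the identical random stream, so a `lambda_physics = 0` run and a
#' physics-free run are bit-compatible.
#'
#' @param train a `crop_dataset`.
#' @param kb a [crop_kb] covering the training labels, or `NULL` for a
#'   physics-free network.
#' @param config a [pinn_config]; `n_classes` must match the dataset.
#' @param allow_uncovered if `TRUE`, crops missing from the kb receive a
#'   neutral suitability of 1 (no penalty) instead of an error. Off by
#'   default: silent no-penalty classes would fake physics coverage.
#' @return object of class `crop_pinn` with weights, config, class order,
#'   scaler, kb hash and the per-epoch `history` data.frame of
#'   (data_loss, physics_loss, lambda_physics, total_loss).
#' @export
fit_pinn <- function(train, kb = NULL, config = NULL,
                     allow_uncovered = FALSE) {
  stopifnot(inherits(train, "crop_dataset"))
  if (is.null(config)) config <- pinn_config(length(train$class_order))
  if (config$n_classes != length(train$class_order)) {
    stop("config$n_classes (", config$n_classes,
         ") does not match the dataset (", length(train$class_order), ")",
         call. = FALSE)
  }
  scaler <- fit_scaler(train)
  sc <- apply_scaler(scaler, train)
  X <- sc$X
  y <- sc$y
  n <- nrow(X)
  C <- config$n_classes
  Y <- matrix(0, n, C)
  Y[cbind(seq_len(n), y)] <- 1

  use_physics <- !is.null(kb)
  S <- NULL
  if (use_physics) {
    cov <- validate_coverage(kb, train$class_order)
    if (!cov$ok && !allow_uncovered) {
      stop("knowledge base does not cover crop(s): ",
           paste(cov$uncovered, collapse = ", "),
           "; supply entries or set allow_uncovered = TRUE", call. = FALSE)
    }
    covered <- intersect(train$class_order, kb$class_order)
    S <- matrix(1, n, C, dimnames = list(NULL, train$class_order))
    if (length(covered) > 0) {
      S[, covered] <- kb_suitability(kb, sc$raw_temp,
                                     sc$raw_ph)[, covered, drop = FALSE]
    }
  }

  state <- init_pinn(config)
  opt <- list(W = adam_new(state$W), b = adam_new(state$b))
  lam <- config$lambda_physics
  apply_physics_grad <- use_physics && lam > 0
  t_step <- 0L
  history <- vector("list", config$epochs)

  for (epoch in seq_len(config$epochs)) {
    perm <- sample(n)
    starts <- seq(1, n, by = config$batch_size)
    for (s in starts) {
      idx <- perm[s:min(s + config$batch_size - 1, n)]
      B <- length(idx)
      Xb <- X[idx, , drop = FALSE]
      Yb <- Y[idx, , drop = FALSE]
      fw <- pinn_forward_full(state, Xb)
      dZ3 <- (fw$P - Yb) / B
      if (apply_physics_grad) {
        D <- if (config$physics_mode == "all_crops") {
          -S[idx, , drop = FALSE] / (B * C)
        } else {
          -(Yb * S[idx, , drop = FALSE]) / B
        }
        dZ3 <- dZ3 + lam * fw$P * (D - rowSums(D * fw$P))
      }
      dW3 <- crossprod(fw$A2, dZ3); db3 <- colSums(dZ3)
      dA2 <- tcrossprod(dZ3, state$W[[3]]); dZ2 <- dA2 * (fw$Z2 > 0)
      dW2 <- crossprod(fw$A1, dZ2); db2 <- colSums(dZ2)
      dA1 <- tcrossprod(dZ2, state$W[[2]]); dZ1 <- dA1 * (fw$Z1 > 0)
      dW1 <- crossprod(Xb, dZ1); db1 <- colSums(dZ1)

      t_step <- t_step + 1L
      gW <- list(dW1, dW2, dW3); gb <- list(db1, db2, db3)
      for (l in 1:3) {
        up <- adam_step(state$W[[l]], gW[[l]], opt$W[[l]],
                        config$learning_rate, t_step)
        state$W[[l]] <- up$param; opt$W[[l]] <- up$state
        up <- adam_step(state$b[[l]], gb[[l]], opt$b[[l]],
                        config$learning_rate, t_step)
        state$b[[l]] <- up$param; opt$b[[l]] <- up$state
      }
    }
    P_full <- pinn_forward(state, X)
    d_l <- cross_entropy_loss(P_full, y)
    p_l <- if (use_physics) {
      physics_loss(P_full, sc$raw_temp, sc$raw_ph, kb,
                   class_order = train$class_order,
                   mode = config$physics_mode, y = y, suitability = S)
    } else NA_real_
    tl <- d_l + if (use_physics) lam * p_l else 0
    if (!is.finite(tl)) {
      stop("training diverged at epoch ", epoch, " (total loss = ", tl, ")",
           call. = FALSE)
    }
    history[[epoch]] <- data.frame(epoch = epoch, data_loss = d_l,
                                   physics_loss = p_l, lambda_physics = lam,
                                   total_loss = tl)
  }

  structure(list(weights = state, config = config,
                 class_order = train$class_order, scaler = scaler,
                 kb_hash = if (use_physics) kb_hash(kb) else NA_character_,
                 physics_informed = use_physics,
                 history = do.call(rbind, history)),
            class = "crop_pinn")
}

#' @export
print.crop_pinn <- function(x, ...) {
  cat("Physics-informed network:",
      paste(c(x$config$n_features, x$config$hidden, x$config$n_classes),
            collapse = " -> "), "\n")
  cat("  lambda_physics:", x$config$lambda_physics,
      if (!x$physics_informed) "(physics-free)", "\n")
  cat("  final total loss:",
      format(utils::tail(x$history$total_loss, 1), digits = 6), "\n")
  invisible(x)
}

#' Predict class probabilities or labels from a fitted PINN
#'
#' @param object a `crop_pinn`.
#' @param newdata a `crop_dataset` or raw feature matrix (physical units);
#'   scaling uses the scaler fitted at training time.
#' @param type `"prob"` for the probability matrix, `"label"` for argmax
#'   labels.
#' @param ... unused.
#' @return probability matrix (columns = `class_order`) or character labels.
#' @export
predict.crop_pinn <- function(object, newdata, type = c("prob", "label"),
                              ...) {
  type <- match.arg(type)
  sc <- apply_scaler(object$scaler, newdata)
  P <- pinn_forward(object$weights, sc$X)
  colnames(P) <- object$class_order
  if (type == "prob") P else object$class_order[max.col(P, "first")]
}
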