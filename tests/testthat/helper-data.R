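# Shared fixtures, all generated in code.

toy_kb <- function(n_classes = 3, seed = 7) {
  make_default_knowledge_base(n_classes, seed)
}

# well-separated small dataset for model sanity checks
toy_data <- function(n_classes = 3, samples_per_class = 30, separation = 6,
                     noise_scale = 0.5, physics_fidelity = 1, seed = 1,
                     kb = NULL) {
  generate_crops(synthetic_config(n_classes = n_classes,
                                  samples_per_class = samples_per_class,
                                  separation = separation,
                                  noise_scale = noise_scale,
                                  physics_fidelity = physics_fidelity,
                                  seed = seed),
                 kb = kb)
}

small_pinn_config <- function(n_classes, epochs = 30, ...) {
  pinn_config(n_classes, hidden = c(16, 16), epochs = epochs,
              batch_size = 16, ...)
}

# light base specs so ensemble tests stay fast
light_specs <- function(lambda_physics = 0.1) {
  default_base_specs(
    lambda_physics = lambda_physics,
    rf = list(n_estimators = 30),
    et = list(n_estimators = 40),
    gbt = list(n_estimators = 15, learning_rate = 0.3, max_depth = 4),
    pinn = list(hidden = c(16, 16), epochs = 25, batch_size = 16))
}

# independent oracle: nearest-centroid classifier on raw features
nearest_centroid_predict <- function(train, test) {
  Xtr <- as.matrix(train$df[, agripinn:::CROP_FEATURES])
  Xte <- as.matrix(test$df[, agripinn:::CROP_FEATURES])
  centroids <- do.call(rbind, lapply(split(seq_len(nrow(Xtr)),
                                           train$df$label),
                                     function(i) colMeans(Xtr[i, , drop = FALSE])))
  d <- outer(rowSums(Xte^2), rep(1, nrow(centroids))) -
    2 * Xte %*% t(centroids) +
    outer(rep(1, nrow(Xte)), rowSums(centroids^2))
  rownames(centroids)[max.col(-d, "first")]
}

# independent oracle: per-sample per-crop double loop for the physics penalty
physics_loss_naive <- function(probs, temp, ph, kb, class_order,
                               mode = "all_crops", y = NULL) {
  n <- nrow(probs); C <- ncol(probs)
  total <- 0
  for (i in seq_len(n)) {
    if (mode == "all_crops") {
      acc <- 0
      for (c in seq_len(C)) {
        e <- kb$entries[match(class_order[c], kb$entries$label), ]
        sc <- physics_scores(temp[i], ph[i], e)
        acc <- acc + (1 - probs[i, c] * sc$temp_score * sc$ph_score)
      }
      total <- total + acc / C
    } else {
      e <- kb$entries[match(class_order[y[i]], kb$entries$label), ]
      sc <- physics_scores(temp[i], ph[i], e)
      total <- total + (1 - probs[i, y[i]] * sc$temp_score * sc$ph_score)
    }
  }
  total / n
}

# independent oracle: one-vs-rest TP/TN/FP/FN metrics from a confusion matrix
metrics_naive <- function(cm) {
  C <- nrow(cm); total <- sum(cm)
  prec <- rec <- numeric(C)
  for (c in seq_len(C)) {
    tp <- cm[c, c]
    fp <- sum(cm[-c, c])
    fn <- sum(cm[c, -c])
    prec[c] <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec[c] <- if (tp + fn == 0) 0 else tp / (tp + fn)
  }
  list(accuracy = sum(diag(cm)) / total,
       precision = mean(prec), recall = mean(rec))
}

random_probs <- function(n, C) {
  P <- matrix(stats::rexp(n * C), n, C)
  P / rowSums(P)
}
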