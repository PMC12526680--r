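test_that("init_pinn builds the declared layer shapes deterministically", {
  cfg <- pinn_config(n_classes = 22, n_features = 7, hidden = c(64, 64),
                     seed = 11)
  st <- init_pinn(cfg)
  expect_equal(dim(st$W[[1]]), c(7, 64))
  expect_equal(dim(st$W[[2]]), c(64, 64))
  expect_equal(dim(st$W[[3]]), c(64, 22))
  expect_identical(init_pinn(cfg), st)
  expect_error(pinn_config(n_classes = 3, hidden = c(0, 8)), "positive")
})

test_that("forward pass yields row-stochastic, order-preserving output", {
  cfg <- pinn_config(n_classes = 5, n_features = 7, hidden = c(8, 8),
                     seed = 2)
  st <- init_pinn(cfg)
  X <- matrix(rnorm(70), 10, 7)
  P <- pinn_forward(st, X)
  expect_equal(rowSums(P), rep(1, 10), tolerance = 1e-6)
  expect_true(all(P >= 0))
  perm <- sample(10)
  expect_equal(pinn_forward(st, X[perm, ]), P[perm, ], tolerance = 1e-12)
  # zero final layer => uniform 1/C
  st$W[[3]][] <- 0; st$b[[3]][] <- 0
  expect_equal(pinn_forward(st, X), matrix(1 / 5, 10, 5), tolerance = 1e-12)
  expect_error(pinn_forward(st, X[, 1:3]), "width mismatch")
})

test_that("cross-entropy matches closed forms", {
  C <- 22; n <- 10
  uniform <- matrix(1 / C, n, C)
  expect_equal(cross_entropy_loss(uniform, rep(1L, n)), log(22),
               tolerance = 1e-10)
  half <- matrix((1 - 0.5) / (C - 1), n, C); half[, 3] <- 0.5
  expect_equal(cross_entropy_loss(half, rep(3L, n)), log(2),
               tolerance = 1e-10)
  onehot <- matrix(0, n, C); onehot[, 5] <- 1
  expect_lt(cross_entropy_loss(onehot, rep(5L, n)), 1e-9)
  expect_gte(cross_entropy_loss(onehot, rep(5L, n)), 0)
  # one-hot label matrix input is equivalent to indices
  Y <- matrix(0, n, C); Y[cbind(1:n, rep(3L, n))] <- 1
  expect_equal(cross_entropy_loss(half, Y),
               cross_entropy_loss(half, rep(3L, n)))
  expect_error(cross_entropy_loss(uniform, rep(1L, n + 1)), "batch")
})

test_that("physics penalty matches closed forms and stays in [0,1]", {
  kb <- crop_kb(data.frame(label = "rice", mu_temp = 25, sigma_temp = 3,
                           mu_ph = 6, sigma_ph = 0.5))
  # p = 1 at both optima -> zero penalty
  expect_equal(physics_loss(matrix(1, 1, 1), 25, 6, kb, "rice"), 0,
               tolerance = 1e-12)
  # p = 0 -> penalty 1 regardless of the scores
  expect_equal(physics_loss(matrix(0, 1, 1), 25, 6, kb, "rice"), 1,
               tolerance = 1e-12)
  # p = 1 at (mu_T + sigma_T, mu_pH + sigma_pH) -> 1 - e^{-1}
  expect_equal(physics_loss(matrix(1, 1, 1), 28, 6.5, kb, "rice"),
               1 - exp(-1), tolerance = 1e-10)
  # boundedness for arbitrary probabilities
  kb4 <- toy_kb(4, seed = 5)
  set.seed(1)
  P <- random_probs(50, 4)
  v <- physics_loss(P, runif(50, 0, 45), runif(50, 3, 10), kb4,
                    kb4$class_order)
  expect_gte(v, 0); expect_lte(v, 1)
})

test_that("batched physics penalty equals the naive double loop", {
  kb <- toy_kb(5, seed = 8)
  set.seed(99)
  for (rep in 1:10) {
    n <- sample(2:12, 1)
    P <- random_probs(n, 5)
    temp <- runif(n, 5, 45); ph <- runif(n, 3, 10)
    y <- sample(5, n, replace = TRUE)
    expect_equal(physics_loss(P, temp, ph, kb, kb$class_order),
                 physics_loss_naive(P, temp, ph, kb, kb$class_order),
                 tolerance = 1e-8)
    expect_equal(physics_loss(P, temp, ph, kb, kb$class_order,
                              mode = "true_class", y = y),
                 physics_loss_naive(P, temp, ph, kb, kb$class_order,
                                    mode = "true_class", y = y),
                 tolerance = 1e-8)
  }
})

test_that("total_loss is the weighted sum, recorded field by field", {
  lb <- total_loss(1.0, 0.5, 0)
  expect_equal(lb$total_loss, 1.0)
  expect_equal(total_loss(1.0, 0.5, 2)$total_loss, 2.0)
  expect_equal(total_loss(0, 0, 7)$total_loss, 0)
  expect_equal(lb$lambda_physics, 0)
  expect_error(total_loss(1, 1, -1), "lambda_physics")
})

test_that("physics gradient pulls probability toward suitable crops", {
  # frozen uniform probabilities: d physics / d p_ic = -S_ic / (n*C),
  # checked by central finite differences on the loss itself
  kb <- toy_kb(3, seed = 4)
  n <- 4; C <- 3
  temp <- c(20, 25, 30, 22); ph <- c(6, 6.5, 7, 5.5)
  S <- kb_suitability(kb, temp, ph)
  P <- matrix(1 / C, n, C)
  eps <- 1e-6
  for (i in 1:n) for (c in 1:C) {
    Pp <- P; Pp[i, c] <- P[i, c] + eps
    Pm <- P; Pm[i, c] <- P[i, c] - eps
    fd <- (physics_loss(Pp, temp, ph, kb, kb$class_order) -
             physics_loss(Pm, temp, ph, kb, kb$class_order)) / (2 * eps)
    expect_lt(abs(fd - (-S[i, c] / (n * C))), 1e-8)
  }
  # more suitable crops get the (more negative) steeper descent direction
  grad <- -S / (n * C)
  expect_equal(apply(grad, 1, which.min), apply(S, 1, which.max))
})

test_that("lambda = 0 training is bit-compatible with a physics-free net", {
  kb <- toy_kb(3, seed = 3)
  ds <- toy_data(n_classes = 3, samples_per_class = 20, seed = 3, kb = kb)
  cfg <- small_pinn_config(3, epochs = 10, lambda_physics = 0, seed = 7)
  with_kb <- fit_pinn(ds, kb = kb, config = cfg)
  without <- fit_pinn(ds, kb = NULL, config = cfg)
  expect_equal(with_kb$history$data_loss, without$history$data_loss,
               tolerance = 1e-8)
  expect_equal(with_kb$history$total_loss, without$history$total_loss,
               tolerance = 1e-8)
  expect_identical(with_kb$weights, without$weights)
  expect_identical(predict(with_kb, ds), predict(without, ds))
})

test_that("training fits separable data and logs a consistent history", {
  kb <- toy_kb(3, seed = 1)
  ds <- toy_data(n_classes = 3, samples_per_class = 40, separation = 6,
                 noise_scale = 0.5, seed = 1, kb = kb)
  cfg <- small_pinn_config(3, epochs = 60, lambda_physics = 0.1, seed = 42)
  fit <- fit_pinn(ds, kb = kb, config = cfg)
  expect_true(all(is.finite(fit$history$total_loss)))
  # loss identity at every logged epoch
  expect_equal(fit$history$total_loss,
               fit$history$data_loss + 0.1 * fit$history$physics_loss,
               tolerance = 1e-10)
  acc <- mean(predict(fit, ds, type = "label") == ds$df$label)
  expect_gte(acc, 0.99)
  # determinism of refits and predictions
  expect_identical(fit_pinn(ds, kb = kb, config = cfg)$weights, fit$weights)
  P <- predict(fit, ds)
  expect_identical(predict(fit, ds), P)
  expect_equal(rowSums(P), rep(1, n_samples(ds)), tolerance = 1e-6)
  expect_identical(ds$class_order[max.col(P, "first")],
                   predict(fit, ds, type = "label"))
})

test_that("kb coverage is enforced unless the neutral fallback is enabled", {
  ds <- toy_data(n_classes = 3, samples_per_class = 10, seed = 2)
  kb2 <- crop_kb(toy_kb(3)$entries[1:2, ])
  cfg <- small_pinn_config(3, epochs = 2)
  expect_error(fit_pinn(ds, kb = kb2, config = cfg), "does not cover")
  expect_s3_class(fit_pinn(ds, kb = kb2, config = cfg,
                           allow_uncovered = TRUE), "crop_pinn")
})
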