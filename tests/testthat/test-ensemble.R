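kb_ens <- toy_kb(3, seed = 21)
ds_ens <- toy_data(n_classes = 3, samples_per_class = 30, separation = 6,
                   noise_scale = 0.5, seed = 21, kb = kb_ens)
folds_ens <- make_folds(ds_ens$df$label, k = 3, seed = 42)

test_that("base_spec validates kinds and fit_base dispatches all four", {
  expect_error(base_spec("boosted_stumps"), "arg")
  for (spec in light_specs()) {
    fit <- fit_base(spec, ds_ens, kb = kb_ens, seed = 4)
    P <- predict(fit, ds_ens, type = "prob")
    expect_equal(dim(P), c(90L, 3L))
    expect_equal(rowSums(P), rep(1, 90), tolerance = 1e-6)
    expect_identical(predict(fit_base(spec, ds_ens, kb = kb_ens, seed = 4),
                             ds_ens, type = "prob"), P)
  }
})

test_that("a lambda=0 pinn base behaves as a plain network base", {
  spec0 <- base_spec("pinn", hidden = c(16, 16), epochs = 10,
                     lambda_physics = 0)
  with_kb <- fit_base(spec0, ds_ens, kb = kb_ens, seed = 9)
  plain <- fit_pinn(ds_ens, kb = NULL,
                    config = pinn_config(3, hidden = c(16, 16), epochs = 10,
                                         lambda_physics = 0, seed = 9))
  expect_identical(with_kb$weights, plain$weights)
})

test_that("meta-feature matrix has B*C row-stochastic blocks, no leakage", {
  specs1 <- light_specs()[1]
  M1 <- build_meta_features(specs1, ds_ens, kb = kb_ens, folds = folds_ens)
  expect_equal(dim(M1), c(90L, 3L))
  expect_equal(rowSums(M1), rep(1, 90), tolerance = 1e-6)

  specs4 <- light_specs()
  M4 <- build_meta_features(specs4, ds_ens, kb = kb_ens, folds = folds_ens)
  expect_equal(ncol(M4), 4 * 3)
  expect_false(anyNA(M4))
  for (b in 1:4) {
    block <- M4[, ((b - 1) * 3 + 1):(b * 3)]
    expect_equal(rowSums(block), rep(1, 90), tolerance = 1e-6)
  }
  prov <- attr(M4, "provenance")
  expect_equal(prov$k, 3)
  expect_equal(prov$bases, vapply(specs4, `[[`, "", "kind"))
})

test_that("meta features are equivariant under row permutation", {
  set.seed(77)
  perm <- sample(n_samples(ds_ens))
  ds_perm <- subset_dataset(ds_ens, perm)
  # carry the same fold plan through the permutation so fold contents match
  inv <- match(seq_along(perm), perm)
  folds_perm <- folds_ens
  folds_perm$folds <- lapply(folds_ens$folds, function(f) {
    list(train = sort(inv[f$train]), validation = sort(inv[f$validation]))
  })
  # exact-greedy boosting without subsampling is invariant to row order, so
  # it isolates the meta-feature assembly (indexing) from sampler effects
  specs <- light_specs()[3]
  M <- build_meta_features(specs, ds_ens, kb = kb_ens, folds = folds_ens)
  Mp <- build_meta_features(specs, ds_perm, kb = kb_ens, folds = folds_perm)
  expect_equal(Mp[inv[seq_along(perm)], ], M, ignore_attr = TRUE,
               tolerance = 1e-12)
})

test_that("stacking fits, predicts coherently and beats no one unfairly", {
  model <- fit_stacking(light_specs(), ds_ens, kb = kb_ens,
                        folds = folds_ens, seed = 5)
  both <- predict(model, ds_ens, type = "both")
  expect_equal(rowSums(both$prob), rep(1, 90), tolerance = 1e-6)
  expect_identical(both$label,
                   ds_ens$class_order[max.col(both$prob, "first")])
  expect_true(all(both$label %in% ds_ens$class_order))
  expect_identical(predict(model, ds_ens, type = "label"), both$label)
  acc <- mean(both$label == ds_ens$df$label)
  expect_gte(acc, 0.95)

  # single-base stacking reproduces that base's argmax on separable data
  single <- fit_stacking(light_specs()[1], ds_ens, kb = kb_ens,
                         folds = folds_ens, seed = 5)
  base_fit <- fit_base(light_specs()[[1]], ds_ens, kb = kb_ens, seed = 5)
  agree <- mean(predict(single, ds_ens, type = "label") ==
                  predict(base_fit, ds_ens, type = "label"))
  expect_gte(agree, 0.97)

  hard <- fit_stacking(light_specs()[c(1, 2)], ds_ens, kb = kb_ens,
                       folds = folds_ens, seed = 5, hard_labels = TRUE)
  expect_true(all(predict(hard, ds_ens, type = "label") %in%
                    ds_ens$class_order))
})

test_that("models round-trip through the versioned serialization", {
  model <- fit_stacking(light_specs()[c(1, 4)], ds_ens, kb = kb_ens,
                        folds = folds_ens, seed = 2)
  path <- tempfile(fileext = ".rds")
  save_crop_model(model, path)
  back <- load_crop_model(path)
  expect_identical(predict(back, ds_ens, type = "prob"),
                   predict(model, ds_ens, type = "prob"))
  prov <- attr(back, "provenance")
  expect_equal(prov$format, "agripinn_model")
  expect_equal(prov$model_class, "crop_stacking")
  expect_false(is.na(prov$kb_hash))

  pf <- fit_pinn(ds_ens, kb = kb_ens, config = small_pinn_config(3, epochs = 5))
  save_crop_model(pf, path)
  expect_identical(predict(load_crop_model(path), ds_ens),
                   predict(pf, ds_ens))
  # wrong file type is rejected
  saveRDS(list(a = 1), path)
  expect_error(load_crop_model(path), "not an agripinn model")
})
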