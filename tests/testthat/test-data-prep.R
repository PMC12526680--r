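write_toy_csv <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE)
  path
}

toy_df <- function(n = 4) {
  data.frame(N = seq(10, by = 5, length.out = n), P = 20, K = 30,
             temperature = 25, humidity = 60, ph = 6.5, rainfall = 100,
             label = rep(c("rice", "maize"), length.out = n))
}

test_that("read_samples parses the canonical CSV schema", {
  path <- write_toy_csv(toy_df(4))
  ds <- read_samples(path)
  expect_s3_class(ds, "crop_dataset")
  expect_equal(n_samples(ds), 4)
  expect_equal(ds$class_order, c("maize", "rice"))
  # case-insensitive headers
  df <- toy_df(2); names(df) <- toupper(names(df))
  ds2 <- read_samples(write_toy_csv(df))
  expect_equal(n_samples(ds2), 2)
})

test_that("read_samples rejects bad input with context", {
  df <- toy_df(4)
  expect_error(read_samples(write_toy_csv(df[, -7])), "rainfall")
  df_bad <- toy_df(4); df_bad$ph[3] <- 15
  expect_error(read_samples(write_toy_csv(df_bad)), "ph.*row 3|row 3")
  df_chr <- toy_df(2); df_chr$N <- c("x", "y")
  expect_error(read_samples(write_toy_csv(df_chr)), "N")
  empty <- tempfile(fileext = ".csv")
  writeLines("N,P,K,temperature,humidity,ph,rainfall,label", empty)
  expect_error(read_samples(empty), "empty")
})

test_that("MinMax scaler maps train to [0,1], extrapolates out of range", {
  M <- cbind(a = c(10, 20, 30), b = c(7, 7, 7))
  sc <- fit_scaler(M)
  tr <- apply_scaler(sc, M)
  expect_equal(tr$X[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(tr$X[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  expect_equal(sc$min[["a"]], 10)
  expect_equal(sc$max[["a"]], 30)

  ds <- crop_dataset(toy_df(3))
  sc7 <- fit_scaler(ds)
  out <- apply_scaler(sc7, ds)
  expect_true(all(out$X >= 0 & out$X <= 1))
  # constant features transform to 0 by convention
  expect_true(all(out$X[, "P"] == 0))
  # midpoint and endpoints on the varying N column (10, 15, 20)
  expect_equal(out$X[, "N"], c(0, 0.5, 1), ignore_attr = TRUE)
  # raw physics carriers are bit-identical passthroughs
  expect_identical(out$raw_temp, ds$df$temperature,
                   ignore_attr = TRUE)
  expect_identical(as.numeric(out$raw_ph), ds$df$ph)

  # held-out value outside the train range scales outside [0,1]
  ds2 <- crop_dataset(within(toy_df(1), N <- 40))
  out2 <- apply_scaler(sc7, ds2)
  expect_equal(out2$X[, "N"], 3, ignore_attr = TRUE)  # (40-10)/(20-10)
  expect_error(apply_scaler(sc7, matrix(1, 2, 3)), "mismatch")
})

test_that("stratified split is exact, seeded and reproducible", {
  ds <- toy_data(n_classes = 2, samples_per_class = 100, seed = 5)
  sp <- split_train_test(ds, test_fraction = 0.2, seed = 42)
  expect_equal(unname(table(sp$train$df$label)), c(80L, 80L),
               ignore_attr = TRUE)
  expect_equal(unname(table(sp$test$df$label)), c(20L, 20L),
               ignore_attr = TRUE)
  sp2 <- split_train_test(ds, test_fraction = 0.2, seed = 42)
  expect_identical(sp$test_idx, sp2$test_idx)
  sp3 <- split_train_test(ds, test_fraction = 0.2, seed = 43)
  expect_false(identical(sp$test_idx, sp3$test_idx))
  expect_equal(unname(table(sp3$test$df$label)), c(20L, 20L),
               ignore_attr = TRUE)

  single <- crop_dataset(rbind(ds$df, within(ds$df[1, ], label <- "solo")))
  expect_warning(split_train_test(single, seed = 1), "single sample")
})

test_that("stratified folds partition the data with per-class balance <= 1", {
  ds <- toy_data(n_classes = 3, samples_per_class = 20, seed = 2)
  fp <- make_folds(ds$df$label, k = 5, seed = 42)
  all_val <- sort(unlist(lapply(fp$folds, `[[`, "validation")))
  expect_identical(all_val, seq_len(n_samples(ds)))
  for (f in fp$folds) {
    expect_identical(sort(c(f$train, f$validation)), seq_len(n_samples(ds)))
    expect_length(intersect(f$train, f$validation), 0)
  }
  counts <- sapply(fp$folds, function(f) table(ds$df$label[f$validation]))
  expect_true(all(counts == 4))

  # uneven class sizes: brute-force |count_i - count_j| <= 1 check
  labels <- c(rep("a", 101), rep("b", 53), rep("c", 7))
  fp2 <- make_folds(labels, k = 5, seed = 42)
  for (cls in c("a", "b", "c")) {
    per_fold <- vapply(fp2$folds, function(f) {
      sum(labels[f$validation] == cls)
    }, integer(1))
    expect_lte(max(per_fold) - min(per_fold), 1)
  }

  expect_identical(make_folds(ds$df$label, k = 5, seed = 42), fp)
  expect_error(make_folds(c("a", "b"), k = 3), "exceeds")
  expect_error(make_folds(rep("a", 10), k = 1), "at least 2")
  expect_warning(make_folds(c(rep("a", 10), "b"), k = 5), "fewer than k")
})
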