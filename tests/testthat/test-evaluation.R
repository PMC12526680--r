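test_that("confusion counts by class order and rejects unknown labels", {
  cm <- confusion(c("a", "a", "b", "b"), c("a", "b", "b", "b"), c("a", "b"))
  expect_equal(unclass(cm), matrix(c(1L, 0L, 1L, 2L), 2,
                                   dimnames = list(true = c("a", "b"),
                                                   predicted = c("a", "b"))))
  expect_equal(sum(cm), 4)
  perfect <- confusion(c("a", "b", "b"), c("a", "b", "b"), c("a", "b"))
  expect_equal(sum(diag(perfect)), 3)
  expect_equal(sum(perfect) - sum(diag(perfect)), 0)
  expect_error(confusion("a", "z", c("a", "b")), "not in class_order")
  expect_error(confusion(c("a", "a"), "a", c("a", "b")), "length")
})

test_that("metrics match the hand-computed one-vs-rest values", {
  cm <- confusion(c("a", "a", "b", "b"), c("a", "b", "b", "b"), c("a", "b"))
  m <- metrics(cm)
  expect_equal(m$accuracy, 0.75)
  expect_equal(m$precision, (1 / 1 + 2 / 3) / 2, tolerance = 1e-12)
  expect_equal(m$recall, (1 / 2 + 2 / 2) / 2, tolerance = 1e-12)

  diag_cm <- matrix(c(5L, 0L, 0L, 7L), 2)
  md <- metrics(diag_cm)
  expect_equal(unlist(md), c(accuracy = 1, precision = 1, recall = 1))

  all_wrong <- matrix(c(0L, 2L, 2L, 0L), 2)
  expect_equal(metrics(all_wrong)$accuracy, 0)

  # class never predicted -> zero precision denominator: contributes 0, warns
  never_pred <- matrix(c(0L, 0L, 2L, 2L), 2)
  expect_warning(mz <- metrics(never_pred), "zero")
  expect_equal(mz$precision, (0 + 2 / 4) / 2)

  # weighted averaging weights by class support
  m_w <- metrics(cm, average = "weighted")
  expect_equal(m_w$recall, (2 / 4) * (1 / 2) + (2 / 4) * 1)
})

test_that("metrics equal a brute-force per-class computation", {
  set.seed(31)
  for (rep in 1:25) {
    C <- sample(2:6, 1)
    cm <- matrix(rpois(C * C, 3), C)
    if (any(colSums(cm) == 0) || any(rowSums(cm) == 0)) {
      expect_warning(m <- metrics(cm))
    } else {
      m <- metrics(cm)
    }
    expect_equal(unlist(m), unlist(metrics_naive(cm)), tolerance = 1e-12)
  }
})

test_that("macro recall equals mean per-class accuracy on balanced data", {
  set.seed(8)
  for (rep in 1:10) {
    C <- 4; per <- 25
    cm <- matrix(0L, C, C)
    for (r in 1:C) {
      draws <- table(factor(sample(C, per, replace = TRUE), levels = 1:C))
      cm[r, ] <- as.integer(draws)
    }
    if (any(colSums(cm) == 0)) next
    m <- metrics(cm)
    expect_equal(m$recall, mean(diag(cm) / rowSums(cm)), tolerance = 1e-12)
  }
})

constant_factory <- function(label) {
  function(train, kb, seed) {
    structure(list(label = label, class_order = train$class_order),
              class = "constant_model")
  }
}

predict.constant_model <- function(object, newdata, type = "label", ...) {
  rep(object$label, n_samples(newdata))
}
registerS3method("predict", "constant_model", predict.constant_model)

test_that("cross_validate aggregates fold metrics with population sd", {
  ds <- toy_data(n_classes = 4, samples_per_class = 20, seed = 12)
  folds <- make_folds(ds$df$label, k = 5, seed = 42)
  suppressWarnings(
    rep_const <- cross_validate(constant_factory(ds$class_order[1]), ds,
                                folds = folds))
  # balanced classes + exact stratification: every fold scores exactly 1/C
  expect_equal(rep_const$folds$accuracy, rep(0.25, 5))
  expect_equal(rep_const$mean$accuracy, 0.25, tolerance = 1e-12)
  expect_equal(rep_const$sd$accuracy, 0)
  expect_equal(rep_const$mean$accuracy, mean(rep_const$folds$accuracy),
               tolerance = 1e-12)
  expect_equal(rep_const$sd$accuracy,
               sqrt(mean((rep_const$folds$accuracy -
                            mean(rep_const$folds$accuracy))^2)),
               tolerance = 1e-12)

  # identical seeds reproduce the report byte-for-byte
  factory <- function(train, kb, seed) {
    fit_random_forest(train, n_estimators = 15, seed = seed)
  }
  r1 <- cross_validate(factory, ds, folds = folds)
  r2 <- cross_validate(factory, ds, folds = folds)
  expect_identical(cv_report_json(r1), cv_report_json(r2))
  expect_identical(r1$folds, r2$folds)
})

test_that("cross_validate surfaces fold failures with the fold index", {
  ds <- toy_data(n_classes = 3, samples_per_class = 10, seed = 12)
  boom <- function(train, kb, seed) stop("nope")
  expect_error(cross_validate(boom, ds), "fold 1")
})
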