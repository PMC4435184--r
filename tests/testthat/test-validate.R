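test_that("error metrics follow their definitions", {
  T0 <- matrix(c(10, 20, 5, 8, 50, 60), 2)
  expect_equal(error_metric(T0, T0, "rms_relative"), rep(0, 3))
  expect_equal(error_metric(T0, T0, "as_printed"), rep(0, 3))
  expect_equal(error_metric(matrix(10), matrix(9), "rms_relative"), 10)
  expect_equal(error_metric(matrix(10), matrix(9), "as_printed"), 100)

  # brute-force loop oracle on random matrices
  for (seed in 1:5) {
    Tm <- withr::with_seed(seed, matrix(stats::runif(30, 1, 10), 10))
    Y <- withr::with_seed(seed + 99, matrix(stats::runif(30, 1, 10), 10))
    loop_rms <- sapply(1:3, function(j) {
      acc <- 0
      for (i in 1:10) acc <- acc + ((Tm[i, j] - Y[i, j]) / Tm[i, j])^2
      sqrt(acc / 10) * 100
    })
    expect_equal(error_metric(Tm, Y, "rms_relative"), loop_rms,
                 tolerance = 1e-12)
    loop_signed <- sapply(1:3, function(j) mean(Tm[, j] - Y[, j]) * 100)
    expect_equal(error_metric(Tm, Y, "as_printed"), loop_signed,
                 tolerance = 1e-12)
  }

  expect_error(error_metric(T0, T0[1, , drop = FALSE]), "shape")
  expect_error(error_metric(matrix(0), matrix(1), "rms_relative"), "zero")
})

test_that("LOOCV partitions test every record exactly once", {
  d <- toy_dataset(5)
  folds <- loocv_folds(d)
  expect_length(folds, 5)
  tested <- vapply(folds, `[[`, character(1), "test")
  expect_setequal(tested, d$ids)
  expect_false(anyDuplicated(tested) > 0)
  for (f in folds) {
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), d$ids)
  }
})

test_that("hold-out validation never leaks test records", {
  d <- toy_dataset(12)
  cfg <- train_config("SCGA", iterations = 15, seed = 5)
  res <- holdout_validate(d, d$ids[1:3], cfg, repeats = 1)
  expect_equal(res$n_train, 9)
  expect_equal(res$n_test, 3)
  expect_error(holdout_validate(d, d$ids, cfg), "proper subset")
  expect_error(holdout_validate(d, character(0), cfg), "proper subset|unknown")
  expect_error(holdout_validate(d, "nope", cfg), "unknown")
  # scaler fitting sees the training split only: holding out the extreme
  # record leaves it outside the fitted input range
  imax <- which.max(d$inputs[, 1])
  net <- fit_scalers(init_network(0), subset_dataset(d, setdiff(1:12, imax)))
  xs <- palpinv:::scale_channels(d$inputs[imax, , drop = FALSE],
                                 net$input_scaler)
  expect_gt(max(xs), 1)
})

test_that("repeated validation with a fixed seed is reproducible", {
  d <- toy_dataset(10)
  cfg <- train_config("SCGA", iterations = 15, seed = 3)
  r1 <- holdout_validate(d, d$ids[1:2], cfg, repeats = 2)
  r2 <- holdout_validate(d, d$ids[1:2], cfg, repeats = 2)
  expect_equal(r1$test_error, r2$test_error, tolerance = 0)
  expect_equal(r1$seeds, c(3, 4))
})

test_that("training reduces the test error below the untrained network", {
  d <- toy_dataset(16, seed = 77)
  cfg <- train_config("SCGA", iterations = 60, seed = 0)
  test_ids <- d$ids[13:16]
  trained <- holdout_validate(d, test_ids, cfg, repeats = 5)
  untrained <- holdout_validate(d, test_ids,
                                train_config("SCGA", iterations = 1,
                                             seed = 0), repeats = 5)
  expect_lt(mean(trained$test_error), mean(untrained$test_error))
})

test_that("an almost-constant target is learned to near-zero error", {
  X <- withr::with_seed(50, matrix(stats::runif(30), 10, 3,
    dimnames = list(NULL, c("f_max", "f_total", "f_area"))))
  Tm <- cbind(d = 8 + 1e-6 * X[, 1], h = 5 + 1e-6 * X[, 2],
              E = 60 + 1e-6 * X[, 3])
  d <- make_dataset(X, Tm)
  res <- loocv_validate(d, train_config("LMA", iterations = 25, seed = 1),
                        repeats = 1)
  expect_true(all(res$test_error < 0.1))
})

test_that("LOOCV averages its folds and reports the scheme", {
  d <- toy_dataset(6)
  cfg <- train_config("SCGA", iterations = 10, seed = 2)
  res <- loocv_validate(d, cfg, repeats = 1)
  expect_s3_class(res, "validation_result")
  expect_equal(res$folds, 6)
  expect_equal(res$scheme, "LOOCV")
  tab <- as.data.frame(res)
  expect_equal(tab$output, c("size", "depth", "modulus"))
  expect_true(all(tab$test_pct >= 0))
})

test_that("a larger iteration budget does not raise the median train error", {
  d <- toy_dataset(14, seed = 9)
  med <- vapply(c(10, 50, 100), function(it) {
    errs <- vapply(1:5, function(sd) {
      mean(holdout_validate(d, d$ids[13:14],
                            train_config("SCGA", iterations = it, seed = sd),
                            repeats = 1)$train_error)
    }, numeric(1))
    stats::median(errs)
  }, numeric(1))
  expect_true(all(diff(med) <= 1e-9))
})
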