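# Hold-out and leave-one-out validation harnesses and the percent-error
# metrics used to report inversion performance.

#' Per-output percent error between targets and predictions
#'
#' Two modes are reported throughout the package:
#'
#' * `"rms_relative"` (the headline metric): per output, the root mean
#'   square of the relative residual `(T - Y) / T`, times 100.
#' * `"as_printed"`: per output, the plain average of the signed residual
#'   `T - Y`, times 100.  This reproduces the literal form of the
#'   published error formula; because signed residuals cancel, it can be
#'   near zero for an unbiased but inaccurate predictor, so it is reported
#'   for comparability, never as the headline.  Callers pass scaled values
#'   for this mode.
#'
#' @param T Target matrix (records x outputs).
#' @param Y Prediction matrix, same shape.
#' @param mode `"rms_relative"` or `"as_printed"`.
#' @return Numeric vector of per-output errors, %.
#' @export
error_metric <- function(T, Y, mode = c("rms_relative", "as_printed")) {
  mode <- match.arg(mode)
  T <- as.matrix(T)
  Y <- as.matrix(Y)
  if (!all(dim(T) == dim(Y))) stop("T and Y must have identical shape")
  if (mode == "rms_relative") {
    if (any(T == 0)) {
      stop("zero target value: rms_relative error is undefined")
    }
    sqrt(colMeans(((T - Y) / T)^2)) * 100
  } else {
    colMeans(T - Y) * 100
  }
}

new_validation_result <- function(scheme, cfg, repeats, seeds, n_train,
                                  n_test, tr, te, trp, tep, fold_count = NA) {
  structure(
    list(scheme = scheme, algorithm = cfg$algorithm,
         iterations = cfg$iterations, repeats = repeats, seeds = seeds,
         n_train = n_train, n_test = n_test, folds = fold_count,
         train_error = tr, test_error = te,
         train_error_printed = trp, test_error_printed = tep),
    class = "validation_result"
  )
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf("<validation_result> %s / %s, %d iterations, %d repeat(s)\n",
              x$scheme, x$algorithm, x$iterations, x$repeats))
  tab <- rbind(train = x$train_error, test = x$test_error)
  colnames(tab) <- c("size", "depth", "modulus")
  cat("rms-relative error (%):\n")
  print(round(tab, 3))
  invisible(x)
}

#' @export
as.data.frame.validation_result <- function(x, ...) {
  data.frame(
    scheme = x$scheme, algorithm = x$algorithm, iterations = x$iterations,
    output = c("size", "depth", "modulus"),
    train_pct = as.numeric(x$train_error),
    test_pct = as.numeric(x$test_error),
    train_printed_pct = as.numeric(x$train_error_printed),
    test_printed_pct = as.numeric(x$test_error_printed),
    repeats = x$repeats, stringsAsFactors = FALSE)
}

# one train/evaluate pass; returns per-output train and test errors
fit_and_score <- function(data, train_idx, test_idx, cfg, seed) {
  train <- subset_dataset(data, train_idx)
  test <- subset_dataset(data, test_idx)
  net <- init_network(seed = seed)
  net <- fit_scalers(net, train)
  net <- train_network(net, train, cfg)$net
  score <- function(split) {
    Y <- predict_parameters(net, split$inputs)
    Ts <- scale_channels(split$targets, net$output_scaler)
    Ys <- scale_channels(Y, net$output_scaler)
    list(rms = error_metric(split$targets, Y, "rms_relative"),
         printed = error_metric(Ts, Ys, "as_printed"))
  }
  list(train = score(train), test = score(test))
}

#' Hold-out validation
#'
#' Splits the dataset into non-overlapping training and test parts by the
#' supplied test ids, then, for each repeat (with initialization seed
#' `cfg$seed + repeat - 1`): fits the scalers on the training split only,
#' trains the network, and evaluates the per-output percent errors on both
#' splits.  Errors are averaged over repeats.
#'
#' @param data A `palp_dataset`.
#' @param test_ids Character ids (or integer indices) of the held-out test
#'   records; must be a nonempty proper subset.
#' @param cfg A [train_config()].
#' @param repeats Number of repeats averaged.
#' @return A `validation_result`.
#' @export
holdout_validate <- function(data, test_ids, cfg = train_config(),
                             repeats = 10) {
  stopifnot(inherits(data, "palp_dataset"), repeats >= 1)
  idx <- if (is.character(test_ids)) match(test_ids, data$ids) else
    as.integer(test_ids)
  if (anyNA(idx)) stop("unknown test ids")
  n <- nrow(data$inputs)
  if (length(idx) == 0 || length(idx) >= n) {
    stop("test set must be a nonempty proper subset of the data")
  }
  train_idx <- setdiff(seq_len(n), idx)
  if (length(intersect(train_idx, idx)) > 0) {
    stop("train/test overlap detected")
  }
  seeds <- cfg$seed + seq_len(repeats) - 1
  acc <- lapply(seeds, function(sd) fit_and_score(data, train_idx, idx, cfg,
                                                  sd))
  avg <- function(part, metric) {
    rowMeans(vapply(acc, function(a) a[[part]][[metric]], numeric(3)))
  }
  new_validation_result(
    scheme = "HOV", cfg = cfg, repeats = repeats, seeds = seeds,
    n_train = length(train_idx), n_test = length(idx),
    tr = avg("train", "rms"), te = avg("test", "rms"),
    trp = avg("train", "printed"), tep = avg("test", "printed"))
}

#' Leave-one-out cross-validation
#'
#' Runs exactly `n` folds, each training on `n - 1` records (scalers
#' refitted on the training portion of every fold) and testing on the
#' single held-out record; every record is tested exactly once.  The final
#' error is the average of the fold errors, then averaged over `repeats`
#' initialization seeds (`cfg$seed + repeat - 1`).
#'
#' @param data A `palp_dataset` with at least 3 records.
#' @param cfg A [train_config()].
#' @param repeats Number of repeats averaged.
#' @param progress Print a dot per completed fold.
#' @return A `validation_result`.
#' @export
loocv_validate <- function(data, cfg = train_config(), repeats = 10,
                           progress = FALSE) {
  stopifnot(inherits(data, "palp_dataset"), repeats >= 1)
  n <- nrow(data$inputs)
  if (n < 3) stop("leave-one-out validation needs at least 3 records")
  seeds <- cfg$seed + seq_len(repeats) - 1
  per_rep <- lapply(seeds, function(sd) {
    folds <- lapply(seq_len(n), function(i) {
      fit_and_score(data, setdiff(seq_len(n), i), i, cfg, sd)
    })
    if (progress) cat(".")
    list(
      tr = rowMeans(vapply(folds, function(f) f$train$rms, numeric(3))),
      te = rowMeans(vapply(folds, function(f) f$test$rms, numeric(3))),
      trp = rowMeans(vapply(folds, function(f) f$train$printed, numeric(3))),
      tep = rowMeans(vapply(folds, function(f) f$test$printed, numeric(3))))
  })
  if (progress) cat("\n")
  avg <- function(nm) rowMeans(vapply(per_rep, `[[`, numeric(3), nm))
  new_validation_result(
    scheme = "LOOCV", cfg = cfg, repeats = repeats, seeds = seeds,
    n_train = n - 1, n_test = 1,
    tr = avg("tr"), te = avg("te"), trp = avg("trp"), tep = avg("tep"),
    fold_count = n)
}

#' LOOCV fold assignments
#'
#' The partition LOOCV uses: fold `i` tests record `i`.  Exposed for
#' bookkeeping audits.
#'
#' @param data A `palp_dataset`.
#' @return List of `n` folds, each `list(train = ids, test = id)`.
#' @export
loocv_folds <- function(data) {
  n <- nrow(data$inputs)
  lapply(seq_len(n), function(i) {
    list(train = data$ids[-i], test = data$ids[i])
  })
}
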