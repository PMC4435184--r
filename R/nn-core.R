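# Small feed-forward inversion network: three weighted layers (3 sigmoid,
# 4 sigmoid, 3 linear units by default) mapping the scaled FEM feature
# triple to the scaled inclusion parameters (d, h, E).

act_fun <- function(tag) {
  switch(tag,
         sigmoid = function(z) 1 / (1 + exp(-z)),
         linear = function(z) z,
         stop("unknown activation tag: ", tag))
}

# derivative expressed in the activation value a = f(z)
act_deriv <- function(tag) {
  switch(tag,
         sigmoid = function(a) a * (1 - a),
         linear = function(a) rep(1, length(a)),
         stop("unknown activation tag: ", tag))
}

#' Initialize the inversion network
#'
#' Weights are drawn uniformly from \[-1, 1\] scaled by `1/sqrt(fan-in)`,
#' biases start at zero, and the input/output scalers are identity until
#' [fit_scalers()] is called.  Fully reproducible from the seed.
#'
#' @param seed Integer seed for the weight draw.
#' @param sizes Layer widths, first entry the input dimension; the default
#'   `c(3, 3, 4, 3)` gives three weighted layers of 3, 4 and 3 neurons.
#' @param activations Activation tag per weighted layer (`"sigmoid"` or
#'   `"linear"`); length `length(sizes) - 1`.
#' @return Object of class `palp_network`.
#' @export
init_network <- function(seed = 0, sizes = c(3, 3, 4, 3),
                         activations = c("sigmoid", "sigmoid", "linear")) {
  stopifnot(length(sizes) >= 2, length(activations) == length(sizes) - 1)
  nl <- length(activations)
  W <- b <- vector("list", nl)
  withr::with_seed(seed, {
    for (l in seq_len(nl)) {
      fan_in <- sizes[l]
      W[[l]] <- matrix(stats::runif(sizes[l + 1] * fan_in, -1, 1) /
                         sqrt(fan_in),
                       nrow = sizes[l + 1], ncol = fan_in)
      b[[l]] <- numeric(sizes[l + 1])
    }
  })
  identity_scaler <- list(min = rep(0, 3), range = rep(1, 3))
  structure(
    list(sizes = sizes, activations = activations, W = W, b = b,
         input_scaler = identity_scaler, output_scaler = identity_scaler,
         scalers_fitted = FALSE),
    class = "palp_network"
  )
}

#' @export
print.palp_network <- function(x, ...) {
  cat(sprintf("<palp_network> layers %s, activations %s, %d parameters%s\n",
              paste(x$sizes, collapse = "-"),
              paste(x$activations, collapse = "/"),
              length(flatten_weights(x)),
              if (x$scalers_fitted) ", scalers fitted" else ""))
  invisible(x)
}

#' Flatten / restore the network parameter vector
#'
#' The parameter vector stacks, per layer, the weight matrix
#' (column-major) followed by the bias vector.
#'
#' @param net A `palp_network`.
#' @param theta Numeric parameter vector of matching length.
#' @return `flatten_weights` returns the parameter vector; `set_weights`
#'   returns the network with parameters replaced.
#' @export
flatten_weights <- function(net) {
  unname(unlist(lapply(seq_along(net$W),
                       function(l) c(as.vector(net$W[[l]]), net$b[[l]]))))
}

#' @rdname flatten_weights
#' @export
set_weights <- function(net, theta) {
  at <- 0L
  for (l in seq_along(net$W)) {
    nw <- length(net$W[[l]])
    net$W[[l]] <- matrix(theta[at + seq_len(nw)], nrow = nrow(net$W[[l]]))
    at <- at + nw
    nb <- length(net$b[[l]])
    net$b[[l]] <- theta[at + seq_len(nb)]
    at <- at + nb
  }
  if (at != length(theta)) stop("parameter vector length mismatch")
  net
}

# Affine min-max scaling helpers (matrix rows = records).
scale_channels <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$min), 2, scaler$range, "/")
}
unscale_channels <- function(X, scaler) {
  sweep(sweep(X, 2, scaler$range, "*"), 2, scaler$min, "+")
}

#' Paired training dataset of features and inclusion parameters
#'
#' @param inputs `n` x 3 matrix of FEM-unit features (columns max, total,
#'   area).
#' @param targets `n` x 3 matrix of inclusion parameters (columns d mm,
#'   h mm, E kPa).
#' @param ids Record identifiers (default row names or indices).
#' @return Object of class `palp_dataset`.
#' @export
make_dataset <- function(inputs, targets, ids = NULL) {
  inputs <- as.matrix(inputs)
  targets <- as.matrix(targets)
  if (nrow(inputs) == 0) stop("dataset must be nonempty")
  if (nrow(inputs) != nrow(targets)) {
    stop("inputs and targets must have the same number of records")
  }
  if (!all(is.finite(inputs)) || !all(is.finite(targets))) {
    stop("dataset contains non-finite entries")
  }
  if (is.null(ids)) {
    ids <- rownames(inputs)
    if (is.null(ids)) ids <- as.character(seq_len(nrow(inputs)))
  }
  if (anyDuplicated(ids)) stop("dataset ids must be unique")
  structure(list(inputs = inputs, targets = targets, ids = as.character(ids)),
            class = "palp_dataset")
}

#' Dataset from scenarios and their forward features
#'
#' @param features `n` x 3 feature matrix, as from [fem_features()].
#' @param scenarios List of the matching [inclusion_scenario()]s.
#' @return A [make_dataset()] object with targets (d, h, E).
#' @export
scenario_dataset <- function(features, scenarios) {
  tab <- scenario_table(scenarios)
  make_dataset(features,
               cbind(d = tab$d_mm, h = tab$h_mm, E = tab$E_inc_kPa),
               ids = tab$id)
}

#' @export
print.palp_dataset <- function(x, ...) {
  cat(sprintf("<palp_dataset> %d records, inputs [%s], targets [%s]\n",
              nrow(x$inputs), paste(colnames(x$inputs), collapse = ", "),
              paste(colnames(x$targets), collapse = ", ")))
  invisible(x)
}

#' Subset a dataset by record ids or indices
#'
#' @param data A `palp_dataset`.
#' @param ids Character ids or integer indices to keep.
#' @return A `palp_dataset` with the selected records.
#' @export
subset_dataset <- function(data, ids) {
  idx <- if (is.character(ids)) match(ids, data$ids) else ids
  if (anyNA(idx)) stop("unknown record ids: ",
                       paste(ids[is.na(idx)], collapse = ", "))
  make_dataset(data$inputs[idx, , drop = FALSE],
               data$targets[idx, , drop = FALSE], data$ids[idx])
}

#' Fit the min-max input/output scalers on a dataset
#'
#' Per-channel affine maps sending the training data to \[0, 1\] for both
#' the feature inputs and the parameter targets.  Scalers fitted on a
#' training split only may map test records outside \[0, 1\]; that is
#' expected and harmless.
#'
#' @param net A `palp_network`.
#' @param data A `palp_dataset`.
#' @return The network with fitted scalers.
#' @export
fit_scalers <- function(net, data) {
  stopifnot(inherits(net, "palp_network"), inherits(data, "palp_dataset"))
  mk <- function(X) {
    lo <- apply(X, 2, min)
    hi <- apply(X, 2, max)
    if (any(hi - lo == 0)) {
      stop("zero-range channel: cannot fit min-max scaler for '",
           paste(colnames(X)[hi - lo == 0], collapse = ", "), "'")
    }
    list(min = unname(lo), range = unname(hi - lo))
  }
  net$input_scaler <- mk(data$inputs)
  net$output_scaler <- mk(data$targets)
  net$scalers_fitted <- TRUE
  net
}

# Forward pass in scaled space; returns all layer activations for use by
# the backward passes.  Xs: n x sizes[1] matrix.
nn_forward_scaled <- function(net, Xs) {
  A <- vector("list", length(net$W) + 1L)
  A[[1]] <- Xs
  for (l in seq_along(net$W)) {
    Z <- sweep(A[[l]] %*% t(net$W[[l]]), 2, net$b[[l]], "+")
    A[[l + 1L]] <- act_fun(net$activations[l])(Z)
  }
  A
}

#' Run the network forward on feature inputs
#'
#' Scales the physical-unit features into \[0, 1\], applies the declared
#' layer composition, and maps the outputs back to physical units
#' (d mm, h mm, E kPa).
#'
#' @param net A `palp_network`.
#' @param inputs A [feature_triple()], a list of them, or an `n` x 3
#'   matrix in FEM units.
#' @return `n` x 3 matrix with columns `d`, `h`, `E`.
#' @export
forward_pass <- function(net, inputs) {
  stopifnot(inherits(net, "palp_network"))
  X <- if (is.matrix(inputs)) inputs else feature_matrix(inputs)
  if (!net$scalers_fitted) {
    warning("scalers not fitted; treating inputs/outputs as already scaled")
  }
  A <- nn_forward_scaled(net, scale_channels(X, net$input_scaler))
  Y <- unscale_channels(A[[length(A)]], net$output_scaler)
  colnames(Y) <- c("d", "h", "E")
  Y
}

#' Predict inclusion parameters from features
#'
#' [forward_pass()] requiring fitted scalers: the raw physical-unit
#' estimate, not clamped to the training ranges.
#'
#' @param net A trained `palp_network` with fitted scalers.
#' @param features Features in FEM units (triple, list, or matrix).
#' @return `n` x 3 matrix with columns `d` (mm), `h` (mm), `E` (kPa).
#' @export
predict_parameters <- function(net, features) {
  if (!net$scalers_fitted) {
    stop("network scalers are not fitted; train the network (or call ",
         "fit_scalers) before predicting physical parameters")
  }
  forward_pass(net, features)
}

# Scaled-space residual vector and its Jacobian w.r.t. the parameter
# vector, by backpropagation.  Residuals are stacked output-major:
# e = as.vector(Yhat - T) (all records of output 1, then output 2, ...).
# J has one row per residual and one column per parameter, ordered as in
# flatten_weights().
nn_residual_jacobian <- function(net, Xs, Ts) {
  n <- nrow(Xs)
  A <- nn_forward_scaled(net, Xs)
  L <- length(net$W)
  Yh <- A[[L + 1L]]
  e <- as.vector(Yh - Ts)
  if (!all(is.finite(e))) stop("non-finite residuals in network evaluation")

  derivs <- lapply(seq_len(L), function(l) {
    matrix(act_deriv(net$activations[l])(A[[l + 1L]]), nrow = n)
  })
  n_out <- net$sizes[length(net$sizes)]
  npar <- sum(vapply(seq_len(L), function(l) length(net$W[[l]]) +
                       length(net$b[[l]]), numeric(1)))
  J <- matrix(0, n * n_out, npar)
  for (o in seq_len(n_out)) {
    rows <- (o - 1L) * n + seq_len(n)
    # delta at the output layer for output unit o: d e / d Z_L
    delta <- matrix(0, n, n_out)
    delta[, o] <- derivs[[L]][, o]
    at <- npar
    for (l in rev(seq_len(L))) {
      nb <- length(net$b[[l]])
      nw <- length(net$W[[l]])
      # bias block for layer l
      J[rows, at - nb + seq_len(nb)] <- delta
      at <- at - nb
      # weight block, column-major over (unit k, input j)
      Aprev <- A[[l]]
      nin <- ncol(Aprev)
      blk <- matrix(0, n, nw)
      for (j in seq_len(nin)) {
        blk[, (j - 1L) * nb + seq_len(nb)] <- delta * Aprev[, j]
      }
      J[rows, at - nw + seq_len(nw)] <- blk
      at <- at - nw
      if (l > 1L) delta <- (delta %*% net$W[[l]]) * derivs[[l - 1L]]
    }
  }
  list(e = e, J = J)
}

#' Residual vector and Jacobian of the network on a dataset
#'
#' Residuals are computed in scaled space (inputs and targets mapped
#' through the network's scalers), stacked one row per record and output;
#' the Jacobian `d e / d theta` is computed by backpropagation, one column
#' per weight or bias in [flatten_weights()] order.
#'
#' @param net A `palp_network`.
#' @param data A `palp_dataset`.
#' @return List with elements `e` (length `3n`) and `J` (`3n` x `npar`).
#' @export
error_and_jacobian <- function(net, data) {
  stopifnot(inherits(net, "palp_network"), inherits(data, "palp_dataset"))
  Xs <- scale_channels(data$inputs, net$input_scaler)
  Ts <- scale_channels(data$targets, net$output_scaler)
  nn_residual_jacobian(net, Xs, Ts)
}

# Sum-of-squares error and its gradient in scaled space (direct backprop,
# no Jacobian materialized) -- the objective both trainers minimize.
nn_error <- function(net, Xs, Ts) {
  A <- nn_forward_scaled(net, Xs)
  sum((A[[length(A)]] - Ts)^2)
}

nn_error_grad <- function(net, Xs, Ts) {
  n <- nrow(Xs)
  A <- nn_forward_scaled(net, Xs)
  L <- length(net$W)
  delta <- 2 * (A[[L + 1L]] - Ts) * act_deriv(net$activations[L])(A[[L + 1L]])
  g <- vector("list", L)
  for (l in rev(seq_len(L))) {
    g[[l]] <- c(as.vector(crossprod(delta, A[[l]])), colSums(delta))
    if (l > 1L) {
      delta <- (delta %*% net$W[[l]]) *
        act_deriv(net$activations[l - 1L])(A[[l]])
    }
  }
  as.numeric(unlist(g))
}
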