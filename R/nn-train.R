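# Training algorithms.  Both are written against generic closures so the
# optimizers can be verified on analytic problems independent of the
# network: Levenberg-Marquardt on a residual/Jacobian pair, and scaled
# conjugate gradient on an error/gradient pair.

#' Training configuration
#'
#' @param algorithm `"SCGA"` (scaled conjugate gradient) or `"LMA"`
#'   (Levenberg-Marquardt).
#' @param iterations Maximum number of training iterations.
#' @param tol Convergence tolerance on the decrease of the summed squared
#'   error between accepted iterations; `0` runs the full budget.
#' @param mu0,beta LMA: initial damping and its multiplicative adaptation
#'   factor (damping is divided by `beta` after an accepted step and
#'   multiplied by `beta` after a rejected one).
#' @param sigma SCGA: relative offset of the finite-difference
#'   curvature probe.
#' @param lambda0 SCGA: initial scale (regularization) parameter.
#' @param seed Seed for the weight initialization used by the validation
#'   harnesses.
#' @return Named list of class `train_config`.
#' @export
train_config <- function(algorithm = c("SCGA", "LMA"), iterations = 100,
                         tol = 0, mu0 = 1e-3, beta = 10, sigma = 1e-4,
                         lambda0 = 1e-6, seed = 0) {
  stopifnot(iterations >= 1, mu0 > 0, beta > 1, sigma > 0, lambda0 > 0,
            tol >= 0)
  structure(list(algorithm = match.arg(algorithm),
                 iterations = as.integer(iterations), tol = tol, mu0 = mu0,
                 beta = beta, sigma = sigma, lambda0 = lambda0, seed = seed),
            class = "train_config")
}

#' Levenberg-Marquardt least-squares optimizer
#'
#' Minimizes `E(x) = sum(e(x)^2)` by damped Gauss-Newton steps
#' `dx = solve(J'J + mu I, J'e)`.  The damping `mu` is divided by `beta`
#' whenever a step reduces `E` and multiplied by `beta` whenever a trial
#' step would increase `E` (the trial is rejected and the previous
#' parameters restored).  With very large `mu` the step direction
#' approaches steepest descent; with small `mu` it approaches Gauss-Newton.
#'
#' @param theta0 Initial parameter vector.
#' @param residual_fn Function `theta -> list(e, J)` returning the residual
#'   vector and its Jacobian.
#' @param mu0 Initial damping.
#' @param beta Damping adaptation factor (> 1).
#' @param maxit Maximum accepted iterations.
#' @param tol Stop when the decrease in `E` falls below `tol`.
#' @param mu_max Damping ceiling: if `mu` exceeds it while no step is
#'   accepted, the optimizer stops (flat to machine precision).
#' @return List with `theta`, `history` (accepted `E` per iteration,
#'   starting with the initial error), `mu`, `iterations`, `converged`.
#' @export
lma_optimize <- function(theta0, residual_fn, mu0 = 1e-3, beta = 10,
                         maxit = 100, tol = 0, mu_max = 1e12) {
  theta <- theta0
  mu <- mu0
  rj <- residual_fn(theta)
  E <- sum(rj$e^2)
  history <- E
  converged <- FALSE
  for (it in seq_len(maxit)) {
    JtJ <- crossprod(rj$J)
    Jte <- crossprod(rj$J, rj$e)
    accepted <- FALSE
    repeat {
      step <- tryCatch(
        solve(JtJ + mu * diag(nrow(JtJ)), Jte),
        error = function(e) NULL)
      if (is.null(step)) {
        mu <- mu * beta
        if (mu > mu_max) {
          stop("normal-equation solve failed up to the damping ceiling; ",
               "Jacobian is numerically degenerate")
        }
        next
      }
      theta_try <- theta - as.numeric(step)
      rj_try <- residual_fn(theta_try)
      E_try <- sum(rj_try$e^2)
      if (is.finite(E_try) && E_try < E) {
        theta <- theta_try
        rj <- rj_try
        dE <- E - E_try
        E <- E_try
        mu <- mu / beta
        accepted <- TRUE
        break
      }
      mu <- mu * beta
      if (mu > mu_max) break
    }
    if (!accepted) {
      converged <- TRUE
      break
    }
    history <- c(history, E)
    if (dE < tol) {
      converged <- TRUE
      break
    }
  }
  list(theta = theta, history = history, mu = mu, iterations = it,
       converged = converged)
}

#' Scaled conjugate gradient optimizer
#'
#' Conjugate-gradient minimization with second-order information obtained
#' from a finite-difference Hessian-vector product along the search
#' direction, regularized by an adaptively scaled parameter `lambda` that
#' keeps the local curvature estimate positive definite.  Memory use is
#' O(N) in the number of parameters: only vectors are stored, never a
#' Hessian.  The conjugate direction is restarted to steepest descent
#' every `restart` iterations.
#'
#' Per iteration: the curvature `delta = p' H p` is probed by
#' `(grad(x + sigma_k p) - grad(x)) / sigma_k` with
#' `sigma_k = sigma / |p|`, scaled by `lambda`; repaired to positive if
#' needed; the step `alpha = p'r / delta` is taken if the comparison
#' parameter `Delta` (the ratio of actual to predicted error decrease) is
#' nonnegative; `lambda` is halved when `Delta >= 0.75` and quadrupled
#' when `Delta < 0.25`.
#'
#' @param theta0 Initial parameter vector.
#' @param fn Error function `theta -> E`.
#' @param gr Gradient function `theta -> grad E`.
#' @param sigma Relative finite-difference offset.
#' @param lambda0 Initial scale parameter.
#' @param maxit Maximum iterations.
#' @param tol Stop when the decrease of `E` over an accepted step falls
#'   below `tol`.
#' @param restart Restart period for the conjugate direction; defaults to
#'   the number of parameters.
#' @param grad_tol Terminate when the gradient norm falls below this.
#' @return List with `theta`, `history` (`E` after each iteration,
#'   starting with the initial error), `lambda`, `iterations`,
#'   `converged`.
#' @export
scg_optimize <- function(theta0, fn, gr, sigma = 1e-4, lambda0 = 1e-6,
                         maxit = 100, tol = 0, restart = length(theta0),
                         grad_tol = 1e-12) {
  x <- theta0
  lambda <- lambda0
  lambda_bar <- 0
  r <- -gr(x)
  p <- r
  success <- TRUE
  E_x <- fn(x)
  history <- E_x
  s <- NULL
  delta <- NULL
  converged <- FALSE
  for (k in seq_len(maxit)) {
    if (!is.finite(lambda) || lambda > 1e120) {
      stop("scale parameter lambda escalated to a non-finite value ",
           "(iteration ", k, ", E = ", E_x, "); the error surface is ",
           "numerically degenerate")
    }
    p2 <- sum(p * p)
    if (p2 == 0) {
      converged <- TRUE
      break
    }
    if (success) {
      sigma_k <- sigma / sqrt(p2)
      s <- (gr(x + sigma_k * p) - gr(x)) / sigma_k
      delta <- sum(p * s)
    }
    # scale the curvature estimate
    s <- s + (lambda - lambda_bar) * p
    delta <- delta + (lambda - lambda_bar) * p2
    if (delta <= 0) {
      # make the curvature positive definite
      s <- s + (lambda - 2 * delta / p2) * p
      lambda_bar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambda_bar
    }
    mu_k <- sum(p * r)
    if (delta == 0) {
      lambda_bar <- lambda
      lambda <- 4 * lambda
      success <- FALSE
      history <- c(history, E_x)
      next
    }
    alpha <- mu_k / delta
    E_trial <- fn(x + alpha * p)
    Delta_k <- 2 * delta * (E_x - E_trial) / mu_k^2
    if (is.finite(Delta_k) && Delta_k >= 0) {
      dE <- E_x - E_trial
      x <- x + alpha * p
      E_x <- E_trial
      r_new <- -gr(x)
      lambda_bar <- 0
      success <- TRUE
      if (k %% restart == 0) {
        p <- r_new
      } else {
        beta_k <- (sum(r_new * r_new) - sum(r_new * r)) / mu_k
        p <- r_new + beta_k * p
      }
      r <- r_new
      if (Delta_k >= 0.75) lambda <- lambda / 2
      if (dE < tol) {
        history <- c(history, E_x)
        converged <- TRUE
        break
      }
    } else {
      lambda_bar <- lambda
      success <- FALSE
    }
    if (!is.finite(Delta_k) || Delta_k < 0.25) lambda <- 4 * lambda
    history <- c(history, E_x)
    if (sqrt(sum(r * r)) < grad_tol) {
      converged <- TRUE
      break
    }
  }
  list(theta = x, history = history, lambda = lambda, iterations = k,
       converged = converged)
}

# closures binding a network and scaled dataset to the optimizers
nn_closures <- function(net, data) {
  Xs <- scale_channels(data$inputs, net$input_scaler)
  Ts <- scale_channels(data$targets, net$output_scaler)
  list(
    resid = function(theta) {
      nn_residual_jacobian(set_weights(net, theta), Xs, Ts)
    },
    fn = function(theta) nn_error(set_weights(net, theta), Xs, Ts),
    gr = function(theta) nn_error_grad(set_weights(net, theta), Xs, Ts)
  )
}

#' Train the network by Levenberg-Marquardt
#'
#' @param net A `palp_network` (scalers should already be fitted on the
#'   training data, see [fit_scalers()]).
#' @param data A `palp_dataset`.
#' @param cfg A [train_config()] with `algorithm = "LMA"`.
#' @return List with the trained `net` and the per-iteration error
#'   `history` (summed squared residuals in scaled space).
#' @export
train_lma <- function(net, data, cfg = train_config(algorithm = "LMA")) {
  stopifnot(cfg$algorithm == "LMA")
  cl <- nn_closures(net, data)
  res <- lma_optimize(flatten_weights(net), cl$resid, mu0 = cfg$mu0,
                      beta = cfg$beta, maxit = cfg$iterations, tol = cfg$tol)
  list(net = set_weights(net, res$theta), history = res$history,
       mu = res$mu, iterations = res$iterations)
}

#' Train the network by scaled conjugate gradient
#'
#' @inheritParams train_lma
#' @param cfg A [train_config()] with `algorithm = "SCGA"`.
#' @return List with the trained `net` and the per-iteration error
#'   `history`.
#' @export
train_scga <- function(net, data, cfg = train_config(algorithm = "SCGA")) {
  stopifnot(cfg$algorithm == "SCGA")
  cl <- nn_closures(net, data)
  res <- scg_optimize(flatten_weights(net), cl$fn, cl$gr, sigma = cfg$sigma,
                      lambda0 = cfg$lambda0, maxit = cfg$iterations,
                      tol = cfg$tol)
  list(net = set_weights(net, res$theta), history = res$history,
       lambda = res$lambda, iterations = res$iterations)
}

#' Train the network with the algorithm named in the configuration
#'
#' @inheritParams train_lma
#' @param cfg A [train_config()].
#' @return See [train_lma()] / [train_scga()].
#' @export
train_network <- function(net, data, cfg = train_config()) {
  if (cfg$algorithm == "LMA") train_lma(net, data, cfg)
  else train_scga(net, data, cfg)
}

#' Write / read network weights as versioned plain text
#'
#' Stores layer sizes, activation tags, the flattened parameter vector and
#' both scalers with 17 significant digits, so a written network restores
#' bit-exactly.
#'
#' @param net A `palp_network`.
#' @param path File path.
#' @return `read_network` returns a `palp_network`; `write_network`
#'   returns `path` invisibly.
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "palp_network"))
  num <- function(v) paste(sprintf("%.17g", v), collapse = " ")
  lines <- c(
    "palpinv-network v1",
    paste("sizes", paste(net$sizes, collapse = " ")),
    paste("activations", paste(net$activations, collapse = " ")),
    paste("theta", num(flatten_weights(net))),
    paste("input_min", num(net$input_scaler$min)),
    paste("input_range", num(net$input_scaler$range)),
    paste("output_min", num(net$output_scaler$min)),
    paste("output_range", num(net$output_scaler$range)),
    paste("scalers_fitted", as.integer(net$scalers_fitted)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "palpinv-network v1")) {
    stop("not a palpinv network file")
  }
  fields <- list()
  for (ln in lines[-1]) {
    parts <- strsplit(ln, " ")[[1]]
    fields[[parts[1]]] <- parts[-1]
  }
  net <- init_network(seed = 0, sizes = as.integer(fields$sizes),
                      activations = fields$activations)
  net <- set_weights(net, as.numeric(fields$theta))
  net$input_scaler <- list(min = as.numeric(fields$input_min),
                           range = as.numeric(fields$input_range))
  net$output_scaler <- list(min = as.numeric(fields$output_min),
                            range = as.numeric(fields$output_range))
  net$scalers_fitted <- as.logical(as.integer(fields$scalers_fitted))
  net
}
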