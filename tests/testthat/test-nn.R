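test_that("initialization is seeded and bounded", {
  n1 <- init_network(seed = 0)
  expect_identical(flatten_weights(n1), flatten_weights(init_network(0)))
  expect_false(identical(flatten_weights(n1),
                         flatten_weights(init_network(1))))
  th <- flatten_weights(n1)
  expect_length(th, 43)          # (3x3+3) + (4x3+4) + (3x4+3)
  expect_true(all(abs(th) <= 1))
  # biases start at zero
  expect_true(all(unlist(n1$b) == 0))
})

test_that("forward pass composes the declared layers", {
  # zero network: output equals the final-layer bias, i.e. zero
  n0 <- init_network(0)
  n0 <- set_weights(n0, rep(0, 43))
  out <- suppressWarnings(forward_pass(n0, matrix(stats::runif(9), 3,
    dimnames = list(NULL, c("f_max", "f_total", "f_area")))))
  expect_true(all(out == 0))

  # against an independent per-record loop implementation
  sig <- function(z) 1 / (1 + exp(-z))
  for (seed in 1:10) {
    net <- init_network(seed)
    X <- withr::with_seed(100 + seed, matrix(stats::rnorm(9), 3))
    ref <- t(apply(X, 1, function(x) {
      a1 <- sig(net$W[[1]] %*% x + net$b[[1]])
      a2 <- sig(net$W[[2]] %*% a1 + net$b[[2]])
      as.numeric(net$W[[3]] %*% a2 + net$b[[3]])
    }))
    got <- suppressWarnings(forward_pass(net, X))
    expect_equal(unname(got), ref, tolerance = 1e-12)
    # hidden activations stay inside (0, 1)
    A <- palpinv:::nn_forward_scaled(net, X)
    expect_true(all(A[[2]] > 0 & A[[2]] < 1))
    expect_true(all(A[[3]] > 0 & A[[3]] < 1))
  }
})

test_that("backpropagated Jacobian matches central finite differences", {
  worst <- 0
  for (seed in 1:20) {
    net <- init_network(seed)
    d <- toy_dataset(6, seed = 200 + seed)
    net <- fit_scalers(net, d)
    rj <- error_and_jacobian(net, d)
    th <- flatten_weights(net)
    hh <- 1e-6
    fd <- vapply(seq_along(th), function(i) {
      tp <- th; tp[i] <- tp[i] + hh
      tm <- th; tm[i] <- tm[i] - hh
      (error_and_jacobian(set_weights(net, tp), d)$e -
         error_and_jacobian(set_weights(net, tm), d)$e) / (2 * hh)
    }, numeric(length(rj$e)))
    worst <- max(worst, max(abs(fd - rj$J)) / max(abs(fd)))
  }
  expect_lt(worst, 1e-6)
})

test_that("the gradient equals 2 J'e and matches finite differences of E", {
  net <- fit_scalers(init_network(3), toy_dataset(8))
  d <- toy_dataset(8)
  rj <- error_and_jacobian(net, d)
  cl <- palpinv:::nn_closures(net, d)
  th <- flatten_weights(net)
  expect_equal(cl$gr(th), 2 * as.numeric(crossprod(rj$J, rj$e)),
               tolerance = 1e-12)
  hh <- 1e-6
  fd <- vapply(seq_along(th), function(i) {
    tp <- th; tp[i] <- tp[i] + hh
    tm <- th; tm[i] <- tm[i] - hh
    (cl$fn(tp) - cl$fn(tm)) / (2 * hh)
  }, numeric(1))
  expect_equal(cl$gr(th), fd, tolerance = 1e-5)
})

test_that("duplicating records duplicates residuals and Jacobian rows", {
  net <- fit_scalers(init_network(4), toy_dataset(5))
  d <- toy_dataset(5)
  d2 <- make_dataset(rbind(d$inputs, d$inputs), rbind(d$targets, d$targets),
                     ids = c(d$ids, paste0(d$ids, "b")))
  a <- error_and_jacobian(net, d)
  b <- error_and_jacobian(net, d2)
  expect_length(b$e, 2 * length(a$e))
  # output-major stacking: rows for output o are the records in order
  n <- nrow(d$inputs)
  for (o in 1:3) {
    expect_equal(b$e[(o - 1) * 2 * n + seq_len(n)],
                 a$e[(o - 1) * n + seq_len(n)])
    expect_equal(b$J[(o - 1) * 2 * n + seq_len(n), ],
                 a$J[(o - 1) * n + seq_len(n), ])
  }
})

test_that("min-max scalers map the data to [0, 1] and invert exactly", {
  d <- toy_dataset(20)
  net <- fit_scalers(init_network(0), d)
  Xs <- palpinv:::scale_channels(d$inputs, net$input_scaler)
  expect_equal(unname(apply(Xs, 2, min)), rep(0, 3))
  expect_equal(unname(apply(Xs, 2, max)), rep(1, 3))
  back <- palpinv:::unscale_channels(Xs, net$input_scaler)
  expect_equal(back, d$inputs, tolerance = 1e-12)
  # scalers fitted on a training split may map test data outside [0, 1]
  tr <- subset_dataset(d, 1:10)
  net_tr <- fit_scalers(init_network(0), tr)
  Xs_all <- palpinv:::scale_channels(d$inputs, net_tr$input_scaler)
  expect_true(any(Xs_all < 0 | Xs_all > 1))
  # degenerate channel is rejected
  flat <- d
  flat$inputs[, 2] <- 1
  expect_error(fit_scalers(init_network(0), flat), "zero-range")
})

test_that("LMA solves a linear least-squares network in one accepted step", {
  # single weighted linear layer: the residual is linear in the parameters,
  # so one (barely damped) Gauss-Newton step is exact
  net <- init_network(5, sizes = c(3, 3), activations = "linear")
  X <- withr::with_seed(20, matrix(stats::runif(36), 12, 3,
    dimnames = list(NULL, c("f_max", "f_total", "f_area"))))
  B <- matrix(c(1, 2, 0, 0, 1, 1, 1, 0, 3), 3) * 0.1
  d <- make_dataset(X, X %*% B)
  cl <- palpinv:::nn_closures(net, d)
  res <- lma_optimize(flatten_weights(net), cl$resid, mu0 = 1e-9, maxit = 1)
  expect_lt(res$history[2], 1e-10)
  expect_lt(res$mu, 1e-9)        # accepted step divides the damping
})

test_that("very large damping turns the LMA step into gradient descent", {
  net <- fit_scalers(init_network(6), toy_dataset(10))
  rj <- error_and_jacobian(net, toy_dataset(10))
  g <- as.numeric(crossprod(rj$J, rj$e))
  step <- solve(crossprod(rj$J) + 1e9 * diag(43), g)
  angle <- acos(sum(step * g) / sqrt(sum(step^2) * sum(g^2))) * 180 / pi
  expect_lt(angle, 1)
})

test_that("the LMA step rotates monotonically from descent to Gauss-Newton", {
  net <- fit_scalers(init_network(7), toy_dataset(10))
  rj <- error_and_jacobian(net, toy_dataset(10))
  JtJ <- crossprod(rj$J)
  g <- as.numeric(crossprod(rj$J, rj$e))
  gn <- as.numeric(solve(JtJ + 1e-10 * diag(43), g))
  angles <- vapply(10^seq(6, -6), function(mu) {
    s <- as.numeric(solve(JtJ + mu * diag(43), g))
    acos(sum(s * gn) / sqrt(sum(s^2) * sum(gn^2)))
  }, numeric(1))
  expect_true(all(diff(angles) <= 1e-9))
})

test_that("accepted LMA steps never increase the error", {
  for (seed in 1:5) {
    net <- fit_scalers(init_network(seed), toy_dataset(12, seed))
    r <- train_lma(net, toy_dataset(12, seed),
                   train_config("LMA", iterations = 30))
    expect_true(all(diff(r$history) <= 1e-12))
  }
})

test_that("SCGA attains a quadratic minimum by conjugate-direction steps", {
  A <- withr::with_seed(30, crossprod(matrix(stats::rnorm(25), 5))) +
    0.5 * diag(5)
  b <- withr::with_seed(31, stats::rnorm(5))
  fn <- function(x) 0.5 * sum(x * (A %*% x)) - sum(b * x) + 10
  gr <- function(x) as.numeric(A %*% x - b)
  E_min <- fn(solve(A, b))
  opt <- scg_optimize(rep(0, 5), fn, gr, maxit = 10)
  # finite termination: within (n + a few) iterations of the 5-var problem
  reached <- which(opt$history - E_min < 1e-8)
  expect_true(length(reached) > 0 && min(reached) <= 9)
  expect_true(all(diff(opt$history) <= 1e-12))
})

test_that("SCGA steps with nonnegative comparison parameter reduce E", {
  for (seed in 1:10) {
    net <- fit_scalers(init_network(seed), toy_dataset(12, seed + 50))
    r <- train_scga(net, toy_dataset(12, seed + 50),
                    train_config("SCGA", iterations = 60))
    expect_true(all(diff(r$history) <= 1e-12))
    expect_lt(tail(r$history, 1), r$history[1])
  }
})

test_that("seeded training is bit-reproducible", {
  d <- toy_dataset(15)
  run <- function() {
    net <- fit_scalers(init_network(9), d)
    flatten_weights(train_scga(net, d,
                               train_config("SCGA", iterations = 40))$net)
  }
  expect_identical(run(), run())
})

test_that("a converged network reproduces its training targets", {
  # noiseless, learnable map: targets affine in the inputs
  X <- withr::with_seed(40, matrix(stats::runif(60), 20, 3,
    dimnames = list(NULL, c("f_max", "f_total", "f_area"))))
  Tm <- cbind(d = 2 + 10 * X[, 1], h = 3 + 6 * X[, 2], E = 20 + 80 * X[, 3])
  d <- make_dataset(X, Tm)
  net <- fit_scalers(init_network(2), d)
  r <- train_lma(net, d, train_config("LMA", iterations = 200))
  Y <- predict_parameters(r$net, X)
  expect_true(all(abs(Y - Tm) / Tm < 0.05))
  # prediction is deterministic
  expect_identical(predict_parameters(r$net, X),
                   predict_parameters(r$net, X))
  # unfitted scalers are flagged
  expect_error(predict_parameters(init_network(0), X), "scalers")
  expect_warning(forward_pass(init_network(0), X), "scalers")
})

test_that("a network round-trips bit-exactly through its text format", {
  net <- fit_scalers(init_network(12), toy_dataset(10))
  net <- train_scga(net, toy_dataset(10),
                    train_config("SCGA", iterations = 20))$net
  path <- withr::local_tempfile(fileext = ".txt")
  write_network(net, path)
  back <- read_network(path)
  expect_identical(flatten_weights(back), flatten_weights(net))
  expect_identical(back$input_scaler, net$input_scaler)
  expect_identical(back$output_scaler, net$output_scaler)
  X <- toy_dataset(10)$inputs
  expect_identical(predict_parameters(back, X),
                   predict_parameters(net, X))
})
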