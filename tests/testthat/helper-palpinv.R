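# Shared fixtures.  Heavy objects are built once per test run and
# memoized; everything is generated in code.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  hit <- get0(key, envir = .fixtures)
  if (!is.null(hit)) return(hit)
  val <- force(expr)
  assign(key, val, envir = .fixtures)
  val
}

# coarse mesh for cheap solver tests
fast_cfg <- function(...) fem_config(resolution = 0.5, ...)

ref_scenario <- function() inclusion_scenario(d = 8, h = 5, E_inc = 120)

# small random (but reproducible) dataset in network scale for optimizer
# and bookkeeping tests -- unrelated to the FEM
toy_dataset <- function(n = 12, seed = 42) {
  withr::with_seed(seed, {
    X <- matrix(stats::runif(3 * n), n, 3,
                dimnames = list(NULL, c("f_max", "f_total", "f_area")))
    Tm <- cbind(d = 2 + 12 * X[, 1],
                h = 3 + 9 * plogis(2 * X[, 2] - 1),
                E = 20 + 100 * X[, 3]^1.5)
    make_dataset(X, Tm)
  })
}

# 34-scenario study set (25 random + the 9 calibration phantoms) with its
# forward features at the default mesh; used by the recovery and
# monotonicity acceptance checks
accept_dataset <- function() {
  memo("accept34", {
    scs <- study_scenarios(n = 34, seed = 0)
    feats <- fem_features(scs)
    list(scenarios = scs, features = feats,
         dataset = scenario_dataset(feats, scs),
         calibration_ids = attr(scs, "calibration_ids"))
  })
}

# deformation field with unit per-point cell area (6-point axes spanning
# 6 mm) for quantification examples
unit_area_field <- function(w_fill = 0) {
  g <- seq(0, 6, length.out = 6)
  deformation_field(g, g, matrix(w_fill, 6, 6))
}
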