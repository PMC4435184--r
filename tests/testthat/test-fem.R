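confined_modulus <- function(E, nu) E * (1 - nu) / ((1 + nu) * (1 - 2 * nu))

test_that("meshed tissue volume matches the slab volume", {
  m <- build_model(ref_scenario(), fast_cfg())
  vol <- sum(apply(m$el_size[m$region == "tissue", ], 1, prod))
  s <- ref_scenario()
  expect_equal(vol, s$tissue_side^2 * s$tissue_thickness, tolerance = 1e-3)
  expect_true(all(apply(m$el_size, 1, prod) > 0))
  expect_length(intersect(m$base_nodes, m$probe_top_nodes), 0)
})

test_that("inclusion-tagged element centroids lie inside the sphere", {
  s <- ref_scenario()  # 8 mm sphere, top 5 mm below the surface
  m <- build_model(s, fem_config())
  cen <- (m$lo[m$inclusion_mask, , drop = FALSE] +
            m$hi[m$inclusion_mask, , drop = FALSE]) / 2
  center <- c(s$tissue_side / 2, s$tissue_side / 2,
              s$tissue_thickness - (s$h + s$d / 2))
  expect_true(all(sqrt(rowSums(sweep(cen, 2, center)^2)) <= s$d / 2))
  expect_gt(sum(m$inclusion_mask), 0)
})

test_that("a vanishing stiffness contrast leaves the modulus field uniform", {
  s <- inclusion_scenario(8, 5, 5 * (1 + 1e-9))
  m <- build_model(s, fem_config(partial_volume = FALSE))
  expect_equal(m$E_elem[m$region == "tissue"],
               rep(5, sum(m$region == "tissue")), tolerance = 1e-8)
})

test_that("unresolvably small inclusions are rejected", {
  expect_error(build_model(inclusion_scenario(0.3, 5, 120), fast_cfg()),
               "too coarse")
  expect_error(build_model(inclusion_scenario(2, 5, 120),
                           fem_config(partial_volume = FALSE)),
               "two\\s+elements across")
})

test_that("confined homogeneous slab matches the uniform-strain closed form", {
  s <- inclusion_scenario(8, 5, 5 * (1 + 1e-9), probe_side = 120)
  cfg <- fast_cfg(side_bc = "roller")
  m <- build_model(s, cfg)
  m$E_elem[m$region == "tissue"] <- 5
  f <- solve_indentation(m, indent = 2, full_solution = TRUE)

  # series stack of confined moduli: displacement at the interface
  Mt <- confined_modulus(5, s$nu)
  Mp <- confined_modulus(cfg$probe_modulus_kpa, s$nu)
  ct <- s$tissue_thickness / Mt
  u_int <- -2 * ct / (ct + cfg$probe_height_mm / Mp)

  # probe-bottom field equals the closed form, uniform to round-off
  expect_lt(stats::sd(f$w) / mean(f$w), 1e-6)
  expect_equal(mean(f$w), u_int + 2, tolerance = 1e-8)

  # interior vertical displacement is linear in depth
  u <- attr(f, "u"); dof <- attr(f, "dof"); coords <- attr(f, "coords")
  tn <- which(coords[, 3] <= s$tissue_thickness + 1e-9)
  pred <- u_int * coords[tn, 3] / s$tissue_thickness
  expect_equal(u[dof[tn, 3]], pred, tolerance = 5e-3)
  expect_lt(max(abs(u[dof[tn, 3]] - pred)), 1e-8 * abs(u_int) + 1e-12)
})

test_that("solution is linear in the prescribed indentation", {
  m <- build_model(ref_scenario(), fast_cfg())
  f1 <- solve_indentation(m, indent = 1)
  f2 <- solve_indentation(m, indent = 2)
  expect_equal(f2$w, 2 * f1$w, tolerance = 1e-9)
})

test_that("a centered inclusion gives a mirror-symmetric field", {
  f <- solve_indentation(build_model(ref_scenario(), fast_cfg()))
  asym <- max(max(abs(f$w - f$w[nrow(f$w):1, ])),
              max(abs(f$w - f$w[, ncol(f$w):1]))) / max(abs(f$w))
  expect_lt(asym, 0.01)
})

test_that("a stiffer inclusion deforms the probe more", {
  cfg <- fast_cfg()
  soft <- fem_forward(inclusion_scenario(8, 5, 40), cfg)
  stiff <- fem_forward(inclusion_scenario(8, 5, 120), cfg)
  expect_gt(stiff$f_max, soft$f_max)
})

test_that("indentation outside the small-strain regime is rejected", {
  m <- build_model(ref_scenario(), fast_cfg())
  expect_error(solve_indentation(m, indent = 6), "25%")
  expect_error(solve_indentation(m, indent = -1), "positive")
})

test_that("feature quantification handles degenerate fields", {
  f0 <- unit_area_field(0)
  expect_equal(unlist(quantify_deformation(f0)[1:3]),
               c(f_max = 0, f_total = 0, f_area = 0))
  f1 <- unit_area_field(0)
  f1$w[3, 4] <- 0.3
  ft <- quantify_deformation(f1)
  expect_equal(c(ft$f_max, ft$f_total, ft$f_area), c(0.3, 0.3, 1.0))
  expect_error(deformation_field(1:2, 1:2, matrix(c(1, NA, 1, 1), 2)),
               "non-finite")
})

test_that("total deformation dominates maximum deformation", {
  for (seed in 1:20) {
    w <- withr::with_seed(seed, matrix(abs(stats::rnorm(36, 0, 0.05)), 6))
    ft <- quantify_deformation(deformation_field(1:6, 1:6, w))
    expect_gte(ft$f_total, ft$f_max)
    expect_gte(ft$f_max, 0)
    expect_gte(ft$f_area, 0)
  }
})

test_that("homogeneous scenarios carry no inclusion signal above baseline", {
  s <- inclusion_scenario(8, 5, 5 * (1 + 1e-9))
  ft <- fem_forward(s, fast_cfg())
  expect_equal(c(ft$f_max, ft$f_total, ft$f_area), c(0, 0, 0))
  # without baseline subtraction the features equal the slab baseline
  cfg_raw <- fast_cfg(baseline = "none")
  ft_raw <- fem_forward(s, cfg_raw)
  base <- quantify_deformation(baseline_field(s, cfg_raw),
                               floor_eps = cfg_raw$floor_eps_mm,
                               area_eps = cfg_raw$area_eps_mm)
  expect_equal(c(ft_raw$f_max, ft_raw$f_total, ft_raw$f_area),
               c(base$f_max, base$f_total, base$f_area), tolerance = 1e-6)
})

test_that("batch forward reproduces per-scenario forward", {
  cfg <- fast_cfg()
  scs <- list(inclusion_scenario(8, 5, 120, id = "a"),
              inclusion_scenario(11, 4, 60, id = "b"))
  batch <- fem_features(scs, cfg)
  for (i in 1:2) {
    one <- fem_forward(scs[[i]], cfg)
    expect_equal(unname(batch[i, ]), c(one$f_max, one$f_total, one$f_area),
                 tolerance = 1e-10)
  }
})

test_that("a model round-trips through its text serialization", {
  m <- build_model(ref_scenario(), fast_cfg())
  path <- withr::local_tempfile(fileext = ".txt")
  write_fem_model(m, path)
  m2 <- read_fem_model(path)
  expect_equal(m2$coords, m$coords, ignore_attr = TRUE)
  expect_equal(m2$E_elem, m$E_elem)
  f1 <- solve_indentation(m, indent = 2)
  f2 <- solve_indentation(m2, indent = 2)
  expect_equal(f2$w, f1$w, tolerance = 1e-12)
})
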