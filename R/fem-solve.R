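# Assembly and solution of the linear-elastic indentation problem, and the
# three deformation features extracted from the probe bottom surface.

# Element dof table (ne x 24, interleaved x,y,z per node).
element_dofs <- function(model) {
  eld <- matrix(0L, nrow(model$elems), 24)
  for (j in 1:8) {
    eld[, 3L * j - 2L] <- model$dof[model$elems[, j], 1]
    eld[, 3L * j - 1L] <- model$dof[model$elems[, j], 2]
    eld[, 3L * j] <- model$dof[model$elems[, j], 3]
  }
  eld
}

# Raw assembly triplets: global row/col ids, unit-modulus values, and the
# owning element of every entry.  The stiffness for any modulus field is
# then a sparse reweighting of these triplets.
assembly_triplets <- function(model, eld = element_dofs(model)) {
  groups <- split(seq_len(nrow(eld)), model$group)
  row_rep <- rep(1:24, times = 24)
  col_rep <- rep(1:24, each = 24)
  ii <- jj <- kk <- ee <- vector("list", length(groups))
  for (gi in seq_along(groups)) {
    idx <- groups[[gi]]
    sz <- model$el_size[idx[1], ]
    kv <- as.vector(hex_unit_stiffness(sz[1], sz[2], sz[3], model$nu))
    dsub <- eld[idx, , drop = FALSE]
    ii[[gi]] <- as.vector(dsub[, row_rep])
    jj[[gi]] <- as.vector(dsub[, col_rep])
    kk[[gi]] <- rep(kv, each = length(idx))
    ee[[gi]] <- rep(idx, times = 576L)
  }
  list(i = unlist(ii), j = unlist(jj), k = unlist(kk), elem = unlist(ee))
}

# Sparse global stiffness for the model's element moduli.
assemble_stiffness <- function(model, trip = assembly_triplets(model)) {
  Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$k *
                         model$E_elem[trip$elem],
                       dims = c(model$ndof, model$ndof))
}

# Constrained dof ids and their prescribed values.
boundary_dofs <- function(model, indent, side_bc) {
  d <- model$dof
  fixed <- as.vector(d[model$base_nodes, ])
  top_z <- d[model$probe_top_nodes, 3]
  top_xy <- as.vector(d[model$probe_top_nodes, 1:2])
  ids <- c(fixed, top_xy, top_z)
  vals <- c(rep(0, length(fixed) + length(top_xy)), rep(-indent, length(top_z)))
  if (side_bc == "roller") {
    rx <- d[model$side_x_nodes, 1]
    ry <- d[model$side_y_nodes, 2]
    ids <- c(ids, rx, ry)
    vals <- c(vals, rep(0, length(rx) + length(ry)))
  }
  keep <- !duplicated(ids)
  list(ids = ids[keep], vals = vals[keep])
}

tissue_thickness_of <- function(model) {
  if (!is.null(model$scenario)) return(model$scenario$tissue_thickness)
  tn <- unique(as.vector(model$elems[model$region == "tissue", ]))
  max(model$coords[tn, 3])
}

# Shared linear solve: prescribed dofs eliminated, supernodal Cholesky.
solve_displacements <- function(K, ndof, bc, chol_fac = NULL) {
  free <- setdiff(seq_len(ndof), bc$ids)
  rhs <- -K[free, bc$ids, drop = FALSE] %*% bc$vals
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  fac <- tryCatch(
    if (is.null(chol_fac)) Matrix::Cholesky(Kff, LDL = FALSE, super = TRUE)
    else Matrix::update(chol_fac, Kff),
    error = function(e) stop("singular system: insufficient constraints or ",
                             "degenerate stiffness (", conditionMessage(e),
                             ")", call. = FALSE)
  )
  u <- numeric(ndof)
  u[bc$ids] <- bc$vals
  u[free] <- as.numeric(Matrix::solve(fac, rhs))
  if (!all(is.finite(u))) {
    stop("solver non-convergence: non-finite displacements")
  }
  list(u = u, fac = fac)
}

# Probe-bottom relative displacement grid from a full displacement vector.
probe_field <- function(model, u, indent) {
  w <- u[model$dof[model$probe_bottom_nodes, 3]] + indent
  nxp <- length(model$probe_xb)
  deformation_field(
    x = model$probe_xb - min(model$probe_xb),
    y = model$probe_yb - min(model$probe_yb),
    w = t(matrix(w, nrow = nxp)),
    indent = indent)
}

#' Solve the probe indentation problem
#'
#' Assembles the linear elastic stiffness system for the model, prescribes
#' a downward displacement `indent` on the probe top (with the probe top
#' held laterally), fixes the slab base, and solves the sparse symmetric
#' positive-definite system by direct supernodal Cholesky factorization.
#' Returns the *relative* vertical displacement of the probe bottom
#' surface: the nodal vertical displacement minus the rigid translation
#' `-indent` transmitted through the probe, so that a stiffer obstruction
#' under the probe yields larger positive values.
#'
#' @param model A `fem_model` from [build_model()].
#' @param indent Prescribed probe-top displacement, mm; positive, at most
#'   25% of the tissue thickness (small-strain regime).
#' @param side_bc Optional override of the lateral boundary condition
#'   (`"free"` or `"roller"`); defaults to the model's configuration.
#' @param full_solution If `TRUE`, attach the complete nodal displacement
#'   vector, dof table and coordinates to the result (for verification
#'   studies).
#' @return A `deformation_field`: a regular grid over the probe footprint
#'   (`x`, `y` in mm relative to the probe corner) with the relative
#'   vertical displacement matrix `w` (rows indexed by `y`, columns by
#'   `x`), the per-point cell area, and the indent used.
#' @export
solve_indentation <- function(model, indent = model$config$indent_mm,
                              side_bc = model$config$side_bc,
                              full_solution = FALSE) {
  stopifnot(inherits(model, "fem_model"))
  thick <- tissue_thickness_of(model)
  if (!(indent > 0 && indent <= 0.25 * thick)) {
    stop("indent must be positive and at most 25% of the tissue thickness (",
         0.25 * thick, " mm) for the small-strain model")
  }
  K <- assemble_stiffness(model)
  bc <- boundary_dofs(model, indent, side_bc)
  sol <- solve_displacements(K, model$ndof, bc)
  field <- probe_field(model, sol$u, indent)
  if (full_solution) {
    attr(field, "u") <- sol$u
    attr(field, "dof") <- model$dof
    attr(field, "coords") <- model$coords
  }
  field
}

#' Deformation field of the probe bottom surface
#'
#' @param x,y Grid coordinates in mm, relative to the probe corner.
#' @param w Matrix of relative vertical displacements, mm;
#'   `w[i, j]` corresponds to `(y[i], x[j])`.
#' @param indent Probe-top indentation that produced the field, mm.
#' @return Object of class `deformation_field`.
#' @export
deformation_field <- function(x, y, w, indent = NA_real_) {
  stopifnot(is.matrix(w), nrow(w) == length(y), ncol(w) == length(x))
  if (!all(is.finite(w))) stop("deformation field contains non-finite values")
  side_x <- max(x) - min(x)
  side_y <- max(y) - min(y)
  structure(
    list(x = x, y = y, w = w, indent = indent,
         cell_area = side_x * side_y / length(w)),
    class = "deformation_field"
  )
}

#' @export
print.deformation_field <- function(x, ...) {
  cat(sprintf(
    "<deformation_field> %d x %d grid over %g x %g mm, w in [%.4g, %.4g] mm\n",
    ncol(x$w), nrow(x$w), max(x$x) - min(x$x), max(x$y) - min(x$y),
    min(x$w), max(x$w)))
  invisible(x)
}

#' Feature triple: maximum, total, and area of deformation
#'
#' The three tactile features, in simulation units (`"FEM"`: mm, mm, mm^2)
#' or image units (`"TSIS"`: pixel value, summed pixel value, pixel count).
#'
#' @param f_max Maximum feature (mm or pixel value).
#' @param f_total Total feature (mm or pixel-value sum).
#' @param f_area Area feature (mm^2 or pixel count).
#' @param units `"FEM"` or `"TSIS"`.
#' @param validate Enforce the invariants (`f_max >= 0`, `f_area >= 0`,
#'   and `f_total >= f_max` in FEM units).  Calibrated triples produced by
#'   regression may violate them by residual error and are constructed
#'   with `validate = FALSE`.
#' @return Object of class `feature_triple`.
#' @export
feature_triple <- function(f_max, f_total, f_area, units = c("FEM", "TSIS"),
                           validate = TRUE) {
  units <- match.arg(units)
  stopifnot(is.finite(f_max), is.finite(f_total), is.finite(f_area))
  if (validate) {
    if (f_max < 0) stop("feature invariant violated: f_max must be >= 0")
    if (f_area < 0) stop("feature invariant violated: f_area must be >= 0")
    if (units == "FEM" && f_total < f_max - 1e-9) {
      stop("feature invariant violated: total deformation below maximum ",
           "deformation in FEM units")
    }
  }
  structure(list(f_max = f_max, f_total = f_total, f_area = f_area,
                 units = units),
            class = "feature_triple")
}

#' @export
print.feature_triple <- function(x, ...) {
  cat(sprintf("<feature_triple %s> max = %.6g, total = %.6g, area = %.6g\n",
              x$units, x$f_max, x$f_total, x$f_area))
  invisible(x)
}

#' Stack feature triples into a matrix
#'
#' @param features List of [feature_triple()] objects (or a single one).
#' @return Numeric matrix with columns `f_max`, `f_total`, `f_area`.
#' @export
feature_matrix <- function(features) {
  if (inherits(features, "feature_triple")) features <- list(features)
  out <- t(vapply(features, function(f) c(f$f_max, f$f_total, f$f_area),
                  numeric(3)))
  colnames(out) <- c("f_max", "f_total", "f_area")
  out
}

#' Quantify a deformation field into the three features
#'
#' Grid displacements at or below the detectability floor `floor_eps` are
#' treated as zero (the optical readout cannot register them); on the
#' floored field the features are
#'
#' * maximum deformation: the largest displacement on the probe bottom
#'   grid (mm);
#' * total deformation: the sum of grid displacements (mm);
#' * deformation area: the number of grid points whose displacement exceeds
#'   the area threshold `area_eps`, times the per-point cell area (mm^2).
#'   `area_eps` is the simulation-side analogue of the pixel threshold `k`
#'   used by [quantify_image()].
#'
#' @param field A `deformation_field`.
#' @param floor_eps Detectability floor, mm (see [fem_config()]).
#' @param area_eps Area-count threshold, mm (see [fem_config()]).
#' @return A [feature_triple()] with `units = "FEM"`.
#' @export
quantify_deformation <- function(field, floor_eps = 0.002, area_eps = 0.01) {
  stopifnot(inherits(field, "deformation_field"))
  if (length(field$w) == 0) stop("empty deformation grid")
  w <- field$w
  w[w <= floor_eps] <- 0
  feature_triple(
    f_max = max(w),
    f_total = sum(w),
    f_area = sum(w > area_eps) * field$cell_area,
    units = "FEM"
  )
}

# Baseline (homogeneous slab, no inclusion) probe-bottom field for a given
# geometry and configuration, cached across calls.
baseline_key <- function(s, config) {
  paste("baseline", s$E_bg, s$nu, s$tissue_side, s$tissue_thickness,
        s$probe_side, config$resolution, config$indent_mm,
        config$probe_modulus_kpa, config$probe_height_mm, config$side_bc,
        sep = ":")
}

homogeneous_scenario <- function(s) {
  # same geometry, inclusion stiffness infinitesimally above background so
  # the scenario validates; the modulus field is overridden to E_bg anyway
  inclusion_scenario(d = s$d, h = s$h, E_inc = s$E_bg * (1 + 1e-9),
                     E_bg = s$E_bg, nu = s$nu, tissue_side = s$tissue_side,
                     tissue_thickness = s$tissue_thickness,
                     probe_side = s$probe_side, id = "baseline")
}

#' Baseline probe deformation of the homogeneous slab
#'
#' The probe bottom deforms even without any inclusion, simply from
#' pressing into the soft slab.  This function returns that baseline field
#' for the geometry of `scenario` (the inclusion parameters are ignored);
#' results are cached per geometry and configuration.
#'
#' @param scenario An [inclusion_scenario()] supplying the geometry.
#' @param config A [fem_config()].
#' @return A `deformation_field`.
#' @export
baseline_field <- function(scenario, config = fem_config()) {
  key <- baseline_key(scenario, config)
  hit <- get0(key, envir = .palpinv_cache)
  if (!is.null(hit)) return(hit)
  m0 <- build_model(homogeneous_scenario(scenario), config)
  m0$E_elem[m0$region == "tissue"] <- scenario$E_bg
  f0 <- solve_indentation(m0)
  assign(key, f0, envir = .palpinv_cache)
  f0
}

#' Inclusion-induced deformation field
#'
#' The probe-bottom deformation attributable to the inclusion alone: the
#' scenario's relative-displacement field minus the homogeneous-slab
#' baseline field on the same mesh.  This is the signal the tactile camera
#' visualizes as a bright blob; the baseline is a smooth bowl shared by all
#' scenarios.
#'
#' @param scenario An [inclusion_scenario()].
#' @param config A [fem_config()].
#' @return A `deformation_field` (values may be slightly negative where
#'   the inclusion unloads the probe periphery).
#' @export
inclusion_field <- function(scenario, config = fem_config()) {
  model <- build_model(scenario, config)
  f <- solve_indentation(model)
  f0 <- baseline_field(scenario, config)
  deformation_field(f$x, f$y, f$w - f0$w, indent = f$indent)
}

#' Forward model: scenario to FEM feature triple
#'
#' Composition of [build_model()], [solve_indentation()] and
#' [quantify_deformation()]; deterministic for a fixed configuration.  With
#' the default `baseline = "subtract"` the features are computed from the
#' inclusion-induced field ([inclusion_field()]), so a homogeneous scenario
#' yields exactly (0, 0, 0) and the deformation area grows with the lateral
#' extent of the inclusion's mechanical footprint.  With
#' `baseline = "none"` the raw relative-displacement field is quantified,
#' baseline bowl included.
#'
#' @param scenario An [inclusion_scenario()].
#' @param config A [fem_config()].
#' @return A [feature_triple()] with `units = "FEM"`.
#' @export
fem_forward <- function(scenario, config = fem_config()) {
  if (config$baseline == "subtract") {
    field <- inclusion_field(scenario, config)
  } else {
    field <- solve_indentation(build_model(scenario, config))
  }
  quantify_deformation(field, floor_eps = config$floor_eps_mm,
                         area_eps = config$area_eps_mm)
}

#' Batch forward model over a scenario list
#'
#' Computes FEM feature triples for many scenarios sharing one fixed
#' geometry.  The mesh topology does not depend on (d, h, E), so the
#' assembly index structure, the triplet-to-slot map, the baseline solve
#' and the symbolic Cholesky factorization are computed once; per scenario
#' only the element moduli, the numeric factorization and the solve are
#' redone.  Results are identical to calling [fem_forward()] per scenario.
#'
#' @param scenarios List of scenarios with identical fixed geometry.
#' @param config A [fem_config()].
#' @param progress Print a dot per completed scenario.
#' @return Numeric matrix (`n` x 3) with columns `f_max`, `f_total`,
#'   `f_area`; row names are scenario ids.
#' @export
fem_features <- function(scenarios, config = fem_config(), progress = FALSE) {
  stopifnot(length(scenarios) >= 1)
  geom <- function(s) unlist(s[c("E_bg", "nu", "tissue_side",
                                 "tissue_thickness", "probe_side")])
  g0 <- geom(scenarios[[1]])
  same <- all(vapply(scenarios, function(s) isTRUE(all.equal(geom(s), g0)),
                     logical(1)))
  ids <- vapply(scenarios, function(s) s$id, character(1))
  if (!same) {
    out <- t(vapply(scenarios,
                    function(s) feature_matrix(fem_forward(s, config))[1, ],
                    numeric(3)))
    rownames(out) <- ids
    return(out)
  }

  model <- build_model(scenarios[[1]], config)
  trip <- assembly_triplets(model)
  bc <- boundary_dofs(model, config$indent_mm, config$side_bc)
  free <- setdiff(seq_len(model$ndof), bc$ids)

  # map triplets to slots of the assembled dgCMatrix (column-major order)
  K0 <- Matrix::sparseMatrix(i = trip$i, j = trip$j, x = trip$k,
                             dims = c(model$ndof, model$ndof))
  slot_keys <- (rep.int(seq_len(model$ndof), diff(K0@p)) - 1) * model$ndof +
    (K0@i + 1)
  trip_keys <- (trip$j - 1) * model$ndof + trip$i
  pos <- findInterval(trip_keys, slot_keys)
  # value vector of K for a modulus field E: M %*% E
  M <- Matrix::sparseMatrix(i = pos, j = trip$elem, x = trip$k,
                            dims = c(length(slot_keys), nrow(model$elems)))

  t_idx <- which(model$region == "tissue")
  p_idx <- which(model$region == "probe")
  center_for <- function(s) c(s$tissue_side / 2, s$tissue_side / 2,
                              s$tissue_thickness - (s$h + s$d / 2))
  E_base <- numeric(nrow(model$elems))
  E_base[t_idx] <- g0[["E_bg"]]
  E_base[p_idx] <- config$probe_modulus_kpa

  chol_fac <- NULL
  solve_for <- function(E_elem) {
    K0@x <- as.numeric(M %*% E_elem)
    sol <- solve_displacements(K0, model$ndof, bc, chol_fac)
    chol_fac <<- sol$fac
    u <- sol$u
    u[model$dof[model$probe_bottom_nodes, 3]] + config$indent_mm
  }

  w0 <- if (config$baseline == "subtract") solve_for(E_base) else 0

  nxp <- length(model$probe_xb)
  out <- matrix(NA_real_, length(scenarios), 3,
                dimnames = list(ids, c("f_max", "f_total", "f_area")))
  for (k in seq_along(scenarios)) {
    s <- scenarios[[k]]
    E_elem <- E_base
    if (config$partial_volume) {
      fr <- sphere_fraction(model$lo[t_idx, , drop = FALSE],
                            model$hi[t_idx, , drop = FALSE],
                            center_for(s), s$d / 2)
      if ((s$E_inc - s$E_bg) / s$E_bg > 1e-8 && max(fr) <= 0) {
        stop("resolution too coarse to resolve inclusion in scenario ", s$id)
      }
      E_elem[t_idx] <- 1 / ((1 - fr) / s$E_bg + fr / s$E_inc)
    } else {
      cen <- (model$lo[t_idx, , drop = FALSE] +
                model$hi[t_idx, , drop = FALSE]) / 2
      inside <- rowSums(sweep(cen, 2, center_for(s))^2) <= (s$d / 2)^2
      E_elem[t_idx] <- ifelse(inside, s$E_inc, s$E_bg)
    }
    w <- solve_for(E_elem) - w0
    field <- deformation_field(
      x = model$probe_xb - min(model$probe_xb),
      y = model$probe_yb - min(model$probe_yb),
      w = t(matrix(w, nrow = nxp)), indent = config$indent_mm)
    ft <- quantify_deformation(field, floor_eps = config$floor_eps_mm,
                         area_eps = config$area_eps_mm)
    out[k, ] <- c(ft$f_max, ft$f_total, ft$f_area)
    if (progress) cat(".", if (k %% 50 == 0 || k == length(scenarios)) "\n")
  }
  out
}
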