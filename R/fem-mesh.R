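# Structured hexahedral mesh machinery for the indentation forward model.
#
# All elements are axis-aligned boxes on a tensor-product grid, so the
# element stiffness matrix depends only on the box dimensions and Poisson
# ratio and scales linearly with Young's modulus; unit-modulus matrices are
# cached per geometry.

.palpinv_cache <- new.env(parent = emptyenv())

# 24x24 stiffness of a trilinear 8-node box element (hx x hy x hz, E = 1).
# Near-incompressible materials (nu ~ 0.49) lock under full integration of
# the volumetric term, so the deviatoric part is integrated with the full
# 2x2x2 Gauss rule and the volumetric part with a single central point
# (selective reduced integration).
hex_unit_stiffness <- function(hx, hy, hz, nu) {
  key <- paste("Ke", signif(hx, 12), signif(hy, 12), signif(hz, 12), nu,
               sep = ":")
  hit <- get0(key, envir = .palpinv_cache)
  if (!is.null(hit)) return(hit)

  lam <- nu / ((1 + nu) * (1 - 2 * nu))
  mu <- 1 / (2 * (1 + nu))
  bulk <- lam + 2 * mu / 3
  m <- c(1, 1, 1, 0, 0, 0)
  D_dev <- mu * diag(c(2, 2, 2, 1, 1, 1)) - (2 * mu / 3) * tcrossprod(m)
  D_vol <- bulk * tcrossprod(m)

  signs <- matrix(c(-1, -1, -1,  1, -1, -1,  1, 1, -1,  -1, 1, -1,
                    -1, -1,  1,  1, -1,  1,  1, 1,  1,  -1, 1,  1),
                  ncol = 3, byrow = TRUE)
  Bmat <- function(xi, eta, ze) {
    dNdx <- signs[, 1] / 8 * (1 + signs[, 2] * eta) * (1 + signs[, 3] * ze) * 2 / hx
    dNdy <- signs[, 2] / 8 * (1 + signs[, 1] * xi) * (1 + signs[, 3] * ze) * 2 / hy
    dNdz <- signs[, 3] / 8 * (1 + signs[, 1] * xi) * (1 + signs[, 2] * eta) * 2 / hz
    B <- matrix(0, 6, 24)
    ix <- seq(1, 24, by = 3); iy <- ix + 1L; iz <- ix + 2L
    B[1, ix] <- dNdx; B[2, iy] <- dNdy; B[3, iz] <- dNdz
    B[4, ix] <- dNdy; B[4, iy] <- dNdx
    B[5, iy] <- dNdz; B[5, iz] <- dNdy
    B[6, ix] <- dNdz; B[6, iz] <- dNdx
    B
  }

  detJ <- hx * hy * hz / 8
  g <- 1 / sqrt(3)
  Ke <- matrix(0, 24, 24)
  for (xi in c(-g, g)) for (eta in c(-g, g)) for (ze in c(-g, g)) {
    B <- Bmat(xi, eta, ze)
    Ke <- Ke + crossprod(B, D_dev %*% B) * detJ
  }
  B0 <- Bmat(0, 0, 0)
  Ke <- Ke + crossprod(B0, D_vol %*% B0) * (8 * detJ)
  Ke <- (Ke + t(Ke)) / 2
  assign(key, Ke, envir = .palpinv_cache)
  Ke
}

# Node coordinates and hexahedral connectivity of a tensor-product grid.
# Node numbering: x fastest, then y, then z.
grid3 <- function(xb, yb, zb) {
  nx <- length(xb); ny <- length(yb); nz <- length(zb)
  coords <- cbind(
    x = rep(xb, times = ny * nz),
    y = rep(rep(yb, each = nx), times = nz),
    z = rep(zb, each = nx * ny))
  nid <- function(ix, iy, iz) ix + (iy - 1L) * nx + (iz - 1L) * nx * ny
  ex <- nx - 1L; ey <- ny - 1L; ez <- nz - 1L
  exi <- rep(seq_len(ex), times = ey * ez)
  eyi <- rep(rep(seq_len(ey), each = ex), times = ez)
  ezi <- rep(seq_len(ez), each = ex * ey)
  elems <- cbind(
    nid(exi,      eyi,      ezi),
    nid(exi + 1L, eyi,      ezi),
    nid(exi + 1L, eyi + 1L, ezi),
    nid(exi,      eyi + 1L, ezi),
    nid(exi,      eyi,      ezi + 1L),
    nid(exi + 1L, eyi,      ezi + 1L),
    nid(exi + 1L, eyi + 1L, ezi + 1L),
    nid(exi,      eyi + 1L, ezi + 1L))
  lo <- cbind(xb[exi], yb[eyi], zb[ezi])
  hi <- cbind(xb[exi + 1L], yb[eyi + 1L], zb[ezi + 1L])
  list(coords = coords, elems = elems, lo = lo, hi = hi,
       nx = nx, ny = ny, nz = nz)
}

# Lateral break points: a uniform fine window (probe footprint plus one
# fine cell of margin per side) flanked by a few graded coarse cells.
tensor_breaks <- function(side, probe_side, hf, n_coarse = 3L) {
  c0 <- (side - probe_side) / 2
  lo <- c0 - hf
  hi <- side - c0 + hf
  if (lo <= hf / 2) {
    return(seq(0, side, length.out = round(side / hf) + 1L))
  }
  fine <- seq(lo, hi, by = hf)
  coarse <- seq(0, lo, length.out = n_coarse + 1L)
  sort(unique(round(c(coarse, fine, side - coarse), 9)))
}

#' Forward-model configuration
#'
#' Numerical controls for [build_model()], [solve_indentation()] and
#' [fem_forward()].
#'
#' @param resolution Mesh-density multiplier.  At `resolution = 1` the
#'   probe footprint spans 10 elements per side (2.5 mm cells for the
#'   default 25 mm probe) and the slab thickness 10 element layers;
#'   `resolution = 2` halves every cell size.
#' @param indent_mm Prescribed downward displacement of the probe top, mm.
#'   Must stay below 25% of the tissue thickness (small-strain regime).
#' @param probe_modulus_kpa Young's modulus of the homogeneous probe block.
#' @param probe_height_mm Probe block height, mm.
#' @param floor_eps_mm Detectability floor, mm: probe-bottom displacements
#'   at or below this value are treated as zero by
#'   [quantify_deformation()], emulating the finite sensitivity of the
#'   optical readout (default 2 micrometres).
#' @param area_eps_mm Area-count threshold, mm: the deformation area counts
#'   grid points whose floored displacement exceeds this value (default
#'   10 micrometres), mirroring the pixel threshold `k` of the image-side
#'   area feature.
#' @param side_bc Lateral boundary condition on the slab sides: `"free"`
#'   (traction-free, the physical default) or `"roller"` (zero normal
#'   displacement; used for confined-compression verification problems).
#' @param partial_volume If `TRUE` (default), elements straddling the
#'   inclusion boundary receive a modulus blended harmonically (Reuss
#'   bound, appropriate for the series-compliance load path) by the
#'   sub-sampled volume fraction of inclusion material, which keeps the
#'   forward map smooth in `d` even when the sphere is only one or two
#'   cells wide.  If `FALSE`,
#'   elements are tagged inclusion/background purely by their centroid, and
#'   the mesh must resolve the sphere with at least two cells per diameter.
#' @param baseline Feature extraction reference for [fem_forward()] and
#'   [fem_features()]: `"subtract"` (default) quantifies the
#'   inclusion-induced field (scenario field minus the homogeneous-slab
#'   baseline on the same mesh); `"none"` quantifies the raw
#'   relative-displacement field, baseline bowl included.
#' @return Named list of class `fem_config`.
#' @export
fem_config <- function(resolution = 1, indent_mm = 4, probe_modulus_kpa = 100,
                       probe_height_mm = 10, floor_eps_mm = 0.002,
                       area_eps_mm = 0.01,
                       side_bc = c("free", "roller"), partial_volume = TRUE,
                       baseline = c("subtract", "none")) {
  stopifnot(resolution > 0, indent_mm > 0, probe_modulus_kpa > 0,
            probe_height_mm > 0, floor_eps_mm >= 0,
            area_eps_mm >= floor_eps_mm)
  structure(
    list(resolution = resolution, indent_mm = indent_mm,
         probe_modulus_kpa = probe_modulus_kpa,
         probe_height_mm = probe_height_mm, floor_eps_mm = floor_eps_mm,
         area_eps_mm = area_eps_mm,
         side_bc = match.arg(side_bc), partial_volume = partial_volume,
         baseline = match.arg(baseline)),
    class = "fem_config"
  )
}

# Volume fraction of each element box lying inside the sphere, by sub-cell
# sampling (nsub^3 regular sample points per element).
sphere_fraction <- function(lo, hi, center, radius, nsub = 4L) {
  ne <- nrow(lo)
  frac <- numeric(ne)
  touch <- which(
    lo[, 1] < center[1] + radius & hi[, 1] > center[1] - radius &
    lo[, 2] < center[2] + radius & hi[, 2] > center[2] - radius &
    lo[, 3] < center[3] + radius & hi[, 3] > center[3] - radius)
  if (!length(touch)) return(frac)
  tl <- lo[touch, , drop = FALSE]
  th <- hi[touch, , drop = FALSE]
  dx <- th - tl
  offs <- (seq_len(nsub) - 0.5) / nsub
  count <- numeric(length(touch))
  for (ox in offs) for (oy in offs) for (oz in offs) {
    px <- tl[, 1] + ox * dx[, 1] - center[1]
    py <- tl[, 2] + oy * dx[, 2] - center[2]
    pz <- tl[, 3] + oz * dx[, 3] - center[3]
    count <- count + (px * px + py * py + pz * pz <= radius * radius)
  }
  frac[touch] <- count / nsub^3
  frac
}

#' Build the finite-element model for a scenario
#'
#' Meshes the tissue slab and the probe block with trilinear hexahedra on a
#' structured tensor grid (a uniform fine window under and around the probe
#' footprint, graded coarse cells towards the slab sides), assigns element
#' moduli from the spherical inclusion, and tags boundary node sets.
#'
#' The probe rests on the tissue through a frictionless tied interface:
#' coincident probe-bottom and tissue-top nodes share their vertical degree
#' of freedom but keep independent lateral ones, approximating frictionless
#' contact without lift-off.
#'
#' @param scenario An [inclusion_scenario()].
#' @param config A [fem_config()].
#' @return An object of class `fem_model`.
#' @export
build_model <- function(scenario, config = fem_config()) {
  stopifnot(inherits(scenario, "inclusion_scenario"))
  if (!inherits(config, "fem_config")) config <- do.call(fem_config, config)
  s <- scenario
  res <- config$resolution

  n_lat <- max(2L, round(10 * res))
  hf <- s$probe_side / n_lat
  nzt <- max(2L, round(10 * res))
  hz <- s$tissue_thickness / nzt

  if (s$h + s$d > s$tissue_thickness + 1e-9) {
    stop("inclusion not fully inside tissue: h + d exceeds tissue thickness")
  }
  if (!config$partial_volume && max(hf, hz) > s$d / 2 + 1e-9) {
    stop("resolution too coarse to resolve inclusion: need at least two ",
         "elements across the ", s$d, " mm diameter (cells ",
         signif(max(hf, hz), 3), " mm); increase resolution")
  }

  xb <- tensor_breaks(s$tissue_side, s$probe_side, hf)
  zb <- seq(0, s$tissue_thickness, length.out = nzt + 1L)
  tg <- grid3(xb, xb, zb)
  ntt <- nrow(tg$coords)

  c0 <- (s$tissue_side - s$probe_side) / 2
  xpb <- xb[xb >= c0 - 1e-9 & xb <= s$tissue_side - c0 + 1e-9]
  npz <- max(2L, round(4 * res))
  zpb <- seq(s$tissue_thickness, s$tissue_thickness + config$probe_height_mm,
             length.out = npz + 1L)
  pg <- grid3(xpb, xpb, zpb)
  npp <- nrow(pg$coords)

  coords <- rbind(tg$coords, pg$coords)
  elems <- rbind(tg$elems, pg$elems + ntt)
  lo <- rbind(tg$lo, pg$lo)
  hi <- rbind(tg$hi, pg$hi)
  ne_t <- nrow(tg$elems)
  region <- rep(c("tissue", "probe"), c(ne_t, nrow(pg$elems)))

  # probe-bottom nodes coincide with tissue-top nodes in the footprint
  nxp <- pg$nx
  pb_local <- seq_len(nxp * nxp)                       # probe grid layer iz = 1
  ix_t <- match(round(xpb, 8), round(xb, 8))
  tissue_top_match <- outer(ix_t, (ix_t - 1L) * tg$nx, "+") +
    (length(zb) - 1L) * tg$nx * tg$ny
  tissue_top_match <- as.vector(tissue_top_match)       # tissue ids, x fastest

  # degrees of freedom: tissue nodes own 3 each; probe nodes own x and y,
  # and z unless on the tied interface (shared with the matched tissue node)
  dof <- matrix(0L, nrow(coords), 3)
  dof[seq_len(ntt), ] <- matrix(seq_len(3L * ntt), ncol = 3, byrow = TRUE)
  nxt_dof <- 3L * ntt
  dof[ntt + seq_len(npp), 1] <- nxt_dof + seq_len(npp)
  nxt_dof <- nxt_dof + npp
  dof[ntt + seq_len(npp), 2] <- nxt_dof + seq_len(npp)
  nxt_dof <- nxt_dof + npp
  zdof <- integer(npp)
  interface <- seq_len(npp) %in% pb_local
  zdof[interface] <- dof[tissue_top_match, 3]
  zdof[!interface] <- nxt_dof + seq_len(sum(!interface))
  nxt_dof <- nxt_dof + sum(!interface)
  dof[ntt + seq_len(npp), 3] <- zdof
  ndof <- nxt_dof

  # materials
  center <- c(s$tissue_side / 2, s$tissue_side / 2,
              s$tissue_thickness - (s$h + s$d / 2))
  radius <- s$d / 2
  E_elem <- numeric(nrow(elems))
  frac <- numeric(nrow(elems))
  t_idx <- which(region == "tissue")
  if (config$partial_volume) {
    fr <- sphere_fraction(lo[t_idx, , drop = FALSE], hi[t_idx, , drop = FALSE],
                          center, radius)
    if ((s$E_inc - s$E_bg) / s$E_bg > 1e-8 && max(fr) <= 0) {
      stop("resolution too coarse to resolve inclusion: no element samples ",
           "the ", s$d, " mm sphere; increase resolution")
    }
    frac[t_idx] <- fr
    E_elem[t_idx] <- 1 / ((1 - fr) / s$E_bg + fr / s$E_inc)
  } else {
    cen <- (lo[t_idx, , drop = FALSE] + hi[t_idx, , drop = FALSE]) / 2
    inside <- rowSums(sweep(cen, 2, center)^2) <= radius^2
    frac[t_idx] <- as.numeric(inside)
    E_elem[t_idx] <- ifelse(inside, s$E_inc, s$E_bg)
  }
  E_elem[region == "probe"] <- config$probe_modulus_kpa
  cen_all <- (lo + hi) / 2
  inclusion_mask <- region == "tissue" &
    rowSums(sweep(cen_all, 2, center)^2) <= radius^2

  # boundary node sets
  eps <- 1e-8
  base_nodes <- which(coords[, 3] < eps)
  probe_top_nodes <- ntt + which(pg$coords[, 3] >
                                   max(zpb) - eps)
  probe_bottom_nodes <- ntt + pb_local
  side_x_nodes <- which(coords[, 1] < eps |
                          coords[, 1] > s$tissue_side - eps)
  side_y_nodes <- which(coords[, 2] < eps |
                          coords[, 2] > s$tissue_side - eps)
  if (length(intersect(base_nodes, probe_top_nodes))) {
    stop("degenerate model: base and probe-top node sets overlap")
  }

  el_size <- hi - lo
  if (any(el_size <= 0)) stop("degenerate mesh: non-positive element volume")
  gkey <- paste(signif(el_size[, 1], 9), signif(el_size[, 2], 9),
                signif(el_size[, 3], 9), sep = "x")

  structure(
    list(coords = coords, dof = dof, ndof = ndof, elems = elems,
         lo = lo, hi = hi, el_size = el_size, group = gkey,
         E_elem = E_elem, nu = s$nu, region = region,
         inclusion_mask = inclusion_mask, inclusion_frac = frac,
         base_nodes = base_nodes, probe_top_nodes = probe_top_nodes,
         probe_bottom_nodes = probe_bottom_nodes,
         tissue_top_under_probe = tissue_top_match,
         side_x_nodes = side_x_nodes, side_y_nodes = side_y_nodes,
         probe_xb = xpb, probe_yb = xpb,
         scenario = s, config = config),
    class = "fem_model"
  )
}

#' @export
print.fem_model <- function(x, ...) {
  cat(sprintf(
    "<fem_model> %d nodes, %d elements (%d tissue / %d probe), %d dofs\n",
    nrow(x$coords), nrow(x$elems), sum(x$region == "tissue"),
    sum(x$region == "probe"), x$ndof))
  cat(sprintf("  inclusion: d = %g mm at depth %g mm, E = %g kPa (bg %g kPa)\n",
              x$scenario$d, x$scenario$h, x$scenario$E_inc, x$scenario$E_bg))
  invisible(x)
}

#' Export / import a finite-element model as plain text
#'
#' A simple self-contained mesh format: a node table (coordinates and
#' degree-of-freedom ids, which encode the tied probe-tissue interface), an
#' element table (connectivity, modulus, region), and the boundary node
#' sets.  `read_fem_model` reconstructs a model that [solve_indentation()]
#' accepts.
#'
#' @param model A `fem_model`.
#' @param path File path.
#' @return `read_fem_model` returns a `fem_model`; `write_fem_model`
#'   returns `path` invisibly.
#' @export
write_fem_model <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wl <- function(...) writeLines(paste0(...), con)
  wl("palpinv-mesh v1")
  wl("nu ", formatC(model$nu, format = "g", digits = 17))
  wl("ndof ", model$ndof)
  wl("nodes ", nrow(model$coords))
  utils::write.table(
    cbind(format(model$coords, digits = 17, trim = TRUE), model$dof),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  wl("elements ", nrow(model$elems))
  utils::write.table(
    cbind(model$elems, format(model$E_elem, digits = 17, trim = TRUE),
          model$region),
    con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  for (nm in c("base_nodes", "probe_top_nodes", "probe_bottom_nodes",
               "side_x_nodes", "side_y_nodes")) {
    wl(nm, " ", paste(model[[nm]], collapse = " "))
  }
  wl("probe_xb ", paste(format(model$probe_xb, digits = 17, trim = TRUE),
                        collapse = " "))
  invisible(path)
}

#' @rdname write_fem_model
#' @export
read_fem_model <- function(path) {
  lines <- readLines(path)
  if (!identical(lines[1], "palpinv-mesh v1")) {
    stop("not a palpinv mesh file (missing 'palpinv-mesh v1' header)")
  }
  nu <- as.numeric(strsplit(lines[2], " ")[[1]][2])
  ndof <- as.integer(strsplit(lines[3], " ")[[1]][2])
  nn <- as.integer(strsplit(lines[4], " ")[[1]][2])
  node_rows <- lines[4L + seq_len(nn)]
  nodes <- do.call(rbind, strsplit(trimws(node_rows), "\\s+"))
  coords <- matrix(as.numeric(nodes[, 1:3]), ncol = 3,
                   dimnames = list(NULL, c("x", "y", "z")))
  dof <- matrix(as.integer(nodes[, 4:6]), ncol = 3)
  at <- 5L + nn
  ne <- as.integer(strsplit(lines[at], " ")[[1]][2])
  el_rows <- lines[at + seq_len(ne)]
  em <- do.call(rbind, strsplit(trimws(el_rows), "\\s+"))
  elems <- matrix(as.integer(em[, 1:8]), ncol = 8)
  E_elem <- as.numeric(em[, 9])
  region <- em[, 10]
  at <- at + ne
  sets <- list()
  for (k in 1:5) {
    parts <- strsplit(trimws(lines[at + k]), "\\s+")[[1]]
    sets[[parts[1]]] <- as.integer(parts[-1])
  }
  parts <- strsplit(trimws(lines[at + 6L]), "\\s+")[[1]]
  probe_xb <- as.numeric(parts[-1])

  lo <- cbind(
    pmin(coords[elems[, 1], 1], coords[elems[, 7], 1]),
    pmin(coords[elems[, 1], 2], coords[elems[, 7], 2]),
    pmin(coords[elems[, 1], 3], coords[elems[, 7], 3]))
  hi <- cbind(
    pmax(coords[elems[, 1], 1], coords[elems[, 7], 1]),
    pmax(coords[elems[, 1], 2], coords[elems[, 7], 2]),
    pmax(coords[elems[, 1], 3], coords[elems[, 7], 3]))
  el_size <- hi - lo
  gkey <- paste(signif(el_size[, 1], 9), signif(el_size[, 2], 9),
                signif(el_size[, 3], 9), sep = "x")
  structure(
    list(coords = coords, dof = dof, ndof = ndof, elems = elems,
         lo = lo, hi = hi, el_size = el_size, group = gkey,
         E_elem = E_elem, nu = nu, region = region,
         inclusion_mask = NULL, inclusion_frac = NULL,
         base_nodes = sets$base_nodes,
         probe_top_nodes = sets$probe_top_nodes,
         probe_bottom_nodes = sets$probe_bottom_nodes,
         side_x_nodes = sets$side_x_nodes, side_y_nodes = sets$side_y_nodes,
         probe_xb = probe_xb, probe_yb = probe_xb,
         scenario = NULL, config = fem_config()),
    class = "fem_model"
  )
}
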