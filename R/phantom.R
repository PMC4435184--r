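#' Fixed tissue and probe geometry defaults
#'
#' The estimation problem is posed on an idealized breast model: a flat
#' tissue slab of constant thickness resting on a rigid (bone-like) base,
#' indented from above by a square elastic sensing probe.  These defaults
#' give the slab a 120 mm x 120 mm cross-section, 20 mm thickness, a
#' 25 mm x 25 mm probe footprint, a 5 kPa background modulus and a
#' Poisson ratio of 0.49 (nearly incompressible soft tissue).
#'
#' @return Named list with elements `E_bg_kPa`, `nu`, `tissue_side_mm`,
#'   `tissue_thickness_mm`, `probe_side_mm`.
#' @export
tissue_defaults <- function() {
  list(
    E_bg_kPa = 5,
    nu = 0.49,
    tissue_side_mm = 120,
    tissue_thickness_mm = 20,
    probe_side_mm = 25
  )
}

#' Construct an inclusion scenario
#'
#' An `inclusion_scenario` bundles the three unknowns of the inverse
#' problem -- inclusion diameter `d` (mm), inclusion depth `h` (mm), and
#' inclusion Young's modulus `E_inc` (kPa) -- with the fixed tissue and
#' probe geometry.  The inclusion is a sphere centered on the probe axis.
#'
#' **Depth convention.** `h` is measured from the tissue surface to the
#' *top* of the inclusion, so the sphere center sits at depth `h + d/2`.
#' The constraint `h + d <= tissue_thickness` keeps the inclusion fully
#' inside the slab.
#'
#' @param d Inclusion diameter, mm (> 0).
#' @param h Depth from tissue surface to inclusion top, mm (>= 0).
#' @param E_inc Inclusion Young's modulus, kPa; must exceed `E_bg`.
#' @param E_bg Background tissue Young's modulus, kPa (> 0).
#' @param nu Poisson's ratio, in (0, 0.5).
#' @param tissue_side Lateral tissue extent, mm.
#' @param tissue_thickness Tissue slab thickness, mm.
#' @param probe_side Probe footprint edge, mm.
#' @param id Optional scenario identifier (character).
#' @return An object of class `inclusion_scenario`.
#' @examples
#' sc <- inclusion_scenario(d = 8, h = 5, E_inc = 120)
#' sc$d
#' @export
inclusion_scenario <- function(d, h, E_inc,
                               E_bg = tissue_defaults()$E_bg_kPa,
                               nu = tissue_defaults()$nu,
                               tissue_side = tissue_defaults()$tissue_side_mm,
                               tissue_thickness = tissue_defaults()$tissue_thickness_mm,
                               probe_side = tissue_defaults()$probe_side_mm,
                               id = NA_character_) {
  stopifnot(is.numeric(d), is.numeric(h), is.numeric(E_inc), length(d) == 1L,
            length(h) == 1L, length(E_inc) == 1L)
  d <- unname(d); h <- unname(h); E_inc <- unname(E_inc)
  E_bg <- unname(E_bg); nu <- unname(nu)
  if (!(d > 0)) stop("invalid scenario: inclusion diameter d must be > 0")
  if (!(h >= 0)) stop("invalid scenario: inclusion depth h must be >= 0")
  if (!(h + d <= tissue_thickness + 1e-9)) {
    stop("invalid scenario: h + d <= tissue_thickness violated (inclusion ",
         "extends below the slab base)")
  }
  if (!(E_bg > 0)) stop("invalid scenario: E_bg must be > 0")
  if (!(E_inc > E_bg)) {
    stop("invalid scenario: E_inc > E_bg violated (inclusion must be ",
         "stiffer than background)")
  }
  if (!(nu > 0 && nu < 0.5)) stop("invalid scenario: nu must lie in (0, 0.5)")
  if (!(probe_side > 0 && probe_side <= tissue_side)) {
    stop("invalid scenario: probe_side must be positive and no wider than ",
         "tissue_side")
  }
  structure(
    list(d = d, h = h, E_inc = E_inc, E_bg = E_bg, nu = nu,
         tissue_side = tissue_side, tissue_thickness = tissue_thickness,
         probe_side = probe_side, id = id),
    class = "inclusion_scenario"
  )
}

#' @export
print.inclusion_scenario <- function(x, ...) {
  cat(sprintf(
    "<inclusion_scenario%s> d = %g mm, h = %g mm, E_inc = %g kPa (bg %g kPa, nu %g)\n",
    if (is.na(x$id)) "" else paste0(" ", x$id), x$d, x$h, x$E_inc, x$E_bg, x$nu))
  invisible(x)
}

#' Sampling ranges for scenario parameters
#'
#' Closed intervals from which [sample_scenarios()] draws (d, h, E) triples.
#' Defaults bracket the concrete inclusion values the calibration phantoms
#' use: diameters 2-14 mm, depths 3-12 mm, moduli 20-120 kPa.
#'
#' @param d_range,h_range,E_range Length-2 numeric vectors `c(lo, hi)` in
#'   mm, mm, kPa respectively.
#' @return An object of class `scenario_ranges`.
#' @export
scenario_ranges <- function(d_range = c(2, 14),
                            h_range = c(3, 12),
                            E_range = c(20, 120)) {
  chk <- function(r, nm, lo_min) {
    if (length(r) != 2L || !is.numeric(r) || r[2] < r[1])
      stop("invalid range for ", nm, ": need c(lo, hi) with hi >= lo")
    if (r[1] < lo_min)
      stop("invalid range for ", nm, ": lower bound must be >= ", lo_min)
    r
  }
  structure(
    list(d_range = chk(d_range, "d_range", .Machine$double.eps),
         h_range = chk(h_range, "h_range", 0),
         E_range = chk(E_range, "E_range", .Machine$double.eps)),
    class = "scenario_ranges"
  )
}

#' Randomly sample inclusion scenarios
#'
#' Draws `n` independent (d, h, E) triples uniformly from `ranges`,
#' rejecting and redrawing any triple that violates
#' `h + d <= tissue_thickness`, and attaching the fixed geometry.  The
#' result is a pure function of `(n, ranges, seed)`.
#'
#' @param n Number of scenarios (>= 1).
#' @param ranges A [scenario_ranges()] object.
#' @param seed Integer seed; identical seeds give identical scenario lists.
#' @param geometry Fixed geometry, as from [tissue_defaults()].
#' @return List of `n` [inclusion_scenario()] objects with ids
#'   `"s001", "s002", ...`.
#' @export
sample_scenarios <- function(n, ranges = scenario_ranges(), seed = 0,
                             geometry = tissue_defaults()) {
  stopifnot(n >= 1, inherits(ranges, "scenario_ranges"))
  thick <- geometry$tissue_thickness_mm
  if (ranges$d_range[1] + ranges$h_range[1] > thick) {
    stop("infeasible ranges: no (d, h) satisfies h + d <= tissue_thickness (",
         thick, " mm)")
  }
  if (ranges$E_range[1] <= geometry$E_bg_kPa) {
    stop("infeasible ranges: E_range lower bound must exceed the background ",
         "modulus E_bg = ", geometry$E_bg_kPa, " kPa")
  }
  draw <- function(m, r) stats::runif(m, r[1], r[2])
  triples <- withr::with_seed(seed, {
    d <- draw(n, ranges$d_range)
    h <- draw(n, ranges$h_range)
    E <- draw(n, ranges$E_range)
    repeat {
      bad <- which(h + d > thick)
      if (!length(bad)) break
      d[bad] <- draw(length(bad), ranges$d_range)
      h[bad] <- draw(length(bad), ranges$h_range)
    }
    cbind(d, h, E)
  })
  lapply(seq_len(n), function(i) {
    inclusion_scenario(
      d = triples[i, 1], h = triples[i, 2], E_inc = triples[i, 3],
      E_bg = geometry$E_bg_kPa, nu = geometry$nu,
      tissue_side = geometry$tissue_side_mm,
      tissue_thickness = geometry$tissue_thickness_mm,
      probe_side = geometry$probe_side_mm,
      id = sprintf("s%03d", i))
  })
}

#' Calibration phantom configuration
#'
#' The calibration set consists of three physical phantoms -- a size
#' phantom, a depth phantom and a hardness phantom -- each holding three
#' inclusions, nine in total.  Within each phantom one parameter is varied
#' over a three-point grid while the other two stay at their defaults.
#'
#' @param size_grid Three inclusion diameters, mm.
#' @param depth_grid Three inclusion depths, mm.
#' @param modulus_grid Three inclusion moduli, kPa.
#' @param d_default,h_default,E_default Values of the parameters held fixed.
#' @param geometry Fixed geometry, as from [tissue_defaults()].
#' @return Named list of class `calibration_config`.
#' @export
calibration_config <- function(size_grid = c(2, 8, 14),
                               depth_grid = c(3, 6, 9),
                               modulus_grid = c(40, 80, 120),
                               d_default = 8, h_default = 5, E_default = 120,
                               geometry = tissue_defaults()) {
  for (g in list(size_grid, depth_grid, modulus_grid)) {
    if (length(g) != 3L || !is.numeric(g))
      stop("each calibration grid must hold exactly three numeric values")
  }
  structure(
    list(size_grid = size_grid, depth_grid = depth_grid,
         modulus_grid = modulus_grid, d_default = d_default,
         h_default = h_default, E_default = E_default, geometry = geometry),
    class = "calibration_config"
  )
}

#' Generate the nine calibration-phantom scenarios
#'
#' Deterministically expands a [calibration_config()] into 9 scenarios:
#' three varying diameter only, three varying depth only, three varying
#' modulus only.  Ids are `"cal-size-1"`, ..., `"cal-mod-3"`, and each
#' scenario carries a `"phantom"` attribute naming its group.
#'
#' @param config A [calibration_config()].
#' @return List of 9 [inclusion_scenario()] objects.
#' @export
calibration_scenarios <- function(config = calibration_config()) {
  stopifnot(inherits(config, "calibration_config"))
  g <- config$geometry
  mk <- function(d, h, E, id, phantom) {
    sc <- inclusion_scenario(
      d = d, h = h, E_inc = E, E_bg = g$E_bg_kPa, nu = g$nu,
      tissue_side = g$tissue_side_mm,
      tissue_thickness = g$tissue_thickness_mm,
      probe_side = g$probe_side_mm, id = id)
    attr(sc, "phantom") <- phantom
    sc
  }
  c(
    lapply(1:3, function(i) mk(config$size_grid[i], config$h_default,
                               config$E_default,
                               sprintf("cal-size-%d", i), "size")),
    lapply(1:3, function(i) mk(config$d_default, config$depth_grid[i],
                               config$E_default,
                               sprintf("cal-depth-%d", i), "depth")),
    lapply(1:3, function(i) mk(config$d_default, config$h_default,
                               config$modulus_grid[i],
                               sprintf("cal-mod-%d", i), "hardness"))
  )
}

#' Study scenario set: random triples plus the calibration nine
#'
#' Builds the full scenario set the inversion study trains on: `n - 9`
#' randomly sampled scenarios plus the 9 calibration-phantom scenarios, so
#' the calibration inclusions are a subset of the study set by
#' construction.  With the default `n = 134` this reproduces the study
#' design of 134 forward simulations of which 9 correspond to the physical
#' calibration phantoms.
#'
#' @param n Total number of scenarios (> 9).
#' @param seed Seed forwarded to [sample_scenarios()].
#' @param ranges Sampling ranges for the random part.
#' @param config Calibration-phantom configuration.
#' @return List of `n` scenarios; the attribute `"calibration_ids"` holds
#'   the ids of the 9 calibration scenarios.
#' @export
study_scenarios <- function(n = 134, seed = 0, ranges = scenario_ranges(),
                            config = calibration_config()) {
  stopifnot(n > 9)
  rand <- sample_scenarios(n - 9L, ranges = ranges, seed = seed,
                           geometry = config$geometry)
  cal <- calibration_scenarios(config)
  out <- c(rand, cal)
  attr(out, "calibration_ids") <- vapply(cal, function(s) s$id, character(1))
  out
}

#' Convert a scenario list to a data frame
#'
#' @param scenarios List of [inclusion_scenario()] objects.
#' @return `data.frame` with the canonical column layout
#'   `id, d_mm, h_mm, E_inc_kPa, E_bg_kPa, nu, tissue_side_mm,
#'   tissue_thickness_mm, probe_side_mm`.
#' @export
scenario_table <- function(scenarios) {
  stopifnot(length(scenarios) >= 1)
  data.frame(
    id = vapply(scenarios, function(s) s$id, character(1)),
    d_mm = vapply(scenarios, function(s) s$d, numeric(1)),
    h_mm = vapply(scenarios, function(s) s$h, numeric(1)),
    E_inc_kPa = vapply(scenarios, function(s) s$E_inc, numeric(1)),
    E_bg_kPa = vapply(scenarios, function(s) s$E_bg, numeric(1)),
    nu = vapply(scenarios, function(s) s$nu, numeric(1)),
    tissue_side_mm = vapply(scenarios, function(s) s$tissue_side, numeric(1)),
    tissue_thickness_mm = vapply(scenarios, function(s) s$tissue_thickness,
                                 numeric(1)),
    probe_side_mm = vapply(scenarios, function(s) s$probe_side, numeric(1)),
    stringsAsFactors = FALSE
  )
}

#' Write / read scenario lists as CSV
#'
#' @param scenarios List of scenarios.
#' @param path File path.
#' @return `read_scenarios` returns a list of [inclusion_scenario()]
#'   objects; `write_scenarios` returns `path` invisibly.
#' @export
write_scenarios <- function(scenarios, path) {
  utils::write.csv(scenario_table(scenarios), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_scenarios
#' @export
read_scenarios <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "d_mm", "h_mm", "E_inc_kPa", "E_bg_kPa", "nu",
            "tissue_side_mm", "tissue_thickness_mm", "probe_side_mm")
  if (!all(need %in% names(df))) {
    stop("scenario CSV must have columns: ", paste(need, collapse = ", "))
  }
  lapply(seq_len(nrow(df)), function(i) {
    inclusion_scenario(
      d = df$d_mm[i], h = df$h_mm[i], E_inc = df$E_inc_kPa[i],
      E_bg = df$E_bg_kPa[i], nu = df$nu[i],
      tissue_side = df$tissue_side_mm[i],
      tissue_thickness = df$tissue_thickness_mm[i],
      probe_side = df$probe_side_mm[i], id = as.character(df$id[i]))
  })
}

#' Write / read flat key = value configuration files
#'
#' A minimal flat text format: one `key = value` pair per line, `#`
#' comments allowed, values either a single number or a comma-separated
#' numeric vector.
#'
#' @param config Named list of numeric scalars/vectors.
#' @param path File path.
#' @return `read_config` returns a named list; `write_config` returns
#'   `path` invisibly.
#' @export
write_config <- function(config, path) {
  stopifnot(is.list(config), !is.null(names(config)))
  lines <- vapply(names(config), function(k) {
    v <- config[[k]]
    sprintf("%s = %s", k, paste(formatC(v, format = "g", digits = 17),
                                collapse = ", "))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("malformed config line: ", ln)
    key <- trimws(parts[1])
    vals <- as.numeric(trimws(strsplit(parts[2], ",", fixed = TRUE)[[1]]))
    if (anyNA(vals)) stop("non-numeric value for config key: ", key)
    out[[key]] <- vals
  }
  out
}
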