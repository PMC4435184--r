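# Per-channel linear calibration mapping image-domain (TSIS) features into
# simulation-domain (FEM) feature units, so tactile images can feed an
# inverter trained on simulated features.

#' Fit the TSIS-to-FEM calibration map
#'
#' Ordinary least-squares regression per feature channel with the TSIS
#' (pixel) feature as predictor and the FEM (simulation) feature as
#' response, fitted on paired observations of the calibration phantoms.
#' The regression direction follows deployment: images arrive in pixel
#' units and must be mapped into the simulation units the inversion
#' network was trained in.
#'
#' @param tsis List of [feature_triple()]s (or an `n` x 3 matrix) in TSIS
#'   units.
#' @param fem Paired list of [feature_triple()]s (or matrix) in FEM units.
#' @return Object of class `calibration_map`: per-channel slope, intercept
#'   and coefficient of determination, plus the number of points used.
#' @export
fit_calibration <- function(tsis, fem) {
  X <- if (is.matrix(tsis)) tsis else feature_matrix(tsis)
  Y <- if (is.matrix(fem)) fem else feature_matrix(fem)
  if (nrow(X) != nrow(Y)) stop("tsis and fem feature lists must be paired")
  if (nrow(X) < 2) stop("calibration needs at least 2 paired points")
  channels <- c("max", "total", "area")
  co <- matrix(NA_real_, 3, 3, dimnames = list(channels,
                                               c("slope", "intercept", "r2")))
  for (ch in 1:3) {
    if (stats::sd(X[, ch]) == 0) {
      stop("degenerate predictor: TSIS '", channels[ch],
           "' channel has zero variance")
    }
    fit <- stats::lm(Y[, ch] ~ X[, ch])
    co[ch, 1:2] <- rev(unname(stats::coef(fit)))
    # summary.lm warns on exact fits; a perfect calibration is legitimate
    co[ch, 3] <- suppressWarnings(summary(fit)$r.squared)
  }
  structure(list(coef = co, n_points = nrow(X)), class = "calibration_map")
}

#' @export
print.calibration_map <- function(x, ...) {
  cat(sprintf("<calibration_map> fitted on %d paired points\n", x$n_points))
  print(round(x$coef, 6))
  invisible(x)
}

#' Apply a calibration map to TSIS features
#'
#' Per-channel affine transform into FEM units; the area channel is floored
#' at zero (a negative deformed area is not physical).
#'
#' @param map A `calibration_map` from [fit_calibration()].
#' @param tsis A [feature_triple()] in TSIS units, a list of them, or an
#'   `n` x 3 matrix.
#' @return Same shape as the input, in FEM units: a [feature_triple()] for
#'   a single triple, otherwise a matrix.
#' @export
apply_calibration <- function(map, tsis) {
  stopifnot(inherits(map, "calibration_map"))
  single <- inherits(tsis, "feature_triple")
  X <- if (is.matrix(tsis)) tsis else feature_matrix(tsis)
  Y <- sweep(sweep(X, 2, map$coef[, "slope"], "*"), 2,
             map$coef[, "intercept"], "+")
  Y[, 3] <- pmax(Y[, 3], 0)
  colnames(Y) <- colnames(X)
  if (single) {
    feature_triple(Y[1, 1], Y[1, 2], Y[1, 3], units = "FEM",
                   validate = FALSE)
  } else {
    Y
  }
}

#' Write / read a calibration map as plain text
#'
#' Three `channel slope intercept r2` rows plus a header; numbers are
#' written with 17 significant digits so the map round-trips bit-exactly.
#'
#' @param map A `calibration_map`.
#' @param path File path.
#' @return `read_calibration` returns a `calibration_map`;
#'   `write_calibration` returns `path` invisibly.
#' @export
write_calibration <- function(map, path) {
  stopifnot(inherits(map, "calibration_map"))
  lines <- c(
    paste("palpinv-calibration v1 n_points", map$n_points),
    vapply(rownames(map$coef), function(ch) {
      paste(ch, paste(sprintf("%.17g", map$coef[ch, ]), collapse = " "))
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  lines <- readLines(path)
  head <- strsplit(lines[1], " ")[[1]]
  if (!identical(head[1:2], c("palpinv-calibration", "v1"))) {
    stop("not a palpinv calibration file")
  }
  n_points <- as.integer(head[4])
  co <- matrix(NA_real_, 3, 3,
               dimnames = list(c("max", "total", "area"),
                               c("slope", "intercept", "r2")))
  for (k in 1:3) {
    parts <- strsplit(lines[1 + k], " ")[[1]]
    co[parts[1], ] <- as.numeric(parts[2:4])
  }
  structure(list(coef = co, n_points = n_points), class = "calibration_map")
}
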