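# Synthetic tactile-image rendering (a monotone proxy for the optical
# waveguide readout) and the pixel-domain feature extractors.

# Bilinear interpolation weights from grid coordinates g to query points q
# (rows: queries, two nonzero weights per row).  Tensor-product queries
# make resampling a pair of matrix products.
bilinear_weights <- function(g, q) {
  q <- pmin(pmax(q, min(g)), max(g))
  i <- pmin(pmax(findInterval(q, g), 1L), length(g) - 1L)
  t <- (q - g[i]) / (g[i + 1L] - g[i])
  Wt <- matrix(0, length(q), length(g))
  Wt[cbind(seq_along(q), i)] <- 1 - t
  Wt[cbind(seq_along(q), i + 1L)] <- Wt[cbind(seq_along(q), i + 1L)] + t
  Wt
}

#' Tactile image container
#'
#' An 8-bit grayscale tactile image: integer pixel values in \[0, 255\],
#' default 1024 x 768, with a pixel-pitch attribute in mm/pixel.
#'
#' @param pixels Integer (or whole-number numeric) matrix, values 0-255;
#'   rows are image rows (height), columns are image columns (width).
#' @param pixel_pitch Physical size of one pixel, mm.
#' @return Object of class `tactile_image`.
#' @export
tactile_image <- function(pixels, pixel_pitch = NA_real_) {
  stopifnot(is.matrix(pixels), nrow(pixels) > 0, ncol(pixels) > 0)
  if (any(pixels < 0 | pixels > 255)) {
    stop("pixel values must lie in [0, 255]")
  }
  if (max(abs(pixels - round(pixels))) > 1e-9) {
    stop("pixel values must be 8-bit integers")
  }
  structure(list(pixels = matrix(as.integer(round(pixels)), nrow(pixels)),
                 pixel_pitch = pixel_pitch),
            class = "tactile_image")
}

#' @export
print.tactile_image <- function(x, ...) {
  cat(sprintf("<tactile_image> %d x %d px, values %d..%d, pitch %s mm/px\n",
              ncol(x$pixels), nrow(x$pixels), min(x$pixels), max(x$pixels),
              format(x$pixel_pitch)))
  invisible(x)
}

#' Rendering configuration for the synthetic tactile camera
#'
#' The optical transfer from probe deformation to scattered-light intensity
#' is modeled as an affine gain followed by a Gaussian point-spread blur,
#' additive Gaussian sensor noise, clipping to \[0, 255\] and 8-bit
#' quantization.  This is a deliberately simple monotone proxy for the
#' waveguide optics, not a ray-tracing model.
#'
#' The default gain of 250 pixel-values per mm of deformation places the
#' image-side pixel threshold `k = 5` of [quantify_image()] at a 0.02 mm
#' deformation level, safely above the depth at which a deep inclusion's
#' wide, weak halo would otherwise dominate the thresholded blob area.
#'
#' @param gain Pixel value per mm of deformation (> 0).
#' @param blur_sigma Gaussian point-spread width, pixels (>= 0).
#' @param noise_sd Additive Gaussian noise scale, pixel values (>= 0).
#' @param seed Seed for the noise draw; rendering is a pure function of
#'   (field, config).
#' @param width,height Image size in pixels.
#' @return Named list of class `render_config`.
#' @export
render_config <- function(gain = 250, blur_sigma = 10, noise_sd = 0.5,
                          seed = 0, width = 1024, height = 768) {
  stopifnot(gain > 0, blur_sigma >= 0, noise_sd >= 0, width > 0, height > 0)
  structure(list(gain = gain, blur_sigma = blur_sigma, noise_sd = noise_sd,
                 seed = seed, width = as.integer(width),
                 height = as.integer(height)),
            class = "render_config")
}

#' Render a deformation field as a synthetic tactile image
#'
#' Resamples the probe-bottom deformation grid onto the image raster by
#' bilinear interpolation (the probe footprint spans the image width; the
#' shorter image height crops the footprint vertically, centered), maps
#' displacement to intensity with the affine gain, applies the Gaussian
#' point-spread blur, adds seeded sensor noise, clips to \[0, 255\] and
#' quantizes to 8 bits.  Identical `(field, cfg)` give identical images.
#'
#' @param field A [deformation_field()].
#' @param cfg A [render_config()].
#' @return A [tactile_image()].
#' @export
render_tactile_image <- function(field, cfg = render_config()) {
  stopifnot(inherits(field, "deformation_field"))
  if (!inherits(cfg, "render_config")) cfg <- do.call(render_config, cfg)
  span <- max(field$x) - min(field$x)
  pitch <- span / cfg$width
  xq <- min(field$x) + (seq_len(cfg$width) - 0.5) * pitch
  y0 <- min(field$y) + (span - cfg$height * pitch) / 2
  yq <- y0 + (seq_len(cfg$height) - 0.5) * pitch
  img <- bilinear_weights(field$y, yq) %*% field$w %*%
    t(bilinear_weights(field$x, xq))
  img <- img * cfg$gain
  img[img < 0] <- 0
  if (cfg$blur_sigma > 0) {
    img <- EBImage::gblur(img, sigma = cfg$blur_sigma)
  }
  if (cfg$noise_sd > 0) {
    img <- img + withr::with_seed(
      cfg$seed, matrix(stats::rnorm(length(img), 0, cfg$noise_sd),
                       nrow = cfg$height))
  }
  img <- round(pmin(pmax(img, 0), 255))
  tactile_image(img, pixel_pitch = pitch)
}

#' Extract the three pixel features from a tactile image
#'
#' * maximum pixel value: the pixel value at the intensity-weighted
#'   centroid of the above-threshold region (`mode = "centroid"`, the
#'   default); when no pixel exceeds `k`, falls back to the global maximum.
#'   `mode = "max"` returns the plain global maximum instead.
#' * total pixel value: the sum of all pixel values in the image.
#' * deformation area: the number of pixels strictly greater than the
#'   threshold `k`.
#'
#' @param img A [tactile_image()].
#' @param k Pixel threshold for the area count and centroid support,
#'   0-255; default 5.
#' @param mode `"centroid"` or `"max"` for the first feature.
#' @return A [feature_triple()] with `units = "TSIS"`.
#' @export
quantify_image <- function(img, k = 5, mode = c("centroid", "max")) {
  stopifnot(inherits(img, "tactile_image"), k >= 0, k <= 255)
  mode <- match.arg(mode)
  px <- img$pixels
  mask <- px > k
  if (mode == "max" || !any(mask)) {
    f1 <- max(px)
  } else {
    wts <- px[mask]
    rows <- row(px)[mask]
    cols <- col(px)[mask]
    rc <- round(sum(rows * wts) / sum(wts))
    cc <- round(sum(cols * wts) / sum(wts))
    f1 <- px[rc, cc]
  }
  feature_triple(
    f_max = as.numeric(f1),
    f_total = sum(as.numeric(px)),
    f_area = sum(mask),
    units = "TSIS"
  )
}

#' Read and write 8-bit grayscale tactile images
#'
#' PNG or TIFF, chosen by file extension.  Write-then-read reproduces the
#' pixel array exactly.  Color or >8-bit inputs are rejected with advice to
#' convert.
#'
#' @param img A [tactile_image()].
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param pixel_pitch Optional pitch (mm/pixel) to attach on read.
#' @return `read_tactile_image` returns a [tactile_image()];
#'   `write_tactile_image` returns `path` invisibly.
#' @export
write_tactile_image <- function(img, path) {
  stopifnot(inherits(img, "tactile_image"))
  ext <- tolower(tools::file_ext(path))
  norm <- img$pixels / 255
  if (ext == "png") {
    png::writePNG(norm, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(norm, path, bits.per.sample = 8L)
  } else {
    stop("unsupported image extension '", ext, "': use png or tiff")
  }
  invisible(path)
}

#' @rdname write_tactile_image
#' @export
read_tactile_image <- function(path, pixel_pitch = NA_real_) {
  ext <- tolower(tools::file_ext(path))
  arr <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::readTIFF(path)
  } else {
    stop("unsupported image extension '", ext, "': use png or tiff")
  }
  if (length(dim(arr)) == 3L) {
    stop("image is not single-channel grayscale; convert to 8-bit ",
         "grayscale before reading")
  }
  px <- arr * 255
  if (max(abs(px - round(px))) > 1e-6) {
    stop("image does not hold 8-bit samples; convert to 8-bit grayscale ",
         "before reading")
  }
  tactile_image(round(px), pixel_pitch = pixel_pitch)
}

#' Batch image features for a scenario list
#'
#' End-to-end synthetic image chain: for each scenario, compute the
#' inclusion-induced deformation field, render it as a tactile image, and
#' extract the pixel features.  The per-scenario render seed is offset from
#' `cfg$seed` so noise draws are independent across scenarios yet fully
#' reproducible.
#'
#' @param scenarios List of [inclusion_scenario()] objects.
#' @param fem_cfg A [fem_config()].
#' @param render_cfg A [render_config()].
#' @param k Pixel threshold for [quantify_image()].
#' @return Numeric matrix (`n` x 3), columns `f_max`, `f_total`, `f_area`
#'   in TSIS units; row names are scenario ids.
#' @export
tsis_features <- function(scenarios, fem_cfg = fem_config(),
                          render_cfg = render_config(), k = 5) {
  out <- matrix(NA_real_, length(scenarios), 3,
                dimnames = list(vapply(scenarios, function(s) s$id,
                                       character(1)),
                                c("f_max", "f_total", "f_area")))
  for (i in seq_along(scenarios)) {
    field <- inclusion_field(scenarios[[i]], fem_cfg)
    rc <- render_cfg
    rc$seed <- render_cfg$seed + i - 1L
    ft <- quantify_image(render_tactile_image(field, rc), k = k)
    out[i, ] <- c(ft$f_max, ft$f_total, ft$f_area)
  }
  out
}
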