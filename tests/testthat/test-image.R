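test_that("a zero field renders to an all-zero image", {
  f <- unit_area_field(0)
  img <- render_tactile_image(f, render_config(noise_sd = 0, width = 128,
                                               height = 96))
  expect_true(all(img$pixels == 0L))
  expect_equal(dim(img$pixels), c(96L, 128L))
})

test_that("noise-free rendering is deterministic and monotone in the field", {
  cfg <- render_config(noise_sd = 0, width = 128, height = 96)
  for (seed in 1:5) {
    w <- withr::with_seed(seed, matrix(abs(stats::rnorm(121, 0, 0.05)), 11))
    f <- deformation_field(seq(0, 25, length.out = 11),
                           seq(0, 25, length.out = 11), w)
    img1 <- render_tactile_image(f, cfg)
    expect_identical(img1$pixels,
                     render_tactile_image(f, cfg)$pixels)
    # uniform positive offset raises the total pixel value (pre-clipping)
    f2 <- deformation_field(f$x, f$y, w + 0.05)
    img2 <- render_tactile_image(f2, cfg)
    expect_gt(sum(img2$pixels), sum(img1$pixels))
  }
})

test_that("noisy rendering is a pure function of the seed", {
  f <- unit_area_field(0.05)
  cfg <- render_config(width = 128, height = 96, seed = 11)
  expect_identical(render_tactile_image(f, cfg)$pixels,
                   render_tactile_image(f, cfg)$pixels)
  cfg2 <- cfg; cfg2$seed <- 12
  expect_false(identical(render_tactile_image(f, cfg)$pixels,
                         render_tactile_image(f, cfg2)$pixels))
})

test_that("larger inclusions render larger blobs", {
  cfg <- fast_cfg()
  rcfg <- render_config(noise_sd = 0, width = 256, height = 192)
  counts <- vapply(c(5, 9, 14), function(d) {
    img <- render_tactile_image(
      inclusion_field(inclusion_scenario(d, 5, 120), cfg), rcfg)
    quantify_image(img, k = 5)$f_area
  }, numeric(1))
  expect_true(all(diff(counts) > 0))
})

test_that("pixel features follow their counting definitions", {
  px <- matrix(0L, 20, 30)
  img0 <- tactile_image(px)
  expect_equal(unlist(quantify_image(img0, k = 5)[1:3]),
               c(f_max = 0, f_total = 0, f_area = 0))

  px[7, 13] <- 200L
  img1 <- tactile_image(px)
  ft <- quantify_image(img1, k = 5)
  expect_equal(c(ft$f_max, ft$f_total, ft$f_area), c(200, 200, 1))

  # raising m previously sub-threshold pixels grows the area by exactly m
  base <- withr::with_seed(1, matrix(sample(0:5, 600, replace = TRUE), 20))
  raised <- base
  pick <- withr::with_seed(2, sample(which(base <= 5), 10))
  raised[pick] <- 50L
  d_area <- quantify_image(tactile_image(raised), 5)$f_area -
    quantify_image(tactile_image(base), 5)$f_area
  expect_equal(d_area, 10)
})

test_that("pixel features respect their range bounds", {
  px <- withr::with_seed(3, matrix(sample(0:255, 64 * 48, TRUE), 48))
  img <- tactile_image(px)
  ft <- quantify_image(img, k = 5)
  expect_lte(ft$f_max, 255)
  expect_lte(ft$f_area, length(px))
  expect_lte(ft$f_total, 255 * length(px))
  # centroid mode reads a pixel of the blob; max mode reads the global max
  expect_equal(quantify_image(img, k = 5, mode = "max")$f_max, max(px))
})

test_that("images round-trip losslessly through PNG and TIFF", {
  px <- withr::with_seed(4, matrix(sample(0:255, 64 * 48, TRUE), 48))
  img <- tactile_image(px)
  for (ext in c(".png", ".tif")) {
    path <- withr::local_tempfile(fileext = ext)
    write_tactile_image(img, path)
    back <- read_tactile_image(path)
    expect_identical(back$pixels, img$pixels)
  }
})

test_that("color images are rejected with conversion advice", {
  path <- withr::local_tempfile(fileext = ".png")
  rgb <- withr::with_seed(5, array(stats::runif(16 * 16 * 3), c(16, 16, 3)))
  png::writePNG(rgb, path)
  expect_error(read_tactile_image(path), "grayscale")
})

test_that("full-size synthetic images keep their dimensions", {
  f <- unit_area_field(0.04)
  img <- render_tactile_image(f, render_config(noise_sd = 1, seed = 2))
  expect_equal(dim(img$pixels), c(768L, 1024L))
  path <- withr::local_tempfile(fileext = ".png")
  write_tactile_image(img, path)
  expect_identical(read_tactile_image(path)$pixels, img$pixels)
})
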