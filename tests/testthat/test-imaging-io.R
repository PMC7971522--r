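test_that("background subtraction is per-channel, clamped and integer", {
  mk <- function(vals) {
    px <- array(0L, dim = c(1, 1, 3)); px[1, 1, ] <- as.integer(vals)
    polarized_image(px, 0, "polarized")
  }
  out <- subtract_background(mk(c(700, 650, 600)), mk(c(300, 300, 300)))
  expect_identical(as.integer(out$pixels), c(400L, 350L, 300L))
  out2 <- subtract_background(mk(c(100, 100, 100)), mk(c(300, 300, 300)))
  expect_identical(as.integer(out2$pixels), c(0L, 0L, 0L))
  img <- mk(c(1234, 56, 7))
  expect_true(all(subtract_background(img, img)$pixels == 0L))
  expect_error(subtract_background(array(0L, c(2, 2, 3)), array(0L, c(2, 3, 3))),
               "shape mismatch")
})

test_that("grayscale conversion uses BT.601 weights on real counts", {
  px <- array(0, dim = c(1, 3, 3))
  px[1, 1, ] <- c(1000, 1000, 1000)
  px[1, 2, ] <- c(0, 0, 0)
  px[1, 3, ] <- c(4095, 0, 0)
  g <- to_grayscale(px)
  expect_equal(g[1, 1], 999.9)          # weights sum to 0.9999
  expect_equal(g[1, 2], 0)
  expect_equal(g[1, 3], 4095 * 0.2989)  # 1223.99...
})

test_that("grayscale conversion is linear and monotone", {
  arr <- array(runif(5 * 4 * 3, 0, 4095), dim = c(5, 4, 3))
  for (c_scale in c(0, 0.5, 2)) {
    expect_equal(to_grayscale(arr * c_scale), to_grayscale(arr) * c_scale)
  }
})

test_that("16-bit TIFFs round-trip bit-exactly", {
  g <- matrix(sample(0:4095, 35 * 21, replace = TRUE), 35, 21)
  p <- withr::local_tempfile(fileext = ".tif")
  write_tiff16(g, p)
  expect_identical(read_tiff16(p), g)

  rgb <- array(sample(0:4095, 13 * 17 * 3, replace = TRUE), dim = c(13, 17, 3))
  p2 <- withr::local_tempfile(fileext = ".tif")
  write_tiff16(rgb, p2)
  expect_identical(read_tiff16(p2), rgb)
  expect_error(write_tiff16(matrix(-1, 2, 2), p2), "values")
})

test_that("written TIFFs are readable by an independent implementation", {
  # Python tifffile (pre-installed) as the external oracle
  rgb <- array(sample(0:4095, 9 * 7 * 3, replace = TRUE), dim = c(9, 7, 3))
  p <- withr::local_tempfile(fileext = ".tif")
  write_tiff16(rgb, p)
  out <- suppressWarnings(system2(
    "python", c("-c", shQuote(paste0(
      "import tifffile,sys; a=tifffile.imread(sys.argv[1]); ",
      "print(a.shape, a.dtype, int(a.sum()))")), p),
    stdout = TRUE, stderr = TRUE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0) {
    fail(paste("tifffile oracle failed:", paste(out, collapse = " ")))
  }
  expect_match(out[length(out)],
               sprintf("\\(9, 7, 3\\) uint16 %d", sum(rgb)))
})

test_that("stacks round-trip through manifest + TIFFs bit-exactly", {
  ph <- build_phantom(tiny_spec(noise_sd_counts = 20,
                                background_level_counts = 80))
  stack <- render_stack(ph, acquisition_schedule(60))
  dir <- withr::local_tempdir()
  manifest <- save_stack(stack, dir)
  back <- load_stack(manifest)
  expect_length(back$images, 6)
  for (i in seq_along(stack$images)) {
    expect_identical(back$images[[i]]$pixels, stack$images[[i]]$pixels)
    expect_identical(back$images[[i]]$angle_deg, stack$images[[i]]$angle_deg)
  }
  expect_identical(back$blank$pixels, stack$blank$pixels)
  expect_identical(back$brightfield$pixels, stack$brightfield$pixels)
  expect_equal(back$schedule$delta_theta_deg, 60)
})

test_that("manifest problems yield descriptive errors", {
  ph <- build_phantom(tiny_spec())
  stack <- render_stack(ph, acquisition_schedule(120))
  dir <- withr::local_tempdir()
  manifest <- save_stack(stack, dir)

  m <- jsonlite::read_json(manifest)
  m$images <- Filter(function(e) e$kind != "blank", m$images)
  jsonlite::write_json(m, manifest, auto_unbox = TRUE)
  expect_error(load_stack(manifest), "blank")

  manifest2 <- save_stack(stack, dir)
  m <- jsonlite::read_json(manifest2)
  for (i in seq_along(m$images))
    if (identical(m$images[[i]]$kind, "polarized")) m$images[[i]]$angle_deg <- 0
  jsonlite::write_json(m, manifest2, auto_unbox = TRUE)
  expect_error(load_stack(manifest2), "duplicate")

  manifest3 <- save_stack(stack, dir)
  file.remove(file.path(dir, "pol_002.tif"))
  expect_error(load_stack(manifest3), "missing file")
})

test_that("image_stack validates angles and shapes", {
  ph <- build_phantom(tiny_spec())
  a <- render_polarized(ph, 0); b <- render_polarized(ph, 60)
  b2 <- b; b2$angle_deg <- 0
  expect_error(image_stack(list(a, b2)), "duplicate")
  small <- build_phantom(tiny_spec(image_width_px = 60L, image_height_px = 60L,
                                   lumen_radius_px = 8,
                                   core_inner_radius_px = 20,
                                   core_outer_radius_px = 25))
  expect_error(image_stack(list(a, render_polarized(small, 60))), "dimensions")
})
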