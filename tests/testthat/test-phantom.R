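test_that("build_phantom handles the empty case and is deterministic", {
  spec <- tiny_spec(n_fibers = 0L)
  ph <- build_phantom(spec)
  expect_equal(nrow(ph$fibers), 0)
  expect_s3_class(ph$lumen_contour, "psr_contour")
  expect_s3_class(ph$core_contour, "psr_contour")

  a <- build_phantom(tiny_spec(seed = 7L))
  b <- build_phantom(tiny_spec(seed = 7L))
  expect_identical(a$fibers, b$fibers)
  expect_false(identical(a$fibers, build_phantom(tiny_spec(seed = 8L))$fibers))
})

test_that("invalid phantom specs are rejected", {
  expect_error(tiny_spec(core_inner_radius_px = 20), "lumen_radius")
  expect_error(tiny_spec(core_arc_deg = c(90, 90)), "arc span")
  expect_error(tiny_spec(core_arc_deg = c(0, 400)), "arc span")
  expect_error(tiny_spec(image_width_px = 0), "dimensions")
  expect_error(tiny_spec(fiber_amplitude_range = c(-5, 10)), "amplitudes")
})

test_that("fiber layout respects the cap annulus and orientation law", {
  spec <- tiny_spec(n_fibers = 10000L)
  ph <- build_phantom(spec)
  r <- sqrt((ph$fibers$x - spec$lumen_center_xy[1])^2 +
            (ph$fibers$y - spec$lumen_center_xy[2])^2)
  expect_true(all(r >= spec$lumen_radius_px))
  expect_true(all(r <= spec$core_inner_radius_px))
  expect_true(all(ph$fibers$phi_deg >= 0 & ph$fibers$phi_deg < 180))
  # empirical orientation histogram uniform within 3 SD of multinomial
  # sampling error per bin (deterministic under the fixed seed)
  counts <- table(cut(ph$fibers$phi_deg, breaks = seq(0, 180, by = 10)))
  n <- 10000; p <- 1 / 18
  expect_true(all(abs(counts - n * p) <= 3 * sqrt(n * p * (1 - p))))
})

test_that("render_polarized follows the crossed-polarizer response", {
  # phi = 45, theta = 0: sin^2(90 deg) = 1, peak = full amplitude
  g <- to_grayscale(render_polarized(single_fiber_phantom(45), 0,
                                     noise = FALSE, background = FALSE))
  expect_equal(max(g), 1000, tolerance = 1e-3)
  # phi = 0 aligned with the polarizer axis: extinction
  g0 <- to_grayscale(render_polarized(single_fiber_phantom(0), 0,
                                      noise = FALSE, background = FALSE))
  expect_equal(max(g0), 0)
  # phi = 15, theta = 30: sin^2(2*45) = 1 again
  g2 <- to_grayscale(render_polarized(single_fiber_phantom(15), 30,
                                      noise = FALSE, background = FALSE))
  expect_equal(max(g2), 1000, tolerance = 1e-3)
})

test_that("rendered frames match the brute-force per-pixel oracle", {
  spec <- tiny_spec(image_width_px = 61L, image_height_px = 61L,
                    lumen_radius_px = 8, core_inner_radius_px = 22,
                    core_outer_radius_px = 26, n_fibers = 5L,
                    fiber_length_px = 9, fiber_width_px = 3, seed = 11L)
  ph <- build_phantom(spec)
  for (theta in c(0, 30, 137)) {
    got <- to_grayscale(render_polarized(ph, theta, noise = FALSE,
                                         background = FALSE))
    want <- render_oracle(ph, theta)
    expect_lt(max(abs(got - want)), 1)  # channel quantization only
  }
})

test_that("renders are 12-bit integer images and seed-reproducible", {
  spec <- tiny_spec(noise_sd_counts = 25, background_level_counts = 100,
                    stage_angle_jitter_sd_deg = 0.5, recenter_shift_sd_px = 2)
  ph <- build_phantom(spec)
  img <- render_polarized(ph, 60)
  expect_true(is.integer(img$pixels))
  expect_gte(min(img$pixels), 0)
  expect_lte(max(img$pixels), 4095)
  expect_identical(img$pixels, render_polarized(ph, 60)$pixels)
  expect_identical(attr(img, "realized_angle_deg"),
                   attr(render_polarized(ph, 60), "realized_angle_deg"))
})

test_that("fiber response has the 90-degree period of the doubled angle", {
  phi <- runif(50, 0, 180)
  theta <- runif(50, 0, 360)
  expect_equal(fiber_response(phi, theta), fiber_response(phi, theta + 90))
})

test_that("brightfield delineates lumen, tissue and core", {
  ph <- build_phantom(tiny_spec(noise_sd_counts = 0))
  bf <- render_brightfield(ph)
  expect_identical(bf$kind, "brightfield")
  ctr <- round(ph$spec$lumen_center_xy)
  lumen_px <- bf$pixels[ctr[2] + 1, ctr[1] + 1, 1]
  cap_px <- bf$pixels[ctr[2] + 1, ctr[1] + 1 + ph$spec$lumen_radius_px + 5, 1]
  expect_lt(cap_px, lumen_px)
  expect_identical(bf$pixels, render_brightfield(ph)$pixels)
})

test_that("blank render is the stated background field", {
  spec <- tiny_spec(background_level_counts = 150)
  flat <- render_blank(spec, gradient_frac = 0, noise = FALSE)
  expect_true(all(flat$pixels == 150))
  expect_true(all(subtract_background(flat, flat)$pixels == 0L))

  noisy <- render_blank(tiny_spec(background_level_counts = 150,
                                  noise_sd_counts = 30))
  n_px <- length(noisy$pixels)
  expect_lt(abs(mean(noisy$pixels) - 150), 3 * 30 / sqrt(n_px) + 0.1)
})

test_that("phantom specs round-trip through JSON", {
  spec <- tiny_spec(noise_sd_counts = 12.5, core_arc_deg = c(45, 315),
                    orientation_distribution = "circumferential")
  p <- withr::local_tempfile(fileext = ".json")
  write_phantom_spec(spec, p)
  back <- read_phantom_spec(p)
  expect_equal(back, spec)
  expect_identical(build_phantom(back)$fibers, build_phantom(spec)$fibers)
})

test_that("serial sections share layout and obey thickness/trend controls", {
  spec <- tiny_spec(n_fibers = 40L)
  same <- serial_sections(spec, 30, thickness_cv = 0, cap_trend = 0)
  expect_length(same, 30)
  expect_identical(same[[1]]$fibers, same[[30]]$fibers)

  varied <- serial_sections(spec, 30, thickness_cv = 0.1)
  scales <- vapply(varied, function(p) p$spec$thickness_scale, numeric(1))
  cv <- sd(scales) / mean(scales)
  # sample CV of n = 30 draws: within sampling error of the target
  expect_lt(abs(cv - 0.1), 3 * 0.1 / sqrt(2 * 29))

  shrunk <- serial_sections(spec, 10, cap_trend = 1.5)
  inner <- vapply(shrunk, function(p) p$spec$core_inner_radius_px, numeric(1))
  expect_true(all(diff(inner) < 0))
  nfib <- vapply(shrunk, function(p) nrow(p$fibers), numeric(1))
  expect_true(all(diff(nfib) <= 0))
  expect_error(serial_sections(spec, 30, cap_trend = 2), "collapses the cap")
})
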