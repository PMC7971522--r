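test_that("schedule_angles enumerates the acquisition protocol", {
  expect_equal(schedule_angles(60), c(0, 60, 120, 180, 240, 300))
  expect_length(schedule_angles(2), 180)
  expect_equal(schedule_angles(44, "low"), c(0, 44, 88, 132, 176))
  expect_error(schedule_angles(0), "> 0")
  expect_error(schedule_angles(-4), "> 0")
})

test_that("low and high half-ranges partition the full range", {
  for (d in c(2, 6, 12, 44, 60)) {
    lo <- schedule_angles(d, "low"); hi <- schedule_angles(d, "high")
    expect_equal(sort(c(lo, hi)), schedule_angles(d, "full"))
    expect_length(intersect(lo, hi), 0)
    expect_true(all(lo < 180) && all(hi >= 180 & hi < 360))
  }
})

test_that("coarse_align undoes the stage rotation", {
  spec <- tiny_spec(n_fibers = 1L)
  ph <- build_phantom(spec)
  ph$spec$fiber_length_px <- 36
  ph$spec$fiber_width_px <- 10
  ph$fibers <- data.frame(x = 140, y = 60, phi_deg = 10, amplitude = 1000)
  g0 <- to_grayscale(render_polarized(ph, 0, noise = FALSE, background = FALSE))
  expect_identical(coarse_align(g0, 0)$pixels, g0)  # identity

  g60 <- to_grayscale(render_polarized(ph, 60, noise = FALSE,
                                       background = FALSE))
  al <- coarse_align(g60, 60)
  # footprints at half-maximum should coincide up to interpolation
  m0 <- g0 > max(g0) / 2
  m1 <- al$pixels > max(al$pixels) / 2
  expect_gte(sum(m0 & m1) / sum(m0 | m1), 0.95)
  # aligned intensity keeps the Malus ratio of the rotated render
  expect_equal(max(al$pixels) / max(g0),
               fiber_response(10, 60) / fiber_response(10, 0),
               tolerance = 0.02)
})

test_that("warp round trip returns close to the original", {
  ph <- build_phantom(tiny_spec(n_fibers = 40L, seed = 3L))
  g <- to_grayscale(render_polarized(ph, 0, noise = FALSE, background = FALSE))
  fwd <- warp_rigid(g, 25)
  back <- warp_rigid(fwd$pixels, -25)
  v <- back$validity & warp_rigid(fwd$validity * 1, -25)$pixels > 0.999
  # double bilinear resampling smears the sharp fiber edges; the error
  # must stay a small fraction of the mean signal
  expect_lt(mean(abs(back$pixels[v] - g[v])), 0.15 * mean(g[v]))
})

test_that("estimate_transform recovers known shifts and rotations", {
  ph <- build_phantom(tiny_spec(image_width_px = 325L, image_height_px = 257L,
                                lumen_radius_px = 55,
                                core_inner_radius_px = 80,
                                core_outer_radius_px = 100, n_fibers = 120L,
                                fiber_length_px = 15, fiber_width_px = 3,
                                seed = 5L))
  g <- to_grayscale(render_polarized(ph, 0, noise = FALSE, background = FALSE))

  tr0 <- estimate_transform(g, g)
  expect_equal(tr0$rotation_deg, 0)
  expect_equal(tr0$translation_xy, c(0, 0))
  expect_equal(tr0$quality, 1)

  mv <- warp_rigid(g, 0, c(5, -3))
  tr <- estimate_transform(g, mv$pixels)
  expect_equal(tr$translation_xy, c(-5, 3), tolerance = 0.5)

  mv2 <- warp_rigid(g, 1.5)
  tr2 <- estimate_transform(g, mv2$pixels)
  expect_equal(tr2$rotation_deg, -1.5, tolerance = 0.2)
})

test_that("register_stack maps identical copies by the identity", {
  ph <- build_phantom(tiny_spec(n_fibers = 40L))
  img <- render_polarized(ph, 0, noise = FALSE)
  img2 <- img; img2$angle_deg <- 0.0001  # second copy at an extra angle
  reg <- register_stack(image_stack(list(img, img2)))
  for (f in reg$frames) {
    expect_equal(f$transform$translation_xy, c(0, 0), tolerance = 0.05)
    expect_lt(abs(f$transform$rotation_deg), 0.01)
  }
})

test_that("zero-jitter phantom stacks register to near-identity", {
  ph <- build_phantom(tiny_spec(n_fibers = 80L, noise_sd_counts = 10,
                                background_level_counts = 60, seed = 2L))
  stack <- render_stack(ph, acquisition_schedule(60))
  reg <- register_stack(stack)
  for (f in reg$frames) {
    expect_lt(max(abs(f$transform$translation_xy)), 0.5)
    expect_lt(abs(f$transform$rotation_deg), 0.2)
    expect_gte(f$transform$quality, 0.7)
  }
})

test_that("unregistrable frames fail naming their angle", {
  ph <- build_phantom(tiny_spec(n_fibers = 50L))
  good <- render_polarized(ph, 0, noise = FALSE)
  junk <- good
  junk$angle_deg <- 10
  junk$pixels <- array(
    as.integer(withr::with_seed(1, sample(0:4095, length(good$pixels),
                                          replace = TRUE))),
    dim = dim(good$pixels))
  expect_error(register_stack(image_stack(list(good, junk))),
               "registration failed.*10")
})

test_that("simulated re-centering shifts are recovered", {
  spec <- tiny_spec(image_width_px = 325L, image_height_px = 257L,
                    lumen_radius_px = 55, core_inner_radius_px = 80,
                    core_outer_radius_px = 100, n_fibers = 120L,
                    fiber_length_px = 15, fiber_width_px = 3,
                    recenter_shift_sd_px = 3, noise_sd_counts = 10,
                    background_level_counts = 60, seed = 9L)
  ph <- build_phantom(spec)
  blank <- render_blank(spec)
  f0 <- render_polarized(ph, 0)
  ref <- to_grayscale(subtract_background(f0, blank))
  s0 <- attr(f0, "shift_px")
  errs <- c()
  for (a in c(60, 120, 240)) {
    fr <- render_polarized(ph, a)
    al <- coarse_align(to_grayscale(subtract_background(fr, blank)), a)
    tr <- estimate_transform(ref, al$pixels)
    # frame content sits at R_{-a} s_a relative to the scene, the
    # reference at s_0: expected correction is s_0 - R_{-a} s_a
    s <- attr(fr, "shift_px")
    rot <- -a * pi / 180
    s_al <- c(cos(rot) * s[1] + sin(rot) * s[2],
              -sin(rot) * s[1] + cos(rot) * s[2])
    expect_gte(tr$quality, 0.7)
    errs <- c(errs, tr$translation_xy - (s0 - s_al))
  }
  expect_lt(sqrt(mean(errs^2)), 0.5)
})
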