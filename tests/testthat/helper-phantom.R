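# Small phantoms used across the suite (noise-free by default so tests
# assert exact arithmetic; switch noise back on per test where wanted).

tiny_spec <- function(...) {
  args <- utils::modifyList(
    list(image_width_px = 200L, image_height_px = 160L,
         lumen_radius_px = 28, core_inner_radius_px = 52,
         core_outer_radius_px = 66, n_fibers = 60L,
         fiber_length_px = 14, fiber_width_px = 4,
         background_level_counts = 0, noise_sd_counts = 0, seed = 1L),
    list(...))
  do.call(phantom_spec, args)
}

# Phantom holding exactly one fiber at the image center of an odd-sized
# frame, so the peak pixel is a fixed point of all rotations about the
# center and carries the fiber's exact Malus intensity.
single_fiber_phantom <- function(phi_deg, amplitude = 1000, size = 49L,
                                 length_px = 20, width_px = 5) {
  spec <- phantom_spec(image_width_px = size, image_height_px = size,
                       lumen_radius_px = 3, core_inner_radius_px = 18,
                       core_outer_radius_px = 22, n_fibers = 0L,
                       fiber_length_px = length_px, fiber_width_px = width_px,
                       background_level_counts = 0, noise_sd_counts = 0)
  ph <- build_phantom(spec)
  ctr <- (size - 1) / 2
  ph$fibers <- data.frame(x = ctr, y = ctr, phi_deg = phi_deg,
                          amplitude = amplitude)
  ph
}

# Independent brute-force oracle for render_polarized: per-pixel
# evaluation of the rotated-rectangle coverage times the Malus response,
# then the renderer's orange tint, clipping, quantization and luma,
# written without the package's C++ path.
render_oracle <- function(phantom, theta_deg) {
  spec <- phantom$spec
  h <- spec$image_height_px; w <- spec$image_width_px
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  out <- matrix(0, h, w)
  hl <- spec$fiber_length_px / 2; hw <- spec$fiber_width_px / 2
  for (i in seq_len(nrow(phantom$fibers))) {
    f <- phantom$fibers[i, ]
    s <- sin(2 * (f$phi_deg + theta_deg) * pi / 180)^2
    th <- theta_deg * pi / 180
    x0 <- cx + cos(th) * (f$x - cx) + sin(th) * (f$y - cy)
    y0 <- cy - sin(th) * (f$x - cx) + cos(th) * (f$y - cy)
    a <- (f$phi_deg + theta_deg) * pi / 180
    u <- c(cos(a), -sin(a)); v <- c(-u[2], u[1])
    for (y in 0:(h - 1)) for (x in 0:(w - 1)) {
      du <- (x - x0) * u[1] + (y - y0) * u[2]
      dv <- (x - x0) * v[1] + (y - y0) * v[2]
      cov <- max(0, min(1, hl + 0.5 - abs(du))) *
        max(0, min(1, hw + 0.5 - abs(dv)))
      out[y + 1, x + 1] <- out[y + 1, x + 1] + f$amplitude * s * cov
    }
  }
  tint <- c(1.70, 0.75, (1 - 0.2989 * 1.70 - 0.5870 * 0.75) / 0.1140)
  luma <- c(0.2989, 0.5870, 0.1140)
  gray <- matrix(0, h, w)
  for (ch in 1:3)
    gray <- gray + luma[ch] * round(pmin(pmax(out * tint[ch], 0), 4095))
  gray
}
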