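# Synthetic birefringence phantom: an artery cross-section whose fibrous
# cap contains discrete collagen fibers obeying the ideal crossed-polarizer
# orientation response A * sin^2(2 * (phi + theta)).

#' Specify a synthetic artery-cross-section phantom
#'
#' The phantom emulates a PSR-stained artery section imaged under crossed
#' linear polarizers: a circular lumen, a fibrous cap annulus populated
#' with birefringent fibers, and a necrotic core whose inner boundary
#' terminates the cap.  Defaults describe a desk-scale acquisition
#' (650 x 515 px at 8.7 um/px, i.e. the study camera geometry at half
#' resolution) of a plaque with a cap a few hundred micrometers thick.
#'
#' @param image_width_px,image_height_px frame size in pixels.
#' @param pixel_size_um micrometers per pixel.
#' @param lumen_center_xy lumen center, 0-based (x, y) pixel coordinates;
#'   default is the image center (the acquisition protocol re-centers the
#'   lumen before each capture).
#' @param lumen_radius_px lumen radius in pixels.
#' @param core_inner_radius_px,core_outer_radius_px necrotic-core boundary
#'   radii; the cap is the annulus between `lumen_radius_px` and
#'   `core_inner_radius_px`.
#' @param core_arc_deg `[start, end]` in degrees of the sector where the
#'   core (and hence the cap) exists; `c(0, 360)` for a full annulus.
#' @param n_fibers number of collagen fibers placed in the cap.
#' @param fiber_amplitude_range `[min, max]` peak birefringence amplitude
#'   in counts; defaults sit well above the 600-count positive-pixel
#'   threshold, emulating a collagen-rich cap.
#' @param fiber_length_px,fiber_width_px fiber rectangle dimensions.
#' @param orientation_distribution `"uniform"` in \[0, 180) or
#'   `"circumferential"` (tangent to the lumen with 8-degree jitter).
#' @param background_level_counts residual glare level under crossed
#'   polarizers, per channel.
#' @param noise_sd_counts additive Gaussian read-noise SD per channel.
#' @param stage_angle_jitter_sd_deg SD of the error between nominal and
#'   realized stage angle (manual rotation is inexact).
#' @param recenter_shift_sd_px SD of the residual lateral shift left by
#'   manual lumen re-centering.
#' @param thickness_scale unitless multiplier on all fiber amplitudes,
#'   emulating section-thickness variation between serial sections.
#' @param seed integer RNG seed; fixes fiber layout and all per-frame
#'   noise streams.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(image_width_px = 650L,
                         image_height_px = 515L,
                         pixel_size_um = 8.7,
                         lumen_center_xy = NULL,
                         lumen_radius_px = 110,
                         core_inner_radius_px = 160,
                         core_outer_radius_px = 205,
                         core_arc_deg = c(0, 360),
                         n_fibers = 250L,
                         fiber_amplitude_range = c(1000, 3500),
                         fiber_length_px = 30,
                         fiber_width_px = 6,
                         orientation_distribution = c("uniform", "circumferential"),
                         background_level_counts = 120,
                         noise_sd_counts = 30,
                         stage_angle_jitter_sd_deg = 0,
                         recenter_shift_sd_px = 0,
                         thickness_scale = 1,
                         seed = 1L) {
  orientation_distribution <- match.arg(orientation_distribution)
  if (image_width_px < 1 || image_height_px < 1)
    stop("invalid spec: image dimensions must be positive")
  if (!(lumen_radius_px < core_inner_radius_px &&
        core_inner_radius_px < core_outer_radius_px))
    stop("invalid spec: need lumen_radius < core_inner_radius < core_outer_radius")
  arc_span <- core_arc_deg[2] - core_arc_deg[1]
  if (arc_span <= 0 || arc_span > 360)
    stop("invalid spec: core arc span must lie in (0, 360]")
  if (any(fiber_amplitude_range < 0) || diff(fiber_amplitude_range) < 0)
    stop("invalid spec: fiber amplitudes must be nonnegative with min <= max")
  if (n_fibers < 0) stop("invalid spec: n_fibers must be >= 0")
  if (noise_sd_counts < 0 || background_level_counts < 0)
    stop("invalid spec: noise and background must be nonnegative")
  if (thickness_scale < 0) stop("invalid spec: thickness_scale must be >= 0")
  if (is.null(lumen_center_xy))
    lumen_center_xy <- image_center(image_height_px, image_width_px)
  structure(
    list(image_width_px = as.integer(image_width_px),
         image_height_px = as.integer(image_height_px),
         pixel_size_um = pixel_size_um,
         lumen_center_xy = as.numeric(lumen_center_xy),
         lumen_radius_px = lumen_radius_px,
         core_inner_radius_px = core_inner_radius_px,
         core_outer_radius_px = core_outer_radius_px,
         core_arc_deg = as.numeric(core_arc_deg),
         n_fibers = as.integer(n_fibers),
         fiber_amplitude_range = as.numeric(fiber_amplitude_range),
         fiber_length_px = fiber_length_px,
         fiber_width_px = fiber_width_px,
         orientation_distribution = orientation_distribution,
         background_level_counts = background_level_counts,
         noise_sd_counts = noise_sd_counts,
         stage_angle_jitter_sd_deg = stage_angle_jitter_sd_deg,
         recenter_shift_sd_px = recenter_shift_sd_px,
         thickness_scale = thickness_scale,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Serialize / restore a phantom specification as JSON
#'
#' @param spec a [phantom_spec()].
#' @param path JSON file path.
#' @return `write_phantom_spec` returns `path` invisibly;
#'   `read_phantom_spec` returns the validated `phantom_spec`.
#' @export
write_phantom_spec <- function(spec, path) {
  stopifnot(inherits(spec, "phantom_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom_spec
#' @export
read_phantom_spec <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(phantom_spec, vals)
}

#' Crossed-polarizer orientation response
#'
#' Ideal Malus-type response of a birefringent fiber between crossed
#' linear polarizers: `sin^2(2 * (phi + theta))` with the polarizer axes
#' fixed in the lab frame and the specimen rotated by `theta`.
#'
#' @param phi_deg fiber orientation in degrees.
#' @param theta_deg stage rotation in degrees.
#' @return response factor in \[0, 1\].
#' @export
fiber_response <- function(phi_deg, theta_deg) {
  sinpi(2 * (phi_deg + theta_deg) / 180)^2
}

#' Worst-case composite retention of a fiber over an angle schedule
#'
#' Fraction of a fiber's amplitude retained by a maximum-intensity
#' composite over the given stage angles: `max_theta sin^2(2(phi+theta))`.
#'
#' @param phi_deg fiber orientation(s), degrees.
#' @param angles_deg acquisition stage angles, degrees.
#' @return numeric vector, one retention factor per `phi_deg`.
#' @export
composite_retention <- function(phi_deg, angles_deg) {
  vapply(phi_deg, function(p) max(fiber_response(p, angles_deg)), numeric(1))
}

#' Build a phantom: fiber set plus lumen and core contours
#'
#' Draws the fiber layout (deterministic for a fixed seed) and constructs
#' the lumen contour (circle polygon) and the necrotic-core boundary
#' contour in pixel coordinates.
#'
#' @param spec a [phantom_spec()].
#' @return an object of class `psr_phantom` with elements `spec`,
#'   `fibers` (data frame: x, y, phi_deg, amplitude), `lumen_contour` and
#'   `core_contour`.
#' @export
build_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  cx <- spec$lumen_center_xy[1]; cy <- spec$lumen_center_xy[2]
  hw <- spec$fiber_width_px / 2
  rmin <- spec$lumen_radius_px + hw
  rmax <- spec$core_inner_radius_px - hw
  if (rmax <= rmin)
    stop("invalid spec: cap annulus too thin to hold fibers of this width")
  fibers <- with_seed(spec$seed, {
    n <- spec$n_fibers
    if (n == 0L) {
      data.frame(x = numeric(0), y = numeric(0), phi_deg = numeric(0),
                 amplitude = numeric(0))
    } else {
      r <- sqrt(runif(n, rmin^2, rmax^2))  # area-uniform in the annulus
      ang <- runif(n, spec$core_arc_deg[1], spec$core_arc_deg[2])
      phi <- switch(spec$orientation_distribution,
        uniform = runif(n, 0, 180),
        circumferential = (ang + 90 + rnorm(n, 0, 8)) %% 180
      )
      amp <- runif(n, spec$fiber_amplitude_range[1],
                   spec$fiber_amplitude_range[2]) * spec$thickness_scale
      data.frame(
        x = cx + r * cos(ang * pi / 180),
        y = cy - r * sin(ang * pi / 180),  # y grows downward
        phi_deg = phi,
        amplitude = amp
      )
    }
  })
  structure(
    list(spec = spec,
         fibers = fibers,
         lumen_contour = circle_contour(spec$lumen_center_xy,
                                        spec$lumen_radius_px,
                                        label = "lumen"),
         core_contour = core_boundary_contour(spec)),
    class = "psr_phantom"
  )
}

#' @export
print.psr_phantom <- function(x, ...) {
  cat(sprintf("<psr_phantom> %d x %d px, %d fibers, cap annulus [%g, %g] px\n",
              x$spec$image_height_px, x$spec$image_width_px,
              nrow(x$fibers), x$spec$lumen_radius_px,
              x$spec$core_inner_radius_px))
  invisible(x)
}

# Closed polygon for the core boundary.  For a full annulus this is the
# inner-boundary circle the one-degree rays terminate on; for a partial
# arc it is the annular-sector ring (inner arc out, outer arc back), so
# that rays cast from the lumen center hit the inner ("leading") boundary
# first.
core_boundary_contour <- function(spec) {
  arc <- spec$core_arc_deg
  if (diff(arc) >= 360) {
    circle_contour(spec$lumen_center_xy, spec$core_inner_radius_px,
                   label = "core")
  } else {
    cx <- spec$lumen_center_xy[1]; cy <- spec$lumen_center_xy[2]
    a <- seq(arc[1], arc[2], length.out = max(8, ceiling(diff(arc))))
    rad <- a * pi / 180
    inner <- cbind(cx + spec$core_inner_radius_px * cos(rad),
                   cy - spec$core_inner_radius_px * sin(rad))
    outer <- cbind(cx + spec$core_outer_radius_px * cos(rev(rad)),
                   cy - spec$core_outer_radius_px * sin(rev(rad)))
    structure(list(vertices = rbind(inner, outer), label = "core"),
              class = "psr_contour")
  }
}

# Deterministic per-frame RNG stream derived from the phantom seed and
# the nominal stage angle (so re-rendering any frame is bit-identical).
frame_seed <- function(spec, stage_angle_deg, salt = 0L) {
  (as.numeric(spec$seed) * 1009 + round(stage_angle_deg * 100) +
     salt * 7919) %% 2147483647
}

# Smooth multiplicative illumination field shared by blank and sample
# frames: a gentle corner-to-corner linear gradient.
background_field <- function(spec, gradient_frac = 0.1) {
  h <- spec$image_height_px; w <- spec$image_width_px
  gx <- if (w > 1) (seq_len(w) - 1) / (w - 1) else 0.5
  gy <- if (h > 1) (seq_len(h) - 1) / (h - 1) else 0.5
  g <- outer(gy, gx, function(y, x) (x + y) / 2 - 0.5)
  spec$background_level_counts * (1 + 2 * gradient_frac * g)
}

quantize12 <- function(x) {
  x <- round(x)
  x[x < 0] <- 0
  x[x > MAX_COUNT] <- MAX_COUNT
  storage.mode(x) <- "integer"
  x
}

#' Render a polarized frame of a phantom at a stage angle
#'
#' The specimen geometry rotates counterclockwise by `stage_angle_deg`
#' about the image center (the polarizer axes stay fixed in the lab
#' frame); each fiber pixel contributes `A * sin^2(2(phi + theta))`
#' counts, colored with a fixed orange tint whose luma is exactly the
#' polarized intensity.  Background level, illumination gradient and
#' Gaussian noise are added per channel, then the frame is clipped to
#' \[0, 4095\] and quantized.  When the spec enables them, stage-angle
#' jitter and a residual re-centering shift are drawn deterministically
#' per frame.
#'
#' @param phantom a `psr_phantom`.
#' @param stage_angle_deg nominal stage rotation, degrees.
#' @param noise logical; set `FALSE` for a noise-free render (background
#'   gradient is still applied unless `background = FALSE`).
#' @param background logical; include background level and gradient.
#' @return a [polarized_image()]; attributes `realized_angle_deg` and
#'   `shift_px` record the jittered acquisition.
#' @export
render_polarized <- function(phantom, stage_angle_deg, noise = TRUE,
                             background = TRUE) {
  stopifnot(inherits(phantom, "psr_phantom"))
  spec <- phantom$spec
  h <- spec$image_height_px; w <- spec$image_width_px
  ctr <- image_center(h, w)
  res <- with_seed(frame_seed(spec, stage_angle_deg), {
    jitter <- if (spec$stage_angle_jitter_sd_deg > 0)
      rnorm(1, 0, spec$stage_angle_jitter_sd_deg) else 0
    shift <- if (spec$recenter_shift_sd_px > 0)
      rnorm(2, 0, spec$recenter_shift_sd_px) else c(0, 0)
    noise_arr <- if (noise && spec$noise_sd_counts > 0)
      array(rnorm(h * w * 3, 0, spec$noise_sd_counts), dim = c(h, w, 3))
    else 0
    list(jitter = jitter, shift = shift, noise = noise_arr)
  })
  theta <- stage_angle_deg + res$jitter
  intensity <- render_fibers_cpp(
    h, w, phantom$fibers$x, phantom$fibers$y, phantom$fibers$phi_deg,
    phantom$fibers$amplitude, spec$fiber_length_px, spec$fiber_width_px,
    theta, ctr[1], ctr[2], res$shift[1], res$shift[2]
  )
  bg <- if (background) background_field(spec) else 0
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    px[, , ch] <- intensity * FIBER_TINT[ch] + bg +
      (if (is.array(res$noise)) res$noise[, , ch] else 0)
  }
  img <- polarized_image(quantize12(px), angle_deg = stage_angle_deg,
                         kind = "polarized", pixel_size_um = spec$pixel_size_um)
  attr(img, "realized_angle_deg") <- theta
  attr(img, "shift_px") <- res$shift
  img
}

#' Render the unpolarized bright-field frame of a phantom
#'
#' Bright illumination with a darker tissue annulus; the lumen and the
#' necrotic core are visibly delineated.  Used only for drawing contours,
#' never for quantification.
#'
#' @param phantom a `psr_phantom`.
#' @param base_level_counts illumination level of tissue-free areas.
#' @return a [polarized_image()] of kind `"brightfield"`.
#' @export
render_brightfield <- function(phantom, base_level_counts = 3600) {
  spec <- phantom$spec
  h <- spec$image_height_px; w <- spec$image_width_px
  cx <- spec$lumen_center_xy[1]; cy <- spec$lumen_center_xy[2]
  xg <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  yg <- matrix(seq_len(h) - 1, h, w)
  r <- sqrt((xg - cx)^2 + (yg - cy)^2)
  ang <- (atan2(-(yg - cy), xg - cx) * 180 / pi) %% 360
  in_arc <- if (diff(spec$core_arc_deg) >= 360) TRUE else {
    a0 <- spec$core_arc_deg[1] %% 360; a1 <- spec$core_arc_deg[2] %% 360
    if (a0 <= a1) ang >= a0 & ang < a1 else ang >= a0 | ang < a1
  }
  shade <- matrix(1, h, w)
  tissue <- r >= spec$lumen_radius_px & r <= spec$core_outer_radius_px
  shade[tissue] <- 0.60
  core <- tissue & r >= spec$core_inner_radius_px & in_arc
  shade[core] <- 0.42
  tint <- c(1, 0.75, 0.80)  # pink cast of bright-field PSR
  noise_arr <- with_seed(frame_seed(spec, 0, salt = 2L), {
    if (spec$noise_sd_counts > 0)
      array(rnorm(h * w * 3, 0, spec$noise_sd_counts), dim = c(h, w, 3))
    else array(0, dim = c(h, w, 3))
  })
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3)
    px[, , ch] <- base_level_counts * tint[ch] * shade + noise_arr[, , ch]
  polarized_image(quantize12(px), angle_deg = NA_real_, kind = "brightfield",
                  pixel_size_um = spec$pixel_size_um)
}

#' Render the blank-slide background frame
#'
#' A smooth low-level field: background level times a gentle linear
#' illumination gradient, plus read noise.  This is the image subtracted
#' from every polarized frame.
#'
#' @param spec a [phantom_spec()].
#' @param gradient_frac relative amplitude of the corner-to-corner
#'   gradient (0 for a flat field).
#' @param noise logical; include read noise.
#' @return a [polarized_image()] of kind `"blank"`.
#' @export
render_blank <- function(spec, gradient_frac = 0.1, noise = TRUE) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$image_height_px; w <- spec$image_width_px
  bg <- background_field(spec, gradient_frac)
  noise_arr <- with_seed(frame_seed(spec, 0, salt = 1L), {
    if (noise && spec$noise_sd_counts > 0)
      array(rnorm(h * w * 3, 0, spec$noise_sd_counts), dim = c(h, w, 3))
    else array(0, dim = c(h, w, 3))
  })
  px <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) px[, , ch] <- bg + noise_arr[, , ch]
  polarized_image(quantize12(px), angle_deg = NA_real_, kind = "blank",
                  pixel_size_um = spec$pixel_size_um)
}

#' Render a complete acquisition stack for a phantom
#'
#' One polarized frame per scheduled angle plus the blank and
#' bright-field frames, bundled as an [image_stack()].
#'
#' @param phantom a `psr_phantom`.
#' @param schedule an [acquisition_schedule()] or numeric vector of
#'   stage angles in degrees.
#' @param noise logical, passed to [render_polarized()].
#' @return an [image_stack()].
#' @export
render_stack <- function(phantom, schedule = acquisition_schedule(60), noise = TRUE) {
  angles <- if (inherits(schedule, "acquisition_schedule"))
    schedule$angles_deg else sort(as.numeric(schedule))
  images <- lapply(angles, function(a) render_polarized(phantom, a, noise = noise))
  image_stack(images,
              blank = render_blank(phantom$spec, noise = noise),
              brightfield = render_brightfield(phantom),
              schedule = if (inherits(schedule, "acquisition_schedule"))
                schedule else NULL)
}

#' Simulate serial histological sections of one phantom
#'
#' Produces `n_sections` phantoms sharing the same fiber layout and
#' geometry.  Per-section amplitude scale factors are drawn with the
#' requested coefficient of variation (section thickness modulates
#' birefringent brightness), and a nonzero `cap_trend` shrinks the core
#' inner radius linearly across sections, thinning the cap and dropping
#' the fibers that no longer fit.
#'
#' @param spec a [phantom_spec()] for the first section.
#' @param n_sections number of sections (>= 1).
#' @param thickness_cv coefficient of variation of the per-section
#'   thickness scale (0 for identical sections).
#' @param cap_trend pixels of core-inner-radius shrink per section.
#' @return list of `psr_phantom` objects, one per section.
#' @export
serial_sections <- function(spec, n_sections = 30L, thickness_cv = 0,
                            cap_trend = 0) {
  stopifnot(inherits(spec, "phantom_spec"), n_sections >= 1, thickness_cv >= 0)
  shrink <- cap_trend * (seq_len(n_sections) - 1)
  min_inner <- spec$core_inner_radius_px - max(shrink)
  if (min_inner - spec$lumen_radius_px < 1)
    stop("invalid spec: cap_trend collapses the cap below 1 px")
  scales <- with_seed(spec$seed + 99991, {
    if (thickness_cv == 0) rep(1, n_sections)
    else pmax(rnorm(n_sections, 1, thickness_cv), 0.05)
  })
  base <- build_phantom(spec)
  lapply(seq_len(n_sections), function(k) {
    sk <- spec
    sk$core_inner_radius_px <- spec$core_inner_radius_px - shrink[k]
    sk$thickness_scale <- spec$thickness_scale * scales[k]
    ph <- base
    ph$spec <- sk
    keep <- with(base$fibers,
                 sqrt((x - sk$lumen_center_xy[1])^2 +
                      (y - sk$lumen_center_xy[2])^2) <=
                   sk$core_inner_radius_px - sk$fiber_width_px / 2)
    ph$fibers <- base$fibers[keep, , drop = FALSE]
    ph$fibers$amplitude <- ph$fibers$amplitude * scales[k]
    ph$core_contour <- core_boundary_contour(sk)
    ph
  })
}
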