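# Rotation-prior rigid co-registration of polarized frames to the
# 0-degree reference: coarse alignment by the known stage angle, residual
# translation by phase correlation, and a bounded rotation+translation
# refinement maximizing normalized cross-correlation of structural
# (contrast-saturated) images.

#' Stage angles for an acquisition schedule
#'
#' Multiples of the angular increment within the chosen rotation range:
#' full rotation covers \[0, 360) degrees, the low half-range the angles
#' below 180 and the high half-range those in \[180, 360).
#'
#' @param delta_theta_deg angular increment in degrees, in (0, 180\].
#' @param rotation_range `"full"`, `"low"` or `"high"`.
#' @return sorted numeric vector of stage angles in degrees.
#' @examples
#' schedule_angles(60)          # 0 60 120 180 240 300
#' length(schedule_angles(2))   # 180
#' @export
schedule_angles <- function(delta_theta_deg,
                            rotation_range = c("full", "low", "high")) {
  rotation_range <- match.arg(rotation_range)
  if (!is.numeric(delta_theta_deg) || delta_theta_deg <= 0)
    stop("delta_theta_deg must be > 0")
  if (delta_theta_deg > 180)
    stop("delta_theta_deg must be <= 180")
  angles <- delta_theta_deg * (0:(ceiling(360 / delta_theta_deg) - 1))
  angles <- angles[angles < 360]
  switch(rotation_range,
         full = angles,
         low = angles[angles < 180],
         high = angles[angles >= 180])
}

#' Construct an acquisition schedule
#'
#' @inheritParams schedule_angles
#' @return object of class `acquisition_schedule` with fields
#'   `delta_theta_deg`, `rotation_range`, `angles_deg`.
#' @export
acquisition_schedule <- function(delta_theta_deg,
                                 rotation_range = c("full", "low", "high")) {
  rotation_range <- match.arg(rotation_range)
  structure(
    list(delta_theta_deg = delta_theta_deg,
         rotation_range = rotation_range,
         angles_deg = schedule_angles(delta_theta_deg, rotation_range)),
    class = "acquisition_schedule"
  )
}

#' @export
print.acquisition_schedule <- function(x, ...) {
  cat(sprintf("<acquisition_schedule> delta=%g deg, range=%s, %d angles\n",
              x$delta_theta_deg, x$rotation_range, length(x$angles_deg)))
  invisible(x)
}

schedule_id <- function(schedule) {
  sprintf("dtheta=%g,%s", schedule$delta_theta_deg, schedule$rotation_range)
}

#' Rigid transform between co-registered frames
#'
#' @param rotation_deg residual rotation (counterclockwise-positive).
#' @param translation_xy residual translation in pixels, (dx, dy).
#' @param rotation_center_xy center of rotation in pixel coordinates.
#' @param quality normalized cross-correlation on the valid overlap.
#' @return object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation_deg = 0, translation_xy = c(0, 0),
                            rotation_center_xy = c(0, 0), quality = NA_real_) {
  structure(
    list(rotation_deg = rotation_deg,
         translation_xy = as.numeric(translation_xy),
         rotation_center_xy = as.numeric(rotation_center_xy),
         quality = quality),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> rot=%.4f deg, t=(%.3f, %.3f) px, quality=%.4f\n",
              x$rotation_deg, x$translation_xy[1], x$translation_xy[2],
              x$quality))
  invisible(x)
}

is_identity_transform <- function(rotation_deg, translation_xy,
                                  tol_rot = 1e-9, tol_t = 1e-9) {
  abs(rotation_deg) < tol_rot && all(abs(translation_xy) < tol_t)
}

#' Apply a rigid warp to an image
#'
#' Rotates the image content counterclockwise by `rotation_deg` about
#' `center` and translates it by `translation`, with bilinear
#' interpolation.  Pixels whose value would come from outside the frame
#' are filled with 0 and flagged in the validity mask.
#'
#' @param x numeric matrix (grayscale) or H x W x 3 array (RGB).
#' @param rotation_deg rotation in degrees.
#' @param translation (dx, dy) in pixels.
#' @param center rotation center (x, y); default image center.
#' @return list with `pixels` (same shape as `x`, numeric) and
#'   `validity` (H x W logical).
#' @export
warp_rigid <- function(x, rotation_deg, translation = c(0, 0), center = NULL) {
  d <- dim(x)
  if (is.null(center)) center <- image_center(d[1], d[2])
  if (is_identity_transform(rotation_deg, translation)) {
    return(list(pixels = x * 1.0,
                validity = matrix(TRUE, d[1], d[2])))
  }
  if (length(d) == 2L) {
    r <- warp_rigid_cpp(x, rotation_deg, translation[1], translation[2],
                        center[1], center[2])
    list(pixels = r$pixels, validity = r$validity)
  } else {
    out <- array(0, dim = d)
    validity <- NULL
    for (ch in seq_len(d[3])) {
      r <- warp_rigid_cpp(x[, , ch], rotation_deg, translation[1],
                          translation[2], center[1], center[2])
      out[, , ch] <- r$pixels
      validity <- r$validity
    }
    list(pixels = out, validity = validity)
  }
}

#' Coarse alignment by the known stage angle
#'
#' Rotates a frame by minus its acquisition angle about the image center,
#' undoing the counterclockwise stage rotation so only a small residual
#' transform remains for refinement.
#'
#' @param x grayscale matrix, RGB array or [polarized_image()].
#' @param stage_angle_deg acquisition angle in degrees; defaults to the
#'   image's own angle when `x` is a `polarized_image`.
#' @return list with `pixels` and `validity` as in [warp_rigid()].
#' @export
coarse_align <- function(x, stage_angle_deg = NULL) {
  if (inherits(x, "polarized_image")) {
    if (is.null(stage_angle_deg)) stage_angle_deg <- x$angle_deg
    x <- x$pixels
  }
  stopifnot(is.numeric(stage_angle_deg), !is.na(stage_angle_deg))
  warp_rigid(x, -stage_angle_deg)
}

# Contrast-saturated "structural" projection used as the registration
# similarity channel.  Fiber brightness is modulated by the crossed-
# polarizer response, so raw intensities of two frames at different stage
# angles decorrelate even when perfectly aligned; saturating the
# intensity scale at a quarter of the bright quantile turns the frames
# into near-binary footprint images whose correlation measures geometric
# alignment, not brightness agreement.
structural_image <- function(gray) {
  hi <- as.numeric(quantile(gray, 0.995, names = FALSE))
  if (hi <= 0) hi <- max(gray, 1)
  pmin(gray / (0.25 * hi), 1)
}

ncc <- function(a, b, valid = NULL) {
  if (!is.null(valid)) {
    a <- a[valid]; b <- b[valid]
  }
  sa <- sd(a); sb <- sd(b)
  if (sa == 0 || sb == 0) return(if (isTRUE(all.equal(a, b))) 1 else 0)
  cor(as.vector(a), as.vector(b))
}

# Translation between two frames by phase correlation, with parabolic
# sub-pixel interpolation of the correlation peak.  Returns the (dx, dy)
# to *apply* to `moving` (see warp_rigid) to align it to `reference`.
phase_correlate <- function(reference, moving, max_shift = 50,
                            reference_fft = NULL) {
  fa <- reference_fft %||% fft(reference)
  fb <- fft(moving)
  cross <- fa * Conj(fb)
  r <- Re(fft(cross / pmax(Mod(cross), 1e-12), inverse = TRUE)) / length(cross)
  h <- nrow(r); w <- ncol(r)
  sy <- ifelse(0:(h - 1) > h / 2, 0:(h - 1) - h, 0:(h - 1))
  sx <- ifelse(0:(w - 1) > w / 2, 0:(w - 1) - w, 0:(w - 1))
  allowed <- outer(abs(sy) <= max_shift, abs(sx) <= max_shift)
  rr <- r
  rr[!allowed] <- -Inf
  peak <- arrayInd(which.max(rr), dim(rr))
  py <- peak[1]; px <- peak[2]
  subpix <- function(rm, r0, rp) {
    den <- rm - 2 * r0 + rp
    if (is.finite(den) && abs(den) > 1e-12) {
      d <- 0.5 * (rm - rp) / den
      max(min(d, 0.5), -0.5)
    } else 0
  }
  wrap <- function(i, n) ((i - 1) %% n) + 1
  dy <- subpix(r[wrap(py - 1, h), px], r[py, px], r[wrap(py + 1, h), px])
  dx <- subpix(r[py, wrap(px - 1, w)], r[py, px], r[py, wrap(px + 1, w)])
  c(sx[px] + dx, sy[py] + dy)
}

decimate <- function(x, factor) {
  if (factor <= 1) return(x)
  x[seq(1, nrow(x), by = factor), seq(1, ncol(x), by = factor)]
}

# NCC objective at a candidate residual rotation: rotate the structural
# moving image, recover the best translation at that rotation by phase
# correlation, and score the warped result against the reference.
rotation_objective <- function(ref_s, mov_s, rot, max_shift, ref_fft = NULL) {
  wr <- warp_rigid(mov_s, rot)
  t_at <- phase_correlate(ref_s, wr$pixels, max_shift, ref_fft)
  wt <- warp_rigid(mov_s, rot, t_at)
  list(rot = rot, translation = t_at,
       quality = ncc(ref_s, wt$pixels, wt$validity))
}

parabolic_vertex <- function(x, y) {
  den <- y[1] - 2 * y[2] + y[3]
  if (!is.finite(den) || abs(den) < 1e-12) return(x[2])
  v <- x[2] + 0.5 * (y[1] - y[3]) / den * (x[3] - x[2])
  max(min(v, x[3]), x[1])
}

#' Estimate the residual rigid transform between coarse-aligned frames
#'
#' Residual translation is found by phase correlation; when
#' `refine_rotation` is enabled, rotation and translation are then
#' jointly refined by maximizing normalized cross-correlation of
#' structural images over a bounded search (default |rotation| <= 5
#' degrees, |translation| <= 50 px), with the rotation search run on a
#' decimated image pyramid and polished by parabolic interpolation.
#'
#' @param reference_gray grayscale reference frame (matrix).
#' @param moving_gray grayscale frame to register, already
#'   coarse-aligned, same shape.
#' @param max_rotation_deg,max_translation_px search bounds.
#' @param refine_rotation logical; if `FALSE` only translation is
#'   estimated.
#' @param search_downsample decimation factor for the rotation search.
#' @param rotation_gain_min minimum quality improvement over the
#'   translation-only solution required to accept a nonzero residual
#'   rotation (parsimony guard: the orientation-modulated similarity
#'   surface can yield spurious sub-degree rotation "improvements").
#' @param quality_floor if non-`NULL`, error when the final quality falls
#'   below this normalized cross-correlation.
#' @return a [rigid_transform()]; its `quality` is the NCC of structural
#'   images over the valid overlap (exactly 1 for identical frames).
#' @export
estimate_transform <- function(reference_gray, moving_gray,
                               max_rotation_deg = 5, max_translation_px = 50,
                               refine_rotation = TRUE, search_downsample = 4,
                               rotation_gain_min = 0.005, quality_floor = NULL) {
  stopifnot(identical(dim(reference_gray), dim(moving_gray)))
  center <- image_center(nrow(reference_gray), ncol(reference_gray))
  ref_s <- structural_image(reference_gray)
  mov_s <- structural_image(moving_gray)
  ref_fft <- fft(ref_s)

  # quality of a snapped candidate at full resolution
  snap <- function(rot, t) {
    if (abs(rot) < 0.02) rot <- 0
    t[abs(t) < 0.05] <- 0
    t <- pmax(pmin(t, max_translation_px), -max_translation_px)
    q <- if (is_identity_transform(rot, t)) ncc(ref_s, mov_s) else {
      wt <- warp_rigid(mov_s, rot, t)
      ncc(ref_s, wt$pixels, wt$validity)
    }
    list(rot = rot, t = t, quality = q)
  }

  t0 <- phase_correlate(ref_s, mov_s, max_translation_px, ref_fft)
  best <- snap(0, t0)
  if (refine_rotation && max_rotation_deg > 0) {
    f <- max(1L, as.integer(search_downsample))
    ref_d <- decimate(ref_s, f); mov_d <- decimate(mov_s, f)
    ref_d_fft <- fft(ref_d)
    ms_d <- max(2, ceiling(max_translation_px / f))
    grid <- seq(-max_rotation_deg, max_rotation_deg,
                by = min(1, max_rotation_deg / 2))
    scores <- vapply(grid, function(r)
      rotation_objective(ref_d, mov_d, r, ms_d, ref_d_fft)$quality, numeric(1))
    i <- which.max(scores)
    rot <- if (i == 1 || i == length(grid)) grid[i]
    else parabolic_vertex(grid[(i - 1):(i + 1)], scores[(i - 1):(i + 1)])
    # fine pass at half decimation around the coarse optimum
    f2 <- max(1L, f %/% 2L)
    ref_d2 <- decimate(ref_s, f2); mov_d2 <- decimate(mov_s, f2)
    ref_d2_fft <- fft(ref_d2)
    ms_d2 <- max(2, ceiling(max_translation_px / f2))
    fine <- rot + c(-0.25, 0, 0.25)
    fine_scores <- vapply(fine, function(r)
      rotation_objective(ref_d2, mov_d2, r, ms_d2, ref_d2_fft)$quality,
      numeric(1))
    rot <- parabolic_vertex(fine, fine_scores)
    rot <- max(min(rot, max_rotation_deg), -max_rotation_deg)
    if (rot != 0) {
      wr <- warp_rigid(mov_s, rot)
      t_rot <- phase_correlate(ref_s, wr$pixels, max_translation_px, ref_fft)
      # keep the rotated candidate only if it beats translation-only at
      # full resolution; the decimated search can otherwise hand back a
      # spurious sub-degree rotation
      cand <- snap(rot, t_rot)
      if (cand$quality > best$quality + rotation_gain_min) best <- cand
    }
  }
  # sub-resolution residuals are indistinguishable from noise and were
  # snapped to zero inside `snap` to avoid gratuitous resampling
  if (!is.null(quality_floor) && best$quality < quality_floor)
    stop(sprintf("registration failed: quality %.3f below floor %.3f",
                 best$quality, quality_floor))
  rigid_transform(best$rot, best$t, center, best$quality)
}

#' Apply a rigid transform to an image
#'
#' @param x grayscale matrix or RGB array.
#' @param transform a [rigid_transform()].
#' @return list with `pixels` and `validity`, as [warp_rigid()].
#' @export
apply_transform <- function(x, transform) {
  stopifnot(inherits(transform, "rigid_transform"))
  warp_rigid(x, transform$rotation_deg, transform$translation_xy,
             transform$rotation_center_xy)
}

# Register one background-subtracted frame to the reference: the coarse
# stage-angle rotation and the estimated residual are composed into a
# single warp (rotation residual - stage_angle) so the RGB frame is
# resampled exactly once.
register_frame <- function(ref_gray, frame, quality_floor = 0.7,
                           max_rotation_deg = 5, max_translation_px = 50,
                           refine_rotation = TRUE) {
  stage <- frame$angle_deg
  gray <- to_grayscale(frame)
  aligned <- coarse_align(gray, stage)
  tr <- estimate_transform(ref_gray, aligned$pixels,
                           max_rotation_deg = max_rotation_deg,
                           max_translation_px = max_translation_px,
                           refine_rotation = refine_rotation)
  if (tr$quality < quality_floor) {
    tr2 <- estimate_transform(ref_gray, aligned$pixels,
                              max_rotation_deg = 2 * max_rotation_deg,
                              max_translation_px = 2 * max_translation_px,
                              refine_rotation = refine_rotation)
    if (tr2$quality >= tr$quality) tr <- tr2
  }
  total_rot <- tr$rotation_deg - stage
  warped <- warp_rigid(frame$pixels, total_rot, tr$translation_xy)
  list(rgb = warped$pixels,
       gray = to_grayscale(warped$pixels),
       validity = warped$validity,
       transform = tr,
       angle_deg = stage)
}

#' Register a background-subtracted stack to its 0-degree frame
#'
#' Every non-reference image is coarse-aligned by its stage angle and a
#' residual rigid transform is estimated and applied (one resampling per
#' frame).  Frames whose registration quality stays below the floor after
#' one retry with doubled search bounds cause an error naming the failing
#' angles.
#'
#' @param stack an [image_stack()] whose polarized frames have been
#'   background-subtracted (see [subtract_background()]); if a blank is
#'   attached it is subtracted here.
#' @param quality_floor minimum accepted structural NCC (default 0.7).
#' @param refine_rotation logical; disable to use translation-only
#'   refinement.
#' @return object of class `registered_stack`: list of frames (each with
#'   `rgb`, `gray`, `validity`, `transform`, `angle_deg`) plus the
#'   schedule.
#' @export
register_stack <- function(stack, quality_floor = 0.7, refine_rotation = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  frames <- stack$images
  angles <- vapply(frames, function(f) f$angle_deg, numeric(1))
  if (!is.null(stack$blank))
    frames <- lapply(frames, subtract_background, blank = stack$blank)
  iref <- which(angles == min(angles))[1]
  ref_gray <- to_grayscale(frames[[iref]])
  out <- vector("list", length(frames))
  failures <- character(0)
  for (i in seq_along(frames)) {
    if (i == iref) {
      out[[i]] <- list(rgb = frames[[i]]$pixels * 1.0, gray = ref_gray,
                       validity = matrix(TRUE, nrow(ref_gray), ncol(ref_gray)),
                       transform = rigid_transform(
                         0, c(0, 0),
                         image_center(nrow(ref_gray), ncol(ref_gray)), 1),
                       angle_deg = angles[i])
      next
    }
    reg <- register_frame(ref_gray, frames[[i]], quality_floor = quality_floor,
                          refine_rotation = refine_rotation)
    if (reg$transform$quality < quality_floor)
      failures <- c(failures, format(angles[i]))
    out[[i]] <- reg
  }
  if (length(failures))
    stop("registration failed at angle(s): ", paste(failures, collapse = ", "))
  structure(list(frames = out, schedule = stack$schedule,
                 reference_angle = angles[iref]),
            class = "registered_stack")
}

#' Serialize transforms of a registered stack to JSON
#'
#' @param registered a `registered_stack`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_transforms_json <- function(registered, path) {
  rows <- lapply(registered$frames, function(f)
    list(angle_deg = f$angle_deg,
         rotation_deg = f$transform$rotation_deg,
         dx = f$transform$translation_xy[1],
         dy = f$transform$translation_xy[2],
         quality = f$transform$quality))
  jsonlite::write_json(rows, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
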