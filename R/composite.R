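# Per-pixel maximum-intensity compositing of co-registered frames.
# The maximum is taken on the grayscale projection and the winning
# frame's RGB triplet is copied, so composite colors are realizable
# colors from some input; ties go to the lowest acquisition angle.

composite_image <- function(rgb, gray, source_index, validity,
                            schedule = NULL, transforms = NULL) {
  structure(list(rgb = rgb, gray = gray, source_index = source_index,
                 validity = validity, schedule = schedule,
                 transforms = transforms),
            class = "composite_image")
}

#' @export
print.composite_image <- function(x, ...) {
  cat(sprintf("<composite_image> %d x %d px, %d source frames%s\n",
              nrow(x$gray), ncol(x$gray),
              length(unique(x$source_index[x$validity])),
              if (is.null(x$schedule)) "" else paste0(", ",
                schedule_id(x$schedule))))
  invisible(x)
}

# Running-maximum accumulator used by both the materialized and the
# streaming composite paths.
new_accumulator <- function() {
  list(rgb = NULL, gray = NULL, source = NULL, validity = NULL)
}

accumulate_frame <- function(acc, frame, index) {
  if (is.null(acc$gray)) {
    acc$rgb <- frame$rgb * 1.0
    acc$gray <- frame$gray
    acc$source <- matrix(index, nrow(frame$gray), ncol(frame$gray))
    acc$validity <- frame$validity
    return(acc)
  }
  upd <- frame$gray > acc$gray   # strict: ties keep the earlier frame
  acc$gray[upd] <- frame$gray[upd]
  acc$source[upd] <- index
  for (ch in 1:3) {
    pl <- acc$rgb[, , ch]
    fl <- frame$rgb[, , ch]
    pl[upd] <- fl[upd]
    acc$rgb[, , ch] <- pl
  }
  acc$validity <- acc$validity & frame$validity
  acc
}

finish_accumulator <- function(acc, schedule = NULL, transforms = NULL) {
  if (is.null(acc$gray)) stop("cannot composite an empty stack")
  composite_image(acc$rgb, acc$gray, acc$source, acc$validity,
                  schedule, transforms)
}

#' Maximum-intensity composite of a registered stack
#'
#' At each pixel the source frame with the maximal grayscale intensity
#' is selected and its RGB triplet copied; ties are broken by the lowest
#' acquisition angle.  Validity is the intersection of the input
#' validity masks.
#'
#' @param registered a `registered_stack` from [register_stack()], or a
#'   plain list of frames each holding `rgb`, `gray`, `validity`.
#' @return a `composite_image` with fields `rgb`, `gray`,
#'   `source_index` (which frame supplied each pixel), `validity`.
#' @export
max_composite <- function(registered) {
  frames <- if (inherits(registered, "registered_stack"))
    registered$frames else registered
  if (length(frames) == 0) stop("cannot composite an empty stack")
  acc <- new_accumulator()
  for (i in seq_along(frames)) acc <- accumulate_frame(acc, frames[[i]], i)
  finish_accumulator(
    acc,
    schedule = if (inherits(registered, "registered_stack"))
      registered$schedule,
    transforms = if (inherits(registered, "registered_stack"))
      lapply(frames, `[[`, "transform"))
}

# Streaming registration + compositing.  `frame_fun(angle)` supplies the
# raw polarized frame for one stage angle; frames are background-
# subtracted, registered to the 0-degree reference and folded into one
# running maximum per requested subset, so the whole stack is never held
# in memory.  `subsets` is a named list of logical vectors over `angles`.
stream_composites <- function(frame_fun, angles, blank,
                              subsets = list(full = rep(TRUE, length(angles))),
                              quality_floor = 0.7, refine_rotation = TRUE,
                              schedules = NULL) {
  stopifnot(length(angles) >= 1)
  o <- order(angles)
  angles <- angles[o]
  subsets <- lapply(subsets, function(s) s[o])
  accs <- lapply(subsets, function(s) new_accumulator())
  transforms <- vector("list", length(angles))
  ref_gray <- NULL
  failures <- character(0)
  for (i in seq_along(angles)) {
    raw <- frame_fun(angles[i])
    frame <- if (is.null(blank)) raw else subtract_background(raw, blank)
    if (i == 1) {
      ref_gray <- to_grayscale(frame)
      reg <- list(rgb = frame$pixels * 1.0, gray = ref_gray,
                  validity = matrix(TRUE, nrow(ref_gray), ncol(ref_gray)),
                  transform = rigid_transform(
                    0, c(0, 0),
                    image_center(nrow(ref_gray), ncol(ref_gray)), 1),
                  angle_deg = angles[i])
    } else {
      reg <- register_frame(ref_gray, frame, quality_floor = quality_floor,
                            refine_rotation = refine_rotation)
      if (reg$transform$quality < quality_floor)
        failures <- c(failures, format(angles[i]))
    }
    transforms[[i]] <- reg$transform
    for (nm in names(subsets))
      if (subsets[[nm]][i]) accs[[nm]] <- accumulate_frame(accs[[nm]], reg, i)
  }
  if (length(failures))
    stop("registration failed at angle(s): ", paste(failures, collapse = ", "))
  out <- lapply(names(accs), function(nm)
    finish_accumulator(accs[[nm]],
                       schedule = if (!is.null(schedules)) schedules[[nm]],
                       transforms = transforms))
  names(out) <- names(accs)
  out
}

#' Build composites of a phantom over an acquisition schedule
#'
#' Renders the phantom frame by frame at the scheduled angles, subtracts
#' the rendered blank, registers every frame to the 0-degree reference
#' and folds the frames into per-pixel maximum composites --- one per
#' requested rotation range, all sharing the same registration (the low
#' and high half-range composites use the subset of full-range frames
#' below / from 180 degrees).
#'
#' @param phantom a `psr_phantom`.
#' @param delta_theta_deg angular increment in degrees.
#' @param ranges character vector among `"full"`, `"low"`, `"high"`.
#' @param noise logical; render frames with acquisition noise.
#' @param quality_floor registration quality floor.
#' @param refine_rotation logical; passed to the registrar.
#' @return a single `composite_image` if one range is requested, else a
#'   named list of them.
#' @export
compose_phantom <- function(phantom, delta_theta_deg = 60,
                            ranges = "full", noise = TRUE,
                            quality_floor = 0.7, refine_rotation = TRUE) {
  stopifnot(inherits(phantom, "psr_phantom"),
            all(ranges %in% c("full", "low", "high")))
  angles <- schedule_angles(delta_theta_deg, "full")
  subsets <- lapply(ranges, function(rg)
    angles %in% schedule_angles(delta_theta_deg, rg))
  names(subsets) <- ranges
  # only render the frames some requested range actually uses
  used <- Reduce(`|`, subsets)
  angles <- angles[used]
  subsets <- lapply(subsets, function(s) s[used])
  schedules <- lapply(ranges, acquisition_schedule,
                      delta_theta_deg = delta_theta_deg)
  names(schedules) <- ranges
  blank <- render_blank(phantom$spec, noise = noise)
  out <- stream_composites(
    function(a) render_polarized(phantom, a, noise = noise),
    angles, blank, subsets,
    quality_floor = quality_floor, refine_rotation = refine_rotation,
    schedules = schedules)
  if (length(out) == 1L) out[[1]] else out
}

#' Write a composite and its sidecar planes as TIFFs
#'
#' Writes `<prefix>.tif` (RGB), `<prefix>_gray.tif` (rounded grayscale),
#' `<prefix>_source.tif` (source-frame index) and `<prefix>_valid.tif`
#' (0/1 validity).
#'
#' @param composite a `composite_image`.
#' @param prefix output path prefix.
#' @return the RGB path, invisibly.
#' @export
write_composite <- function(composite, prefix) {
  stopifnot(inherits(composite, "composite_image"))
  write_tiff16(round(composite$rgb), paste0(prefix, ".tif"))
  write_tiff16(round(composite$gray), paste0(prefix, "_gray.tif"))
  write_tiff16(composite$source_index, paste0(prefix, "_source.tif"))
  write_tiff16(composite$validity * 1L, paste0(prefix, "_valid.tif"))
  invisible(paste0(prefix, ".tif"))
}
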