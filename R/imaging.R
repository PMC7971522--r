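#' Construct a polarized-light microscopy image
#'
#' A single RGB frame of 12-bit camera counts together with its nominal
#' stage rotation angle and acquisition kind.
#'
#' @param pixels integer array of dimension H x W x 3 with values in
#'   \[0, 4095\].
#' @param angle_deg nominal stage rotation angle in degrees
#'   (counterclockwise-positive); `NA` for blank/brightfield frames.
#' @param kind one of `"polarized"`, `"brightfield"`, `"blank"`.
#' @param pixel_size_um physical size of one pixel in micrometers.
#' @return an object of class `polarized_image`.
#' @export
polarized_image <- function(pixels, angle_deg = NA_real_,
                            kind = c("polarized", "brightfield", "blank"),
                            pixel_size_um = NA_real_) {
  kind <- match.arg(kind)
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("`pixels` must be an H x W x 3 array")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > MAX_COUNT)
    stop("pixel counts must lie in [0, 4095] (12-bit range)")
  if (any(pixels != round(pixels)))
    stop("pixel counts must be integers")
  storage.mode(pixels) <- "integer"
  structure(
    list(pixels = pixels, angle_deg = angle_deg, kind = kind,
         pixel_size_um = pixel_size_um),
    class = "polarized_image"
  )
}

#' @export
print.polarized_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<polarized_image> %d x %d px, kind=%s, angle=%s deg\n",
              d[1], d[2], x$kind,
              if (is.na(x$angle_deg)) "NA" else format(x$angle_deg)))
  invisible(x)
}

#' Blank-slide background subtraction
#'
#' Subtracts the blank-slide image from a sample image pixel by pixel and
#' channel by channel, clamping at zero (negative light is unphysical and
#' downstream thresholding assumes nonnegative counts).
#'
#' @param image a `polarized_image` or H x W x 3 array.
#' @param blank the blank-slide image acquired under the same illumination
#'   (same shape).
#' @return same type as `image`, with integer counts.
#' @export
subtract_background <- function(image, blank) {
  ipx <- if (inherits(image, "polarized_image")) image$pixels else image
  bpx <- if (inherits(blank, "polarized_image")) blank$pixels else blank
  if (!identical(dim(ipx), dim(bpx)))
    stop(sprintf("shape mismatch: image is %s, blank is %s",
                 paste(dim(ipx), collapse = "x"),
                 paste(dim(bpx), collapse = "x")))
  if (inherits(image, "polarized_image") && inherits(blank, "polarized_image")) {
    if (image$kind == "polarized" && blank$kind == "brightfield")
      stop("a polarized image requires a polarized blank, not a brightfield one")
  }
  out <- pmax(ipx - bpx, 0L)
  dim(out) <- dim(ipx)
  storage.mode(out) <- "integer"
  if (inherits(image, "polarized_image")) {
    image$pixels <- out
    image
  } else out
}

#' RGB to grayscale conversion
#'
#' Converts an RGB count image to grayscale intensity with the ITU-R
#' BT.601 luma weights (0.2989, 0.5870, 0.1140).  The result is kept as
#' real-valued counts: no re-quantization happens before thresholding.
#'
#' @param rgb a `polarized_image`, an H x W x 3 array, or a
#'   `composite_image` (its `gray` plane is returned).
#' @return an H x W numeric matrix of real-valued counts.
#' @export
to_grayscale <- function(rgb) {
  if (inherits(rgb, "composite_image")) return(rgb$gray)
  px <- if (inherits(rgb, "polarized_image")) rgb$pixels else rgb
  if (length(dim(px)) != 3L || dim(px)[3] != 3L)
    stop("`rgb` must be an H x W x 3 array")
  g <- LUMA_WEIGHTS[["r"]] * px[, , 1] +
    LUMA_WEIGHTS[["g"]] * px[, , 2] +
    LUMA_WEIGHTS[["b"]] * px[, , 3]
  dim(g) <- dim(px)[1:2]  # guard against drop for 1-pixel extents
  g
}
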