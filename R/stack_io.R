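# Acquisition stacks on disk: one 16-bit TIFF per frame plus a JSON
# manifest listing file, kind, nominal and realized stage angle.

#' Bundle polarized frames with their blank and bright-field images
#'
#' @param images list of [polarized_image()] of kind `"polarized"`, one
#'   per scheduled angle, all the same shape.
#' @param blank the blank-slide [polarized_image()].
#' @param brightfield the unpolarized bright-field [polarized_image()].
#' @param schedule optional [acquisition_schedule()]; when given, the
#'   stack must contain exactly one image per scheduled angle.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(images, blank = NULL, brightfield = NULL,
                        schedule = NULL) {
  if (length(images) < 1) stop("a stack needs at least one polarized image")
  angles <- vapply(images, function(im) im$angle_deg, numeric(1))
  if (anyNA(angles)) stop("every polarized image needs a stage angle")
  if (is.unsorted(angles, strictly = TRUE)) {
    if (anyDuplicated(angles))
      stop("duplicate stage angle(s): ",
           paste(unique(angles[duplicated(angles)]), collapse = ", "))
    o <- order(angles)
    images <- images[o]
    angles <- angles[o]
  }
  dims <- lapply(images, function(im) dim(im$pixels))
  if (!all(vapply(dims, identical, logical(1), dims[[1]])))
    stop("all images in a stack must share dimensions")
  for (extra in list(blank, brightfield)) {
    if (!is.null(extra) && !identical(dim(extra$pixels), dims[[1]]))
      stop("blank/brightfield dimensions do not match the stack")
  }
  if (!is.null(schedule) &&
      !isTRUE(all.equal(angles, schedule$angles_deg)))
    stop("stack angles do not match the acquisition schedule")
  structure(list(images = images, blank = blank, brightfield = brightfield,
                 schedule = schedule),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d polarized frames%s%s\n", length(x$images),
              if (is.null(x$blank)) "" else " + blank",
              if (is.null(x$brightfield)) "" else " + brightfield"))
  invisible(x)
}

#' Save an image stack as TIFFs plus a JSON manifest
#'
#' @param stack an [image_stack()].
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
save_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "image_stack"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  entries <- list()
  add <- function(img, file) {
    write_tiff16(img$pixels, file.path(dir, file))
    entries[[length(entries) + 1]] <<- list(
      file = file, kind = img$kind,
      angle_deg = if (is.na(img$angle_deg)) NULL else img$angle_deg,
      realized_angle_deg = attr(img, "realized_angle_deg"))
  }
  for (i in seq_along(stack$images))
    add(stack$images[[i]], sprintf("pol_%03d.tif", i))
  if (!is.null(stack$blank)) add(stack$blank, "blank.tif")
  if (!is.null(stack$brightfield)) add(stack$brightfield, "brightfield.tif")
  manifest <- list(
    pixel_size_um = stack$images[[1]]$pixel_size_um,
    delta_theta_deg = if (!is.null(stack$schedule))
      stack$schedule$delta_theta_deg else NULL,
    rotation_range = if (!is.null(stack$schedule))
      stack$schedule$rotation_range else NULL,
    images = entries
  )
  path <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load an image stack from a manifest
#'
#' @param manifest_path path to the `manifest.json` written by
#'   [save_stack()].  The manifest must list exactly one blank, one
#'   brightfield and at least one polarized image with distinct angles.
#' @return an [image_stack()].
#' @export
load_stack <- function(manifest_path) {
  if (!file.exists(manifest_path)) stop("manifest not found: ", manifest_path)
  m <- jsonlite::read_json(manifest_path)
  dir <- dirname(manifest_path)
  psz <- m$pixel_size_um %||% NA_real_
  images <- list(); blank <- NULL; brightfield <- NULL
  for (e in m$images) {
    f <- file.path(dir, e$file)
    if (!file.exists(f))
      stop(sprintf("missing file for %s image: %s", e$kind, e$file))
    px <- read_tiff16(f)
    img <- polarized_image(px, angle_deg = as.numeric(e$angle_deg %||% NA_real_),
                           kind = e$kind, pixel_size_um = psz)
    if (!is.null(e$realized_angle_deg))
      attr(img, "realized_angle_deg") <- e$realized_angle_deg
    switch(e$kind,
           polarized = {images[[length(images) + 1]] <- img},
           blank = {blank <- img},
           brightfield = {brightfield <- img})
  }
  if (is.null(blank)) stop("manifest is missing the blank image")
  if (is.null(brightfield)) stop("manifest is missing the brightfield image")
  angles <- vapply(images, function(im) im$angle_deg, numeric(1))
  if (anyDuplicated(angles))
    stop("duplicate stage angle(s) in manifest: ",
         paste(unique(angles[duplicated(angles)]), collapse = ", "))
  schedule <- if (!is.null(m$delta_theta_deg))
    acquisition_schedule(m$delta_theta_deg, m$rotation_range %||% "full")
  image_stack(images, blank = blank, brightfield = brightfield,
              schedule = schedule)
}

#' Write a contour as a CSV vertex list
#'
#' Columns `x`, `y` in pixel coordinates; the closed ring is implied
#' (last vertex connects back to the first).
#'
#' @param contour a `psr_contour` (see [circle_contour()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  stopifnot(inherits(contour, "psr_contour"))
  write.csv(data.frame(x = contour$vertices[, 1], y = contour$vertices[, 2]),
            path, row.names = FALSE)
  invisible(path)
}

#' Read a contour from a CSV vertex list
#'
#' @param path CSV with columns `x`, `y`.
#' @param label contour label, `"lumen"` or `"core"`.
#' @return a `psr_contour`.
#' @export
read_contour_csv <- function(path, label = c("lumen", "core")) {
  label <- match.arg(label)
  df <- read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("contour CSV needs columns `x` and `y`")
  psr_contour(cbind(df$x, df$y), label)
}
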