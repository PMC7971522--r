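# Cap-region geometry: lumen/core contours, the lumen center, and the
# partition of the cap into one-degree sectors about that center.
#
# Sectors are materialized by polar-angle binning of pixels (angle 0 =
# +x axis, increasing counterclockwise on screen, sector d covering
# [d, d+1) degrees).  This is geometrically equivalent to rasterizing
# explicit one-degree ray polygons but guarantees an exact partition
# with no double-counted boundary pixels.

#' Construct a contour
#'
#' @param vertices n x 2 matrix of (x, y) pixel coordinates forming a
#'   closed ring (the closing edge is implied).
#' @param label `"lumen"` or `"core"`.
#' @return object of class `psr_contour`.
#' @export
psr_contour <- function(vertices, label = c("lumen", "core")) {
  label <- match.arg(label)
  vertices <- as.matrix(vertices)
  if (nrow(vertices) < 3 || ncol(vertices) != 2)
    stop("a contour needs at least 3 (x, y) vertices")
  structure(list(vertices = vertices, label = label), class = "psr_contour")
}

#' Circle contour polygon
#'
#' @param center_xy (x, y) center in pixels.
#' @param radius_px radius in pixels.
#' @param n_vertices number of polygon vertices.
#' @param label contour label.
#' @return a [psr_contour()].
#' @export
circle_contour <- function(center_xy, radius_px, n_vertices = 360,
                           label = c("lumen", "core")) {
  a <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  psr_contour(cbind(center_xy[1] + radius_px * cos(a),
                    center_xy[2] - radius_px * sin(a)),
              match.arg(label))
}

polygon_signed_area <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Lumen center point
#'
#' Area centroid of the lumen polygon; an explicit override point may be
#' supplied instead (the ray origin need not be the centroid).
#'
#' @param lumen_contour a [psr_contour()].
#' @param override optional (x, y) point used verbatim.
#' @return numeric (x, y).
#' @export
lumen_center <- function(lumen_contour, override = NULL) {
  if (!is.null(override)) return(as.numeric(override))
  stopifnot(inherits(lumen_contour, "psr_contour"))
  v <- lumen_contour$vertices
  a <- polygon_signed_area(v)
  if (abs(a) < 1e-9) stop("degenerate lumen polygon (zero area)")
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Even-odd point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, vertices) {
  n <- nrow(vertices)
  inside <- logical(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vertices[i, 1]; yi <- vertices[i, 2]
    xj <- vertices[j, 1]; yj <- vertices[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Radius of the first crossing of rays from `center` with a polygon, for
# a vector of ray angles (degrees, counterclockwise from +x, y down on
# screen).  NA where a ray misses the polygon.
ray_radii <- function(center, vertices, angles_deg) {
  ux <- cos(angles_deg * pi / 180)
  uy <- -sin(angles_deg * pi / 180)
  n <- nrow(vertices)
  best <- rep(Inf, length(angles_deg))
  j <- n
  for (i in seq_len(n)) {
    p1 <- vertices[j, ]; p2 <- vertices[i, ]
    ex <- p2[1] - p1[1]; ey <- p2[2] - p1[2]
    wx <- p1[1] - center[1]; wy <- p1[2] - center[2]
    den <- ux * ey - uy * ex
    ok <- abs(den) > 1e-12
    t <- (wx * ey - wy * ex) / den
    s <- (wx * uy - wy * ux) / den
    # closed interval with tolerance: a ray through a shared vertex may
    # otherwise numerically miss both adjacent edges; duplicate hits are
    # harmless under the min-radius reduction
    hit <- ok & s >= -1e-9 & s <= 1 + 1e-9 & t > 1e-9
    best <- ifelse(hit & t < best, t, best)
    j <- i
  }
  ifelse(is.finite(best), best, NA_real_)
}

#' Partition the cap region into one-degree sectors
#'
#' Casts a ray from the center at each degree `d + 0.5`; sectors whose
#' ray intersects the core contour are active.  A pixel belongs to
#' sector `d` when its polar angle about the center falls in
#' \[d, d+1), it lies outside the lumen boundary, and its radius is
#' smaller than the first ("leading") core-contour crossing along its
#' own polar direction.
#'
#' @param lumen_contour,core_contour [psr_contour()] objects.
#' @param image_shape_hw integer (height, width) of the image frame.
#' @param center optional ray origin; defaults to the lumen centroid.
#'   Must lie strictly inside the lumen polygon.
#' @return object of class `sector_mask`: `labels` (H x W integer,
#'   sector 0--359 for cap pixels, -1 elsewhere), `center_xy`,
#'   `active_degrees`.
#' @export
cap_sector_mask <- function(lumen_contour, core_contour, image_shape_hw,
                            center = NULL) {
  stopifnot(inherits(lumen_contour, "psr_contour"),
            inherits(core_contour, "psr_contour"))
  center <- lumen_center(lumen_contour, override = center)
  if (!point_in_polygon(center[1], center[2], lumen_contour$vertices))
    stop("center must lie strictly inside the lumen polygon")
  h <- as.integer(image_shape_hw[1]); w <- as.integer(image_shape_hw[2])

  active <- which(!is.na(ray_radii(center, core_contour$vertices,
                                   0:359 + 0.5))) - 1L

  # dense radial profiles of both boundaries, interpolated per pixel
  grid_step <- 0.1
  grid <- seq(0, 360 - grid_step, by = grid_step)
  r_core <- ray_radii(center, core_contour$vertices, grid)
  r_lumen <- ray_radii(center, lumen_contour$vertices, grid)

  xg <- matrix(seq_len(w) - 1, h, w, byrow = TRUE)
  yg <- matrix(seq_len(h) - 1, h, w)
  dx <- xg - center[1]; dy <- yg - center[2]
  r <- sqrt(dx^2 + dy^2)
  ang <- (atan2(-dy, dx) * 180 / pi) %% 360
  gi <- (round(ang / grid_step) %% length(grid)) + 1L
  deg <- floor(ang)
  labels <- matrix(-1L, h, w)
  ok <- !is.na(r_core[gi]) & !is.na(r_lumen[gi]) &
    r > r_lumen[gi] & r < r_core[gi] & (deg %in% active)
  labels[ok] <- as.integer(deg[ok])
  structure(list(labels = labels, center_xy = center,
                 active_degrees = as.integer(active)),
            class = "sector_mask")
}

#' @export
print.sector_mask <- function(x, ...) {
  cat(sprintf("<sector_mask> %d x %d px, %d active degrees, %d cap pixels\n",
              nrow(x$labels), ncol(x$labels), length(x$active_degrees),
              sum(x$labels >= 0)))
  invisible(x)
}

#' Union of all active sectors
#'
#' @param mask a [cap_sector_mask()].
#' @return H x W logical matrix: the cap region.
#' @export
sector_union <- function(mask) {
  stopifnot(inherits(mask, "sector_mask"))
  mask$labels >= 0L
}

#' Cap sector mask of a phantom, from its ground-truth contours
#'
#' @param phantom a `psr_phantom`.
#' @param center optional ray-origin override.
#' @return a [cap_sector_mask()].
#' @export
phantom_sector_mask <- function(phantom, center = NULL) {
  stopifnot(inherits(phantom, "psr_phantom"))
  cap_sector_mask(phantom$lumen_contour, phantom$core_contour,
                  c(phantom$spec$image_height_px, phantom$spec$image_width_px),
                  center = center)
}

#' Write a sector mask as a 16-bit TIFF
#'
#' Labels are stored shifted by one (0 = background, d+1 = sector d).
#'
#' @param mask a [cap_sector_mask()].
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_sector_mask_tiff <- function(mask, path) {
  write_tiff16(mask$labels + 1L, path)
}
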