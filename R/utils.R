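# Shared constants and small helpers.

# ITU-R BT.601 luma weights used for all RGB -> grayscale conversion.
LUMA_WEIGHTS <- c(r = 0.2989, g = 0.5870, b = 0.1140)

# Orange fiber tint whose luma equals exactly 1, so that a fiber of
# polarized intensity I has grayscale value I (before quantization).
FIBER_TINT <- c(
  r = 1.70,
  g = 0.75,
  b = (1 - 0.2989 * 1.70 - 0.5870 * 0.75) / 0.1140
)

MAX_COUNT <- 4095L  # 12-bit camera full scale

#' Convert a sensor sampling density to micrometers per pixel
#'
#' @param px_per_mm pixels per millimeter of the imaging system.
#' @param digits decimal places to round to (default 2).
#' @return micrometers per pixel, e.g. `um_per_px(230)` is 4.35.
#' @export
um_per_px <- function(px_per_mm, digits = 2) {
  stopifnot(is.numeric(px_per_mm), px_per_mm > 0)
  round(1000 / px_per_mm, digits)
}

# Run `code` with a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed %% 2147483647))
  force(code)
}

# Geometric center of an H x W pixel grid in (x, y) 0-based coordinates.
image_center <- function(height, width) {
  c((width - 1) / 2, (height - 1) / 2)
}

# Rotation by `deg` counterclockwise on screen (x right, y down),
# applied to an n x 2 matrix of (x, y) offsets.
rotate_xy <- function(xy, deg) {
  ct <- cos(deg * pi / 180)
  st <- sin(deg * pi / 180)
  cbind(ct * xy[, 1] + st * xy[, 2], -st * xy[, 1] + ct * xy[, 2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
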