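# Collagen quantification on the composite: grayscale intensity
# statistics and thresholded collagen-positive pixel counting, per
# one-degree sector and in total, plus the threshold sweep and the
# schedule comparison tables.

#' Quantification configuration
#'
#' @param threshold_counts intensity threshold for collagen-positive
#'   pixels (default 600 counts, derived in the source protocol from the
#'   lumen-area intensity mean of 300 and SD of 232 counts after
#'   background correction).
#' @param sweep_thresholds thresholds for [threshold_sweep()].
#' @return object of class `quant_config`.
#' @export
quant_config <- function(threshold_counts = 600,
                         sweep_thresholds = seq(0, 1000, by = 25)) {
  if (threshold_counts < 0) stop("threshold must be >= 0")
  if (any(sweep_thresholds < 0) || is.unsorted(sweep_thresholds))
    stop("sweep thresholds must be nonnegative and ascending")
  structure(list(threshold_counts = threshold_counts,
                 sweep_thresholds = sweep_thresholds),
            class = "quant_config")
}

cap_gray <- function(composite_gray, mask) {
  gray <- if (inherits(composite_gray, "composite_image")) {
    if (!all(composite_gray$validity[mask$labels >= 0L]))
      stop("composite does not cover the whole cap region (invalid pixels)")
    composite_gray$gray
  } else composite_gray
  if (!identical(dim(gray), dim(mask$labels)))
    stop("mask and image shapes differ")
  gray
}

per_degree_frame <- function(mask) {
  data.frame(degree = mask$active_degrees,
             area_px = as.integer(table(factor(mask$labels[mask$labels >= 0L],
                                               levels = mask$active_degrees))))
}

#' Per-degree and total grayscale intensity in the cap
#'
#' @param composite_gray H x W grayscale matrix (real counts) or a
#'   `composite_image`.
#' @param mask a [cap_sector_mask()].
#' @return object of class `quant_result` holding the per-degree table
#'   (`degree`, `area_px`, `intensity_sum`, `intensity_mean`) and totals.
#' @export
intensity_stats <- function(composite_gray, mask) {
  gray <- cap_gray(composite_gray, mask)
  if (length(mask$active_degrees) == 0)
    stop("no active degrees: the core contour is never hit by a sector ray")
  sel <- mask$labels >= 0L
  f <- factor(mask$labels[sel], levels = mask$active_degrees)
  df <- per_degree_frame(mask)
  df$intensity_sum <- as.numeric(rowsum(gray[sel], f, reorder = FALSE))
  df$intensity_mean <- ifelse(df$area_px > 0, df$intensity_sum / df$area_px, 0)
  quant_result(df, threshold = NA_real_)
}

#' Collagen-positive pixel counts in the cap
#'
#' A pixel is collagen-positive when its grayscale value is strictly
#' greater than the threshold.
#'
#' @inheritParams intensity_stats
#' @param threshold intensity threshold in counts.
#' @return a `quant_result` with per-degree and total `positive_count`.
#' @export
count_positive <- function(composite_gray, mask, threshold = 600) {
  stopifnot(threshold >= 0)
  gray <- cap_gray(composite_gray, mask)
  if (length(mask$active_degrees) == 0)
    stop("no active degrees: the core contour is never hit by a sector ray")
  sel <- mask$labels >= 0L
  f <- factor(mask$labels[sel], levels = mask$active_degrees)
  df <- per_degree_frame(mask)
  df$positive_count <- as.integer(rowsum((gray[sel] > threshold) * 1L, f,
                                         reorder = FALSE))
  quant_result(df, threshold = threshold)
}

quant_result <- function(per_degree, threshold = NA_real_,
                         schedule_id = NA_character_) {
  totals <- list(
    area_px = sum(per_degree$area_px),
    intensity_sum = if ("intensity_sum" %in% names(per_degree))
      sum(per_degree$intensity_sum) else NA_real_,
    positive_count = if ("positive_count" %in% names(per_degree))
      sum(per_degree$positive_count) else NA_integer_
  )
  totals$intensity_mean <- if (!is.na(totals$intensity_sum) && totals$area_px > 0)
    totals$intensity_sum / totals$area_px else NA_real_
  structure(list(per_degree = per_degree, totals = totals,
                 threshold = threshold, schedule_id = schedule_id),
            class = "quant_result")
}

#' @export
print.quant_result <- function(x, ...) {
  cat(sprintf(paste0("<quant_result> %d active degrees, cap area %d px, ",
                     "total intensity %s, positive pixels %s (threshold %s)\n"),
              nrow(x$per_degree), x$totals$area_px,
              format(x$totals$intensity_sum), format(x$totals$positive_count),
              format(x$threshold)))
  invisible(x)
}

#' Full cap quantification of a composite
#'
#' Combines [intensity_stats()] and [count_positive()] into one result.
#'
#' @param composite a `composite_image` or grayscale matrix.
#' @param mask a [cap_sector_mask()].
#' @param config a [quant_config()].
#' @return a `quant_result` whose per-degree table has both the
#'   intensity and the count columns.
#' @export
quantify_cap <- function(composite, mask, config = quant_config()) {
  ints <- intensity_stats(composite, mask)
  cnts <- count_positive(composite, mask, config$threshold_counts)
  df <- ints$per_degree
  df$positive_count <- cnts$per_degree$positive_count
  sid <- if (inherits(composite, "composite_image") &&
             !is.null(composite$schedule))
    schedule_id(composite$schedule) else NA_character_
  quant_result(df, threshold = config$threshold_counts, schedule_id = sid)
}

#' Positive-pixel totals as a function of the intensity threshold
#'
#' @inheritParams intensity_stats
#' @param thresholds ascending thresholds in counts.
#' @return data frame with `threshold`, `positive_count` and `relative`
#'   (count relative to the no-threshold count, i.e. threshold 0).
#' @export
threshold_sweep <- function(composite_gray, mask,
                            thresholds = seq(0, 1000, by = 25)) {
  if (is.unsorted(thresholds)) stop("thresholds must be ascending")
  gray <- cap_gray(composite_gray, mask)
  vals <- gray[mask$labels >= 0L]
  counts <- vapply(thresholds, function(t) sum(vals > t), numeric(1))
  baseline <- sum(vals > 0)
  data.frame(threshold = thresholds,
             positive_count = as.integer(counts),
             relative = if (baseline > 0) counts / baseline else NA_real_)
}

#' Compare quantification results across acquisition schedules
#'
#' Ratios of total cap intensity and total positive counts of each
#' schedule against a designated reference schedule.  All results must
#' come from composites quantified with identical sector masks.
#'
#' @param results named list of `quant_result` (names identify the
#'   schedules).
#' @param reference name of the reference entry (default the last one).
#' @return data frame with one row per schedule: totals and ratios
#'   versus the reference.
#' @export
compare_schedules <- function(results, reference = names(results)[length(results)]) {
  stopifnot(length(results) >= 1, !is.null(names(results)),
            reference %in% names(results))
  areas <- lapply(results, function(r) r$per_degree$area_px)
  if (!all(vapply(areas, identical, logical(1), areas[[1]])))
    stop("results were computed on mismatched masks")
  ref <- results[[reference]]
  data.frame(
    schedule = names(results),
    intensity_total = vapply(results, function(r) r$totals$intensity_sum,
                             numeric(1)),
    count_total = vapply(results, function(r)
      as.numeric(r$totals$positive_count), numeric(1)),
    intensity_ratio = vapply(results, function(r)
      r$totals$intensity_sum / ref$totals$intensity_sum, numeric(1)),
    count_ratio = vapply(results, function(r)
      as.numeric(r$totals$positive_count) /
        as.numeric(ref$totals$positive_count), numeric(1)),
    row.names = NULL
  )
}

#' Lumen-area intensity statistics
#'
#' Mean and SD of composite grayscale intensity over the lumen interior,
#' for users wishing to re-derive an intensity threshold from their own
#' material (the default 600-count threshold was chosen from such lumen
#' statistics).
#'
#' @param composite_gray grayscale matrix or `composite_image`.
#' @param lumen_contour the lumen [psr_contour()].
#' @return list with `mean`, `sd` and `n_px`.
#' @export
lumen_reference_stats <- function(composite_gray, lumen_contour) {
  gray <- if (inherits(composite_gray, "composite_image"))
    composite_gray$gray else composite_gray
  v <- lumen_contour$vertices
  xr <- range(v[, 1]); yr <- range(v[, 2])
  xs <- max(0, floor(xr[1])):min(ncol(gray) - 1, ceiling(xr[2]))
  ys <- max(0, floor(yr[1])):min(nrow(gray) - 1, ceiling(yr[2]))
  px <- rep(xs, each = length(ys)); py <- rep(ys, times = length(xs))
  inside <- point_in_polygon(px, py, v)
  vals <- gray[cbind(py[inside] + 1L, px[inside] + 1L)]
  list(mean = mean(vals), sd = sd(vals), n_px = length(vals))
}

#' Write a quantification result as CSV plus a JSON summary
#'
#' @param result a `quant_result`.
#' @param prefix output path prefix (`<prefix>.csv`, `<prefix>.json`).
#' @return `prefix`, invisibly.
#' @export
write_quant_result <- function(result, prefix) {
  stopifnot(inherits(result, "quant_result"))
  write.csv(result$per_degree, paste0(prefix, ".csv"), row.names = FALSE)
  jsonlite::write_json(
    list(totals = result$totals, threshold = result$threshold,
         schedule = result$schedule_id),
    paste0(prefix, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
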