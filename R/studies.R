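# End-to-end study drivers on phantoms: the angular-increment study (15
# composites per sample: 5 increments x 3 rotation ranges), the
# intensity-threshold sweep and the serial-section repeatability /
# responsivity analog.  All reports are plain data frames; with fixed
# seeds every driver is deterministic end to end.

#' Configure a phantom study
#'
#' @param base_spec a [phantom_spec()] template; each sample reuses it
#'   with its own seed.
#' @param delta_grid angular increments in degrees (default the study
#'   grid 2, 6, 12, 44, 60, which divides 180 degrees approximately
#'   equally).
#' @param ranges rotation ranges to composite.
#' @param reference_delta increment of the reference schedule
#'   (default 60, full range).
#' @param n_samples number of phantom samples.
#' @param seeds per-sample seeds (default `1:n_samples`).
#' @param n_serial_sections sections per block for the repeatability
#'   study.
#' @param thickness_cv coefficient of variation of section thickness.
#' @param cap_trend core-inner-radius shrink (px per section).
#' @param config a [quant_config()] (threshold and sweep grid).
#' @param noise logical; render with acquisition noise.
#' @return object of class `study_config`.
#' @export
study_config <- function(base_spec = phantom_spec(),
                         delta_grid = c(2, 6, 12, 44, 60),
                         ranges = c("full", "low", "high"),
                         reference_delta = 60,
                         n_samples = 6L,
                         seeds = NULL,
                         n_serial_sections = 30L,
                         thickness_cv = 0.15,
                         cap_trend = 0,
                         config = quant_config(),
                         noise = TRUE) {
  if (!(reference_delta %in% delta_grid))
    stop("the reference schedule must be part of the increment grid")
  seeds <- seeds %||% seq_len(n_samples)
  if (length(seeds) != n_samples) stop("need one seed per sample")
  structure(list(base_spec = base_spec, delta_grid = delta_grid,
                 ranges = ranges, reference_delta = reference_delta,
                 n_samples = as.integer(n_samples), seeds = as.integer(seeds),
                 n_serial_sections = as.integer(n_serial_sections),
                 thickness_cv = thickness_cv, cap_trend = cap_trend,
                 config = config, noise = noise),
            class = "study_config")
}

sample_phantom <- function(cfg, seed) {
  spec <- cfg$base_spec
  spec$seed <- as.integer(seed)
  build_phantom(spec)
}

# All requested composites of one sample, quantified on one mask.
sample_results <- function(cfg, seed, deltas = cfg$delta_grid,
                           ranges = cfg$ranges) {
  ph <- sample_phantom(cfg, seed)
  mask <- phantom_sector_mask(ph)
  res <- list()
  for (d in deltas) {
    comps <- compose_phantom(ph, d, ranges = ranges, noise = cfg$noise)
    if (inherits(comps, "composite_image")) comps <- setNames(list(comps), ranges)
    for (rg in names(comps)) {
      res[[sprintf("dtheta=%g,%s", d, rg)]] <-
        quantify_cap(comps[[rg]], mask, cfg$config)
    }
  }
  res
}

#' Angular-increment study
#'
#' For each sample, builds one composite per increment and rotation
#' range (15 with the default grid), quantifies all of them with the
#' identical sector mask, and reports intensity and count ratios of each
#' full-range composite against the reference increment, and of each
#' half-range composite against the full range, with mean/SD summaries
#' across samples.
#'
#' @param cfg a [study_config()].
#' @return list with `per_sample` (data frame of totals and ratios) and
#'   `summary` (mean/SD of each ratio across samples).
#' @export
run_angle_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  rows <- list()
  for (s in seq_len(cfg$n_samples)) {
    res <- sample_results(cfg, cfg$seeds[s])
    ref <- res[[sprintf("dtheta=%g,full", cfg$reference_delta)]]
    for (d in cfg$delta_grid) {
      full <- res[[sprintf("dtheta=%g,full", d)]]
      for (rg in cfg$ranges) {
        r <- res[[sprintf("dtheta=%g,%s", d, rg)]]
        rows[[length(rows) + 1]] <- data.frame(
          sample = s, delta_theta_deg = d, range = rg,
          intensity_total = r$totals$intensity_sum,
          count_total = r$totals$positive_count,
          intensity_vs_reference = r$totals$intensity_sum /
            ref$totals$intensity_sum,
          count_vs_reference = as.numeric(r$totals$positive_count) /
            as.numeric(ref$totals$positive_count),
          intensity_vs_full = r$totals$intensity_sum /
            full$totals$intensity_sum,
          count_vs_full = as.numeric(r$totals$positive_count) /
            as.numeric(full$totals$positive_count))
      }
    }
  }
  per_sample <- do.call(rbind, rows)
  agg <- function(col) {
    m <- stats::aggregate(per_sample[[col]],
                          by = list(delta_theta_deg = per_sample$delta_theta_deg,
                                    range = per_sample$range),
                          FUN = function(x) c(mean = mean(x), sd = sd(x)))
    data.frame(delta_theta_deg = m$delta_theta_deg, range = m$range,
               metric = col, mean = m$x[, "mean"], sd = m$x[, "sd"])
  }
  summary <- do.call(rbind, lapply(
    c("intensity_vs_reference", "count_vs_reference",
      "intensity_vs_full", "count_vs_full"), agg))
  list(per_sample = per_sample, summary = summary)
}

#' Intensity-threshold study
#'
#' For each sample, sweeps the positive-pixel threshold over the
#' configured grid on the composites of the smallest and largest
#' increments (full range), reporting counts relative to no threshold.
#'
#' @param cfg a [study_config()].
#' @return data frame with `sample`, `delta_theta_deg`, `threshold`,
#'   `positive_count`, `relative`.
#' @export
run_threshold_study <- function(cfg) {
  stopifnot(inherits(cfg, "study_config"))
  deltas <- range(cfg$delta_grid)
  rows <- list()
  for (s in seq_len(cfg$n_samples)) {
    ph <- sample_phantom(cfg, cfg$seeds[s])
    mask <- phantom_sector_mask(ph)
    for (d in unique(deltas)) {
      comp <- compose_phantom(ph, d, ranges = "full", noise = cfg$noise)
      sw <- threshold_sweep(comp, mask, cfg$config$sweep_thresholds)
      rows[[length(rows) + 1]] <- cbind(sample = s, delta_theta_deg = d, sw)
    }
  }
  do.call(rbind, rows)
}

#' Serial-section repeatability and responsivity study
#'
#' Simulates serial sections with per-section thickness variation (and
#' an optional cap-thinning trend), composites and quantifies each with
#' its own ground-truth mask, and reports mean grayscale intensity and
#' positive counts per section with their across-section coefficients of
#' variation.  With a nonzero cap trend the count-versus-section slope
#' (the responsivity to cap thinning) is also reported.
#'
#' @param cfg a [study_config()]; uses `n_serial_sections`,
#'   `thickness_cv` and `cap_trend`.
#' @param delta_theta_deg increment used for the per-section composites
#'   (default the reference increment).
#' @return list with `per_section` (data frame), `cv` (list with
#'   `intensity_mean` and `positive_count` CVs) and `count_slope`
#'   (counts per section; `NA` when `cap_trend` is 0).
#' @export
run_repeatability_study <- function(cfg, delta_theta_deg = cfg$reference_delta) {
  stopifnot(inherits(cfg, "study_config"))
  spec <- cfg$base_spec
  spec$seed <- cfg$seeds[1]
  sections <- serial_sections(spec, cfg$n_serial_sections,
                              thickness_cv = cfg$thickness_cv,
                              cap_trend = cfg$cap_trend)
  rows <- lapply(seq_along(sections), function(k) {
    ph <- sections[[k]]
    mask <- phantom_sector_mask(ph)
    comp <- compose_phantom(ph, delta_theta_deg, ranges = "full",
                            noise = cfg$noise)
    q <- quantify_cap(comp, mask, cfg$config)
    data.frame(section = k,
               thickness_scale = ph$spec$thickness_scale,
               cap_area_px = q$totals$area_px,
               intensity_mean = q$totals$intensity_mean,
               positive_count = q$totals$positive_count)
  })
  per_section <- do.call(rbind, rows)
  cv <- function(x) if (mean(x) == 0) NA_real_ else sd(x) / mean(x)
  count_slope <- if (cfg$cap_trend != 0)
    unname(coef(lm(positive_count ~ section, data = per_section))[2])
  else NA_real_
  list(per_section = per_section,
       cv = list(intensity_mean = cv(per_section$intensity_mean),
                 positive_count = cv(per_section$positive_count)),
       count_slope = count_slope)
}

#' Agreement between two composites of the same sample
#'
#' Analog of an inter-operator agreement check: re-acquiring a slide
#' (different jitter/noise realization) should classify nearly the same
#' cap pixels as collagen-positive.  Reports both a pixel-wise overlap
#' (pixels classified identically in both composites, relative to the
#' average positive count) and a total-count ratio.
#'
#' @param composite_a,composite_b `composite_image`s registered to the
#'   same reference.
#' @param mask the shared [cap_sector_mask()].
#' @param threshold positive-pixel threshold in counts.
#' @return list with `pixel_agreement` and `count_ratio`.
#' @export
operator_agreement <- function(composite_a, composite_b, mask,
                               threshold = 600) {
  sel <- mask$labels >= 0L
  pa <- cap_gray(composite_a, mask)[sel] > threshold
  pb <- cap_gray(composite_b, mask)[sel] > threshold
  avg_pos <- (sum(pa) + sum(pb)) / 2
  list(pixel_agreement = if (avg_pos > 0) sum(pa & pb) / avg_pos else NA_real_,
       count_ratio = if (sum(pb) > 0) sum(pa) / sum(pb) else NA_real_)
}
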