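# Hand-built two-sector mask: degree 0 with 10 px, degree 1 with 20 px.
two_sector_mask <- function() {
  labels <- matrix(-1L, 10, 10)
  labels[1:10] <- 0L
  labels[11:30] <- 1L
  structure(list(labels = labels, center_xy = c(0, 0),
                 active_degrees = c(0L, 1L)),
            class = "sector_mask")
}

test_that("intensity stats do the stated arithmetic", {
  mask <- two_sector_mask()
  g <- matrix(100, 10, 10)
  r <- intensity_stats(g, mask)
  expect_equal(r$per_degree$intensity_sum, c(1000, 2000))
  expect_equal(r$per_degree$intensity_mean, c(100, 100))
  expect_equal(r$totals$intensity_sum, 3000)
  expect_equal(intensity_stats(matrix(0, 10, 10), mask)$totals$intensity_sum, 0)
})

test_that("positive counting is strictly greater-than", {
  mask <- two_sector_mask()
  g <- matrix(0, 10, 10)
  g[1:3] <- c(599, 600, 601)
  r <- count_positive(g, mask, 600)
  expect_equal(r$totals$positive_count, 1L)
  # threshold 0 counts exactly the positive-valued cap pixels
  g2 <- matrix(5, 10, 10)
  expect_equal(count_positive(g2, mask, 0)$totals$positive_count,
               r$totals$area_px)
})

test_that("per-degree quantities sum exactly to totals on phantoms", {
  for (seed in 1:3) {
    ph <- build_phantom(tiny_spec(seed = seed, noise_sd_counts = 20,
                                  background_level_counts = 80))
    mask <- phantom_sector_mask(ph)
    comp <- compose_phantom(ph, 120)
    q <- quantify_cap(comp, mask)
    expect_identical(sum(q$per_degree$area_px), q$totals$area_px)
    expect_equal(sum(q$per_degree$intensity_sum), q$totals$intensity_sum)
    expect_identical(sum(q$per_degree$positive_count),
                     as.integer(q$totals$positive_count))
    # brute-force masked aggregation oracle
    sel <- mask$labels >= 0L
    expect_equal(q$totals$intensity_sum, sum(comp$gray[sel]))
    expect_equal(q$totals$positive_count, sum(comp$gray[sel] > 600))
  }
})

test_that("threshold sweep is monotone with the stated extremes", {
  ph <- build_phantom(tiny_spec(seed = 2, noise_sd_counts = 20,
                                background_level_counts = 80))
  mask <- phantom_sector_mask(ph)
  comp <- compose_phantom(ph, 120)
  sw <- threshold_sweep(comp, mask, c(0, seq(100, 1000, by = 100), 1e6))
  expect_true(all(diff(sw$positive_count) <= 0))
  expect_equal(sw$relative[1], 1)
  expect_equal(sw$positive_count[1], sum(comp$gray[mask$labels >= 0L] > 0))
  expect_equal(sw$positive_count[nrow(sw)], 0L)
  expect_error(threshold_sweep(comp, mask, c(5, 1, 10)), "ascending")
})

test_that("bright phantoms keep every fiber pixel above 600 counts", {
  # background-free noise-free render: relative count at threshold 600
  # equals 1 when all fiber contributions exceed 1000 x 0.75
  ph <- build_phantom(tiny_spec(seed = 3, fiber_amplitude_range = c(2000, 3000)))
  mask <- phantom_sector_mask(ph)
  comp <- compose_phantom(ph, 60, noise = FALSE)
  sw <- threshold_sweep(comp, mask, c(0, 600))
  # the threshold-0 baseline counts every antialiased partial-coverage
  # fringe pixel; those fringes are the only pixels the 600-count
  # threshold may drop on a bright phantom
  expect_gt(sw$relative[2], 0.7)
  interior <- comp$gray[mask$labels >= 0L]
  interior <- interior[interior >= 2000 * 0.75]
  expect_true(all(interior > 600))
})

test_that("compare_schedules reports ratios against the reference", {
  ph <- build_phantom(tiny_spec(seed = 4, noise_sd_counts = 10,
                                background_level_counts = 60))
  mask <- phantom_sector_mask(ph)
  comps <- compose_phantom(ph, 60, ranges = c("full", "low"))
  q_full <- quantify_cap(comps$full, mask)
  q_low <- quantify_cap(comps$low, mask)
  tab <- compare_schedules(list(low = q_low, full = q_full),
                           reference = "full")
  expect_equal(tab$count_ratio[tab$schedule == "full"], 1)
  expect_equal(tab$intensity_ratio[tab$schedule == "full"], 1)
  expect_lte(tab$count_ratio[tab$schedule == "low"], 1)
  # arithmetic oracle
  expect_equal(tab$count_ratio[tab$schedule == "low"],
               q_low$totals$positive_count / q_full$totals$positive_count)
  # mismatched masks are refused
  other <- phantom_sector_mask(build_phantom(tiny_spec(seed = 9,
                                                       lumen_radius_px = 30)))
  q_other <- quantify_cap(compose_phantom(
    build_phantom(tiny_spec(seed = 9, lumen_radius_px = 30)), 120,
    noise = FALSE), other)
  expect_error(compare_schedules(list(a = q_other, full = q_full),
                                 reference = "full"), "mask")
})

test_that("lumen reference stats summarize the lumen interior", {
  g <- matrix(300, 100, 100)
  lumen <- circle_contour(c(50, 50), 20, label = "lumen")
  st <- lumen_reference_stats(g, lumen)
  expect_equal(st$mean, 300)
  expect_equal(st$sd, 0)
  expect_lt(abs(st$n_px - pi * 400) / (pi * 400), 0.02)
})

test_that("quant results serialize to CSV + JSON", {
  ph <- build_phantom(tiny_spec())
  mask <- phantom_sector_mask(ph)
  q <- quantify_cap(compose_phantom(ph, 120, noise = FALSE), mask)
  prefix <- file.path(withr::local_tempdir(), "q")
  write_quant_result(q, prefix)
  back <- read.csv(paste0(prefix, ".csv"))
  expect_equal(sum(back$positive_count), as.numeric(q$totals$positive_count))
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$totals$area_px, q$totals$area_px)
})
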