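# Column-width measurement, width distributions, P50, perfused diameter and
# PBR.

test_that("half-depth width of a trapezoidal profile has its closed form", {
  off <- seq(-10, 10, by = 0.25)
  # plateau 6 um, linear shoulders 2 um each: half depth crossed at |x| = 4
  prof <- 1 - 0.5 * pmin(pmax((5 - abs(off)) / 2, 0), 1)
  hw <- half_depth_width(off, prof, background = 1)
  expect_equal(hw$width_um, 8)
  expect_equal(hw$center_um, 0)
  expect_equal(hw$depth, 0.5)
  # at 80% depth the same profile is 6 + 0.4 * 2 wide
  expect_equal(half_depth_width(off, prof, background = 1,
                                level = 0.8)$width_um, 6.8)
  # a pure background profile reports no dip
  flat <- rep(1, length(off))
  expect_false(half_depth_width(off, flat, background = 1)$found)
})

test_that("a noiseless rendered column measures at its drawn width", {
  sc <- generate_scene(scene_params(n_vessels = 1, dperf_um = 7,
                                    true_pbr_um = 0, n_frames = 1,
                                    frame_shape_px = c(64, 60),
                                    noise_sd = 0, curvature_amp_px = 0,
                                    seed = 2))
  fr <- sc$stack$frames[, , 1]
  cl <- detect_vessels(fr, 1)
  seg <- partition_segments(cl[[1]], 1)[[1]]
  m <- measure_column(fr, seg, 1)
  expect_true(m$filled)
  expect_equal(m$width_um, 7, tolerance = 1)   # one pixel-equivalent
  expect_lte(m$min_width_um, m$width_um)
})

test_that("a background-only segment is unfilled with width zero", {
  sc <- default_scene(41, n_vessels = 1, n_frames = 3)
  fr <- sc$stack$frames[, , 1]
  # a synthetic segment placed in empty background, top of the frame
  cl <- straight_centerline(10.4, y0 = 8, diameter_um = 5)
  seg <- partition_segments(cl, 1)[[1]]
  m <- measure_column(fr, seg, 1)
  expect_false(m$filled)
  expect_equal(m$width_um, 0)
})

test_that("percentage RBC filling applies the all-frames rule", {
  p <- list(fake_profile(TRUE), fake_profile(TRUE), fake_profile(TRUE),
            fake_profile(FALSE))
  expect_equal(percent_rbc_filling(p), 75)
  expect_equal(percent_rbc_filling(p[1:3]), 100)
  expect_equal(percent_rbc_filling(list(fake_profile(FALSE))), 0)
  expect_warning(out <- percent_rbc_filling(list()), "undefined")
  expect_true(is.na(out))
})

test_that("the width CDF steps through pooled widths and reaches one", {
  wd <- width_distribution(c(7, 6, 8))
  expect_equal(wd$widths_um, c(6, 7, 8))
  expect_equal(wd$cum_fraction, c(1, 2, 3) / 3)
  wd2 <- width_distribution(rep(5, 10))
  expect_equal(max(wd2$cum_fraction), 1)
  expect_equal(unique(wd2$widths_um), 5)
  # class filtering pools only matching segments
  p <- list(fake_profile(TRUE, widths = c(6, 7), diameter_class = "5-9"),
            fake_profile(TRUE, widths = c(12, 13), diameter_class = "10-19"),
            fake_profile(TRUE, widths = 30, diameter_class = "none"))
  expect_equal(width_distribution(p, "5-9")$widths_um, c(6, 7))
  expect_equal(width_distribution(p, "5-25")$n, 4)
  expect_equal(width_distribution(p)$n, 5)
})

test_that("median P50 interpolates like the sort-based quantile oracle", {
  expect_equal(median_p50(c(6, 7, 8)), 7)
  # symmetric distribution about its centre
  expect_equal(median_p50(c(4, 5, 6, 8, 9, 10)), 7)
  set.seed(8)
  for (i in 1:20) {
    x <- runif(sample(5:200, 1), 2, 25)
    expect_equal(median_p50(x), quantile_oracle(x, 0.5), tolerance = 1e-9)
  }
})

test_that("perfused diameter extrapolates a uniform width CDF to its top", {
  # widths placed at the uniform quantiles (closed-form CDF knots)
  n <- 99
  w <- qunif((1:n) / (n + 1), 5, 12)
  d <- perfused_diameter(width_distribution(w))
  expect_equal(as.numeric(d), 12, tolerance = 1e-9)
  expect_false(attr(d, "degenerate"))
  # large random uniform samples converge to the upper endpoint
  set.seed(33)
  d2 <- perfused_diameter(width_distribution(runif(20000, 5, 12)))
  expect_equal(as.numeric(d2), 12, tolerance = 0.1)
})

test_that("degenerate width distributions give Dperf = P50 and PBR 0", {
  d <- perfused_diameter(width_distribution(rep(6.5, 40)))
  expect_equal(as.numeric(d), 6.5)
  expect_true(attr(d, "degenerate"))
  expect_equal(compute_pbr(as.numeric(d), 6.5), 0)
})

test_that("PBR follows (Dperf - P50) / 2", {
  expect_equal(compute_pbr(11.80, 7.00), 2.40)
  expect_equal(compute_pbr(14.84, 10.56), 2.14)
  expect_equal(compute_pbr(3, 3), 0)
  expect_warning(p <- compute_pbr(6, 7), "negative PBR")
  expect_equal(p, -0.5)
})

test_that("diameter classes round to integer micrometres, bins inclusive", {
  expect_equal(classify_diameter(7.2), "5-9")
  expect_equal(classify_diameter(9.5), "10-19")   # rounds up to 10
  expect_equal(classify_diameter(27.0), "none")
  expect_equal(classify_diameter(c(4.4, 4.5, 9.4, 19.5, 25.4, 25.5)),
               c("none", "5-9", "5-9", "20-25", "20-25", "none"))
})

test_that("Dperf = 2 PBR + P50 holds to machine precision end to end", {
  sc <- default_scene(55, n_vessels = 2, n_frames = 20)
  res <- analyze_recording(sc$stack, run_config(pixel_size_um = 1))
  sg <- res$segments[res$segments$valid & !is.na(res$segments$pbr_um), ]
  expect_gt(nrow(sg), 0)
  expect_equal(sg$dperf_um, 2 * sg$pbr_um + sg$p50_um, tolerance = 1e-12)
  s <- res$site
  expect_equal(s$dperf_um, 2 * s$pbr_5_25 + s$median_p50_um,
               tolerance = 1e-12)
})

test_that("micrometre outputs are invariant to the pixel calibration", {
  widths <- list()
  for (px in c(1, 0.5)) {
    sc <- generate_scene(scene_params(n_vessels = 1, dperf_um = 11.78,
                                      true_pbr_um = 2.39, n_frames = 15,
                                      frame_shape_px = c(64, 120) / px,
                                      pixel_size_um = px,
                                      vessel_length_um = 105, seed = 77))
    fr <- sc$stack$frames[, , 1]
    cl <- detect_vessels(fr, px)
    seg <- partition_segments(cl[[1]], px)[[1]]
    p <- segment_profile(sc$stack, seg)
    widths[[as.character(px)]] <- p$measurements$width_um
  }
  # same seed draws the same physical widths; both rasters must measure them
  expect_equal(widths[["1"]], widths[["0.5"]], tolerance = 0.15)
})

test_that("estimates respond monotonically to the true glycocalyx width", {
  p50s <- pbrs <- numeric(3)
  pbr_true <- c(0.5, 1.5, 2.5)
  for (i in 1:3) {
    sc <- generate_scene(scene_params(n_vessels = 3,
                                      dperf_um = rep(12, 3),
                                      true_pbr_um = pbr_true[i],
                                      n_frames = 40,
                                      frame_shape_px = c(180, 40),
                                      vessel_length_um = 15, seed = 400 + i))
    res <- analyze_recording(sc$stack, run_config(pixel_size_um = 1))
    p50s[i] <- res$site$median_p50_um
    pbrs[i] <- res$site$pbr_5_25
  }
  expect_true(all(diff(p50s) < 0))
  expect_true(all(diff(pbrs) > 0))
})

test_that("zero-glycocalyx scenes estimate PBR below 0.3 um", {
  sc <- generate_scene(scene_params(n_vessels = 2, dperf_um = c(10, 10),
                                    true_pbr_um = 0, n_frames = 40,
                                    frame_shape_px = c(120, 40),
                                    vessel_length_um = 15, seed = 91))
  res <- analyze_recording(sc$stack, run_config(pixel_size_um = 1))
  sg <- res$segments[res$segments$valid, ]
  expect_true(all(sg$pbr_um < 0.3))
  expect_lt(res$site$pbr_5_25, 0.3)
})

test_that("site summaries pool by diameter class and handle empty input", {
  p <- list(fake_profile(TRUE, widths = c(6, 6.5, 7), "5-9", id = "a"),
            fake_profile(TRUE, widths = c(6.2, 6.8, 7.4), "5-9", id = "b"))
  vr <- data.frame(site_id = "s1", n_segments_total = 2L,
                   n_segments_valid = 2L, field_area_mm2 = 1,
                   vvd_um_per_mm2 = 20)
  out <- summarize_site(p, vr)
  # single-class scene: the 5-25 um figure equals that class's figure
  pooled <- width_distribution(c(6, 6.5, 7, 6.2, 6.8, 7.4))
  expect_equal(out$median_p50_um, median_p50(pooled))
  expect_equal(out$pbr_5_25, out$pbr_5_9)
  expect_true(is.na(out$pbr_10_19))
  # zero valid segments: all-missing with a reason
  vr0 <- data.frame(site_id = "s2", n_segments_total = 5L,
                    n_segments_valid = 0L, field_area_mm2 = 1,
                    vvd_um_per_mm2 = 0)
  out0 <- summarize_site(list(), vr0)
  expect_true(is.na(out0$median_p50_um))
  expect_equal(attr(out0, "reason"), "no_valid_segments")
})
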