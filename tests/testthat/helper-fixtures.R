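# Shared fixtures: small synthetic frames, centerlines and segment profiles
# built in code.

# A frame with one horizontal dark band: trapezoidal transverse profile of
# full-width-at-half-depth `width_um`, centred on `row_center`, covering
# columns up to `x_max` (um; Inf = full width).  Background 1, depth 0.5.
band_frame <- function(nrow_px = 60, ncol_px = 120, row_center = 30,
                       width_um = 10, x_max = Inf, depth = 0.5,
                       background = 1, edge_um = 2, pixel_size_um = 1) {
  y <- (seq_len(nrow_px) - 0.5) * pixel_size_um
  x <- (seq_len(ncol_px) - 0.5) * pixel_size_um
  prof <- depth * pmin(pmax((width_um / 2 + edge_um / 2 -
                               abs(y - row_center)) / edge_um, 0), 1)
  fr <- matrix(background, nrow_px, ncol_px)
  cols <- which(x <= x_max)
  fr[, cols] <- background * (1 - matrix(prof, nrow_px, length(cols)))
  fr
}

# Straight synthetic centerline along x at y = y0 with constant diameter.
straight_centerline <- function(length_um, y0 = 30, diameter_um = 10,
                                spacing = 0.5) {
  s <- seq(0, length_um, by = spacing)
  cl <- data.frame(arc_um = s, x_um = s + 2, y_um = rep(y0, length(s)),
                   diameter_um = rep(diameter_um, length(s)))
  class(cl) <- c("centerline", "data.frame")
  cl
}

# Minimal segment_profile stand-in for filling-percentage logic.
fake_profile <- function(filled_all, widths = numeric(0),
                         diameter_class = "10-19", id = "s") {
  structure(list(segment_id = id, filled_all_frames = filled_all,
                 widths_um = widths, p50_um = NA_real_, dperf_um = NA_real_,
                 pbr_um = NA_real_, diameter_class = diameter_class),
            class = "segment_profile")
}

# Independent width oracle: vertical scan through a rendered frame at one
# column, full width at `level` of the dip depth, linear interpolation.
# Deliberately separate from half_depth_width().
scan_width <- function(frame, col, pixel_size_um = 1, level = 0.5) {
  v <- frame[, col]
  y <- (seq_len(nrow(frame)) - 0.5) * pixel_size_um
  bg <- stats::median(v[c(1:5, (length(v) - 4):length(v))])
  i <- which.min(v)
  depth <- bg - v[i]
  if (depth <= 1e-6) return(NA_real_)
  lev <- bg - level * depth
  li <- i; while (li > 1 && v[li] < lev) li <- li - 1
  ri <- i; while (ri < length(v) && v[ri] < lev) ri <- ri + 1
  if (v[li] < lev || v[ri] < lev) return(NA_real_)
  left <- y[li] + (v[li] - lev) / (v[li] - v[li + 1]) * (y[li + 1] - y[li])
  right <- y[ri] - (v[ri] - lev) / (v[ri] - v[ri - 1]) * (y[ri] - y[ri - 1])
  right - left
}

# Sort-based type-7 quantile oracle (manual interpolation, no stats::quantile).
quantile_oracle <- function(x, p) {
  s <- sort(x)
  n <- length(s)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# Balanced one-way ANOVA method-of-moments variance components oracle.
mom_oracle <- function(y, g) {
  a <- stats::anova(stats::aov(y ~ factor(g)))
  k <- length(y) / length(unique(g))
  msb <- a[1, 3]; msw <- a[2, 3]
  c(inter = (msb - msw) / k, intra = msw)
}

default_scene <- function(seed, n_vessels = 4, n_frames = 40,
                          dperf = 11.78, pbr = 2.39) {
  generate_scene(scene_params(n_vessels = n_vessels,
                              dperf_um = rep(dperf, n_vessels),
                              true_pbr_um = pbr, n_frames = n_frames,
                              frame_shape_px = c(60 * n_vessels, 40),
                              vessel_length_um = 15, seed = seed))
}
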