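# RBC column-width measurement and perfused-boundary-region estimation.
#
# For each valid 10-um segment the transverse intensity profile (averaged
# over the segment's 20 minor markers) is measured on every accepted frame:
# the column width is the full width at half depth, a segment is "filled" in
# a frame when the profile depth clears the signal-to-noise threshold.
# Pooled width distributions give the median column width P50; the perfused
# diameter Dperf is the straight-line extrapolation of the width cumulative
# curve to fraction 1; and PBR = (Dperf - P50) / 2 estimates glycocalyx
# thickness.

measure_from_profile <- function(off, profile, noise, r, snr_threshold) {
  annulus <- abs(off) >= 2 * r & abs(off) <= 4 * r
  bg <- stats::median(profile[annulus])
  hw <- half_depth_width(off, profile, background = bg)
  snr <- hw$depth / max(noise, 1e-9)
  filled <- hw$found && snr >= snr_threshold
  if (!filled) {
    return(list(width_um = 0, min_width_um = 0,
                lateral_position_um = NA_real_, snr = snr,
                filled = FALSE, truncated = FALSE))
  }
  mw <- half_depth_width(off, profile, background = bg, level = 0.8)
  list(width_um = hw$width_um, min_width_um = mw$width_um,
       lateral_position_um = hw$center_um, snr = snr, filled = TRUE,
       truncated = hw$truncated)
}

#' Measure the RBC column in one frame for one segment
#'
#' The transverse intensity profile, averaged along the segment's 10-um
#' extent (its 20 minor markers), is probed out to four vessel radii; the
#' local background is the median of the 2-4 radii annulus and the noise the
#' standard deviation of the annulus samples.  The column width is the full
#' width at half depth; a measurement is `filled` when depth / noise reaches
#' `snr_threshold`; unfilled measurements carry width 0.  Profiles whose
#' half-depth crossings are not reached inside the window are flagged
#' `truncated` and excluded from width distributions.
#'
#' @param frame Frame to measure on.
#' @param segment A valid `major_segment`.
#' @param pixel_size_um Pixel calibration.
#' @param snr_threshold Minimum depth-to-noise ratio for a filled column.
#' @return A one-row data.frame: `width_um`, `min_width_um`,
#'   `lateral_position_um` (signed offset of the column centre from the
#'   centerline), `snr`, `filled`, `truncated`.
#' @export
measure_column <- function(frame, segment, pixel_size_um,
                           snr_threshold = 3) {
  stopifnot(inherits(segment, "major_segment"))
  mk <- segment$markers
  r <- max(segment$diameter_um / 2, 1.5)
  off <- seq(-4 * r, 4 * r, by = pixel_size_um / 2)
  grid <- transverse_grid(mk$x_um, mk$y_um, mk$nx, mk$ny, off)
  if (!all(in_frame(frame, grid$x, grid$y, pixel_size_um))) {
    return(data.frame(width_um = 0, min_width_um = 0,
                      lateral_position_um = NA_real_, snr = NA_real_,
                      filled = FALSE, truncated = TRUE))
  }
  vals <- matrix(bilinear_sample(frame, grid$x, grid$y, pixel_size_um),
                 nrow = nrow(mk))
  annulus <- abs(off) >= 2 * r & abs(off) <= 4 * r
  m <- measure_from_profile(off, colMeans(vals),
                            stats::sd(vals[, annulus]), r, snr_threshold)
  as.data.frame(m)
}

#' Measure a segment across all accepted frames of a recording
#'
#' Runs [measure_column()] on every accepted frame (sampling geometry is
#' computed once), then derives the segment-level width distribution
#' statistics: the median column width `p50_um`, the perfused diameter
#' `dperf_um` ([perfused_diameter()]), `pbr_um = (dperf_um - p50_um) / 2`
#' and the diameter class.
#'
#' @param stack A [frame_stack()].
#' @param segment A valid `major_segment`.
#' @param snr_threshold Minimum depth-to-noise ratio for a filled column.
#' @param accepted_frames Optional integer vector of frame indices to use
#'   (e.g. from [frame_qc()]); default all frames.
#' @param dperf_fit_lo,dperf_fit_hi,dperf_extrapolate_to Dperf regression
#'   window and target, see [perfused_diameter()].
#' @return A `segment_profile`: list with `segment_id`, `measurements`
#'   (one row per accepted frame), `filled_all_frames`, `widths_um` (filled,
#'   non-truncated widths), `p50_um`, `dperf_um`, `pbr_um`,
#'   `diameter_class`.
#' @export
segment_profile <- function(stack, segment, snr_threshold = 3,
                            accepted_frames = NULL,
                            dperf_fit_lo = 0.25, dperf_fit_hi = 0.75,
                            dperf_extrapolate_to = 1.0) {
  stopifnot(inherits(stack, "frame_stack"),
            inherits(segment, "major_segment"))
  px <- stack$pixel_size_um
  if (is.null(accepted_frames)) accepted_frames <- seq_len(n_frames(stack))
  mk <- segment$markers
  measure_all <- function(r) {
    off <- seq(-4 * r, 4 * r, by = px / 2)
    grid <- transverse_grid(mk$x_um, mk$y_um, mk$nx, mk$ny, off)
    core <- abs(off) <= 2 * r
    inside <- all(in_frame(get_frame(stack, 1),
                           grid$x[, core, drop = FALSE],
                           grid$y[, core, drop = FALSE], px))
    annulus <- abs(off) >= 2 * r & abs(off) <= 4 * r
    rows <- lapply(accepted_frames, function(f) {
      if (!inside) {
        m <- list(width_um = 0, min_width_um = 0,
                  lateral_position_um = NA_real_, snr = NA_real_,
                  filled = FALSE, truncated = TRUE)
      } else {
        frame <- get_frame(stack, f)
        vals <- matrix(bilinear_sample(frame, grid$x, grid$y, px),
                       nrow = nrow(mk))
        m <- measure_from_profile(off, colMeans(vals),
                                  stats::sd(vals[, annulus]), r,
                                  snr_threshold)
      }
      c(frame_index = f, m, recursive = FALSE)
    })
    do.call(rbind, lapply(rows, as.data.frame))
  }
  # The RBC column can be wider in later frames than on the detection frame,
  # and the background annulus (2-4 radii out) must clear the full lateral
  # excursion zone (which extends to the perfused diameter, not just the
  # detection-frame column width).  The pixelwise minimum over the accepted
  # frames darkens every pixel the column ever covered, so the half-depth
  # width of its transverse profile estimates the excursion envelope; the
  # probing radius is sized from it.
  r0 <- max(segment$diameter_um / 2, 1.5)
  env <- array(Inf, dim = dim(get_frame(stack, 1)))
  for (f in accepted_frames) env <- pmin(env, get_frame(stack, f))
  r <- r0
  for (pass in 1:4) {
    off <- seq(-4 * r, 4 * r, by = px / 2)
    grid <- transverse_grid(mk$x_um, mk$y_um, mk$nx, mk$ny, off)
    core <- abs(off) <= 2 * r
    if (!all(in_frame(env, grid$x[, core, drop = FALSE],
                      grid$y[, core, drop = FALSE], px))) break
    vals <- matrix(bilinear_sample(env, grid$x, grid$y, px),
                   nrow = nrow(mk))
    annulus <- abs(off) >= 2 * r & abs(off) <= 4 * r
    hw <- half_depth_width(off, colMeans(vals),
                           background = stats::median(vals[, annulus]))
    if (!hw$found) break
    if (hw$truncated || hw$width_um / 2 > 1.02 * r) {
      r <- max(hw$width_um / 2, 1.6 * r)
    } else {
      r <- max(hw$width_um / 2, r0)
      break
    }
  }
  meas <- measure_all(r)
  # safety net: remeasure if a filled column still outgrew the window
  for (pass in 1:2) {
    wmax <- suppressWarnings(max(c(meas$width_um[meas$filled], 0)))
    if (wmax / 2 <= 1.05 * r) break
    r <- wmax / 2
    meas <- measure_all(r)
  }
  widths <- meas$width_um[meas$filled & !meas$truncated]
  p50 <- dperf <- pbr <- NA_real_
  cls <- NA_character_
  if (length(widths) >= 1) {
    wd <- width_distribution(widths)
    p50 <- median_p50(wd)
    dperf <- as.numeric(perfused_diameter(wd, fit_lo = dperf_fit_lo,
                                          fit_hi = dperf_fit_hi,
                                          extrapolate_to =
                                            dperf_extrapolate_to))
    pbr <- compute_pbr(dperf, p50)
    cls <- classify_diameter(dperf)
  }
  structure(list(segment_id = segment$segment_id,
                 measurements = meas,
                 filled_all_frames = all(meas$filled),
                 widths_um = widths,
                 p50_um = p50, dperf_um = dperf, pbr_um = pbr,
                 diameter_class = cls),
            class = "segment_profile")
}

#' Percentage of segments with RBC present in every frame
#'
#' @param profiles List of `segment_profile`s for the valid segments of a
#'   recording.
#' @return `100 * (#segments filled in every accepted frame) / (#segments)`;
#'   `NA` (with a warning) when no valid segments were supplied.
#' @export
percent_rbc_filling <- function(profiles) {
  if (length(profiles) == 0) {
    warning("no valid segments; percentage RBC filling undefined")
    return(NA_real_)
  }
  100 * mean(vapply(profiles, function(p) isTRUE(p$filled_all_frames),
                    logical(1)))
}

#' Pooled cumulative distribution of RBC column widths
#'
#' Pools the filled, non-truncated column widths of the supplied segment
#' profiles (optionally restricted to one diameter class, or to `"5-25"` for
#' all classified segments) into an empirical cumulative distribution.
#'
#' @param x A list of `segment_profile`s, or directly a numeric vector of
#'   widths.
#' @param diameter_class `NULL` (all segments), one of `"5-9"`, `"10-19"`,
#'   `"20-25"`, or `"5-25"`.
#' @return A `width_distribution`: sorted `widths_um`, `cum_fraction`
#'   (`i/n`, reaching 1) and `n`.
#' @export
width_distribution <- function(x, diameter_class = NULL) {
  if (is.numeric(x)) {
    widths <- x
  } else {
    keep <- if (is.null(diameter_class)) {
      rep(TRUE, length(x))
    } else if (identical(diameter_class, "5-25")) {
      vapply(x, function(p) !is.na(p$diameter_class) &&
               p$diameter_class != "none", logical(1))
    } else {
      vapply(x, function(p) identical(p$diameter_class, diameter_class),
             logical(1))
    }
    widths <- unlist(lapply(x[keep], function(p) p$widths_um),
                     use.names = FALSE)
  }
  if (length(widths) < 1) {
    warning("empty width pool")
    return(structure(list(widths_um = numeric(0),
                          cum_fraction = numeric(0), n = 0L),
                     class = "width_distribution"))
  }
  w <- sort(widths)
  n <- length(w)
  structure(list(widths_um = w, cum_fraction = seq_len(n) / n, n = n),
            class = "width_distribution")
}

#' Median RBC column width (P50)
#'
#' Width at cumulative fraction 0.5 by linear interpolation of the empirical
#' distribution (type-7 quantile convention).
#'
#' @param distribution A [width_distribution()] or a numeric width vector.
#' @return Median width in micrometres.
#' @export
median_p50 <- function(distribution) {
  w <- if (inherits(distribution, "width_distribution"))
    distribution$widths_um else distribution
  if (length(w) < 1) return(NA_real_)
  unname(stats::quantile(w, 0.5, type = 7))
}

#' Perfused diameter from a width distribution
#'
#' A straight line is fitted (least squares) to the cumulative width curve
#' over the inter-quartile span and evaluated at cumulative fraction
#' `extrapolate_to`: widths are regressed on their plotting positions
#' `i / (n + 1)` restricted to `[fit_lo, fit_hi]`, so the fitted width at
#' fraction 1 estimates the outer limit of RBC lateral excursion.  For a
#' uniform width distribution the cumulative curve is a straight line and
#' the extrapolation recovers its upper endpoint.
#'
#' @param distribution A [width_distribution()] (or numeric width vector).
#' @param fit_lo,fit_hi Cumulative-fraction window of the fit.
#' @param extrapolate_to Target cumulative fraction, default 1.0.
#' @return The perfused diameter (micrometres) with attribute `degenerate`:
#'   when the inter-quartile range is zero (or too few points support a
#'   fit) the median itself is returned, flagged degenerate, so the implied
#'   PBR is 0.
#' @export
perfused_diameter <- function(distribution, fit_lo = 0.25, fit_hi = 0.75,
                              extrapolate_to = 1.0) {
  if (!inherits(distribution, "width_distribution")) {
    distribution <- width_distribution(distribution)
  }
  w <- distribution$widths_um
  n <- distribution$n
  p50 <- median_p50(distribution)
  degenerate <- function(v) structure(v, degenerate = TRUE)
  if (n < 4) return(degenerate(p50))
  q <- unname(stats::quantile(w, c(fit_lo, fit_hi), type = 7))
  if (diff(q) <= 0) return(degenerate(p50))
  Fpos <- seq_len(n) / (n + 1)
  sel <- Fpos >= fit_lo & Fpos <= fit_hi
  if (sum(sel) < 2 || length(unique(w[sel])) < 2) return(degenerate(p50))
  fit <- stats::lm.fit(cbind(1, Fpos[sel]), w[sel])
  b <- fit$coefficients
  if (!is.finite(b[2]) || b[2] <= 0) return(degenerate(p50))
  structure(unname(b[1] + b[2] * extrapolate_to), degenerate = FALSE)
}

#' Perfused boundary region
#'
#' `PBR = (Dperf - P50) / 2`: half the distance between the perfused
#' diameter and the median RBC column width, the cell-poor zone that RBC
#' only transiently enter.  A larger PBR indicates a thinner glycocalyx.
#'
#' @param dperf_um Perfused diameter, micrometres.
#' @param p50_um Median RBC column width, micrometres.
#' @return PBR in micrometres.  A negative value (inconsistent fit, i.e.
#'   `dperf_um < p50_um`) is returned with a warning, not clamped.
#' @examples
#' compute_pbr(11.80, 7.00)   # 2.40
#' compute_pbr(14.84, 10.56)  # 2.14
#' @export
compute_pbr <- function(dperf_um, p50_um) {
  stopifnot(is.finite(dperf_um), is.finite(p50_um),
            dperf_um >= 0, p50_um >= 0)
  pbr <- (dperf_um - p50_um) / 2
  if (pbr < 0) {
    warning("perfused diameter below median column width: negative PBR ",
            "(inconsistent fit)")
  }
  pbr
}

#' Diameter class of a vessel segment
#'
#' The perfused diameter is rounded to the nearest integer micrometre
#' (halves round up) and binned into the reporting classes 5-9, 10-19 and
#' 20-25 um; diameters outside 5-25 um are `"none"` and excluded from PBR
#' reporting.
#'
#' @param dperf_um Perfused diameter(s), micrometres.
#' @return Character vector: `"5-9"`, `"10-19"`, `"20-25"` or `"none"`.
#' @examples
#' classify_diameter(c(7.2, 9.5, 27))   # "5-9" "10-19" "none"
#' @export
classify_diameter <- function(dperf_um) {
  r <- floor(dperf_um + 0.5)
  out <- rep(NA_character_, length(dperf_um))
  ok <- is.finite(r)
  out[ok] <- ifelse(r[ok] < 5 | r[ok] > 25, "none",
                    ifelse(r[ok] <= 9, "5-9",
                           ifelse(r[ok] <= 19, "10-19", "20-25")))
  out
}

class_stats <- function(profiles, cls, ...) {
  wd <- suppressWarnings(width_distribution(profiles,
                                            diameter_class = cls))
  if (wd$n < 1) {
    return(list(p50 = NA_real_, dperf = NA_real_, pbr = NA_real_))
  }
  p50 <- median_p50(wd)
  dperf <- as.numeric(perfused_diameter(wd, ...))
  list(p50 = p50, dperf = dperf, pbr = (dperf - p50) / 2)
}

#' Summarise one recording site
#'
#' Class-level P50 / Dperf / PBR are computed from the width distribution
#' pooled across the site's segments of that diameter class; the headline
#' 5-25 um values use the pool of all classified segments.  Valid vessel
#' density and percentage RBC filling are attached from the validity report
#' and the segment profiles.
#'
#' @param profiles List of `segment_profile`s (valid segments only).
#' @param validity_rep One-row data.frame from [validity_report()].
#' @param ... Dperf fit options passed to [perfused_diameter()].
#' @return One-row data.frame (`site_result`): `site_id`,
#'   `vvd_um_per_mm2`, `pct_rbc_filling`, `median_p50_um`, `dperf_um`,
#'   `pbr_5_25`, `pbr_5_9`, `pbr_10_19`, `pbr_20_25`, `n_segments_total`,
#'   `n_segments_valid`.  With zero valid segments all parameter fields are
#'   `NA` and the row carries `attr(, "reason")`.
#' @export
summarize_site <- function(profiles, validity_rep, ...) {
  stopifnot(is.data.frame(validity_rep), nrow(validity_rep) == 1)
  base <- data.frame(site_id = validity_rep$site_id,
                     vvd_um_per_mm2 = validity_rep$vvd_um_per_mm2,
                     pct_rbc_filling = NA_real_,
                     median_p50_um = NA_real_, dperf_um = NA_real_,
                     pbr_5_25 = NA_real_, pbr_5_9 = NA_real_,
                     pbr_10_19 = NA_real_, pbr_20_25 = NA_real_,
                     n_segments_total = validity_rep$n_segments_total,
                     n_segments_valid = validity_rep$n_segments_valid)
  if (validity_rep$n_segments_valid == 0 || length(profiles) == 0) {
    attr(base, "reason") <- "no_valid_segments"
    return(base)
  }
  base$pct_rbc_filling <- percent_rbc_filling(profiles)
  pooled <- class_stats(profiles, "5-25", ...)
  base$median_p50_um <- pooled$p50
  base$dperf_um <- pooled$dperf
  base$pbr_5_25 <- pooled$pbr
  base$pbr_5_9 <- class_stats(profiles, "5-9", ...)$pbr
  base$pbr_10_19 <- class_stats(profiles, "10-19", ...)$pbr
  base$pbr_20_25 <- class_stats(profiles, "20-25", ...)$pbr
  base
}
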