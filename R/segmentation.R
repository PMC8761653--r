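# Vessel detection, 10-um segment partitioning, contrast-based validity and
# valid vessel density.
#
# Detection targets dark tubular structures on a bright background: the
# frame is inverted, smoothed, thresholded (Otsu) and labelled; each
# connected component yields an ordered centerline (transverse centre of
# mass along the component's principal axis, resampled at 0.5 um arc
# spacing) with a local diameter read as the full width at half depth of the
# transverse intensity profile.  Structures whose diameter reaches 30 um are
# excluded, matching the instrument's working range.

resample_polyline <- function(x, y, spacing) {
  seglen <- sqrt(diff(x)^2 + diff(y)^2)
  arc <- c(0, cumsum(seglen))
  total <- arc[length(arc)]
  if (total < spacing) {
    return(data.frame(arc_um = arc, x_um = x, y_um = y))
  }
  s <- seq(0, total, by = spacing)
  data.frame(arc_um = s,
             x_um = stats::approx(arc, x, xout = s)$y,
             y_um = stats::approx(arc, y, xout = s)$y)
}

polyline_tangents <- function(x, y) {
  n <- length(x)
  tx <- c(x[2] - x[1], x[3:n] - x[1:(n - 2)], x[n] - x[n - 1])
  ty <- c(y[2] - y[1], y[3:n] - y[1:(n - 2)], y[n] - y[n - 1])
  len <- sqrt(tx^2 + ty^2)
  len[len == 0] <- 1
  cbind(tx / len, ty / len)
}

# Transverse half-depth width and profile centre at centerline points.
profile_track <- function(frame, pixel_size_um, x, y, nx, ny, r0) {
  off <- seq(-4 * r0, 4 * r0, by = pixel_size_um / 2)
  grid <- transverse_grid(x, y, nx, ny, off)
  core <- abs(off) <= 2 * r0
  # only the core must be imaged; annulus samples outside the frame clamp
  # to the border, which is background in all but pathological fields
  ok <- in_frame(frame, grid$x[, core, drop = FALSE],
                 grid$y[, core, drop = FALSE], pixel_size_um)
  dim(ok) <- c(length(x), sum(core))
  vals <- matrix(bilinear_sample(frame, grid$x, grid$y, pixel_size_um),
                 nrow = length(x))
  annulus <- abs(off) >= 2 * r0 & abs(off) <= 4 * r0
  res <- vapply(seq_along(x), function(i) {
    if (!all(ok[i, ])) return(c(NA_real_, NA_real_))
    bg <- stats::median(vals[i, annulus])
    hw <- half_depth_width(off, vals[i, ], background = bg)
    if (!hw$found || hw$truncated) return(c(NA_real_, NA_real_))
    c(hw$width_um, hw$center_um)
  }, numeric(2))
  data.frame(width_um = res[1, ], center_um = res[2, ])
}

#' Detect vessel centerlines on a frame
#'
#' @param first_frame Numeric matrix (intensities in `[0, 1]`, vessels dark).
#' @param pixel_size_um Pixel calibration, micrometres per pixel.
#' @param max_diameter_um Vessels whose median local diameter reaches this
#'   value are excluded (instrument convention: analyse vessels < 30 um).
#' @param min_length_um Minimum centerline length retained.
#' @param blur_sigma_px Gaussian smoothing applied before thresholding.
#' @param min_area_um2 Minimum component area retained.
#' @return A list of `centerline` objects (data.frames with `arc_um`,
#'   `x_um`, `y_um`, `diameter_um`), ordered top-left first.  A uniform
#'   frame yields an empty list; a saturated or black frame additionally
#'   raises a quality warning.
#' @export
detect_vessels <- function(first_frame, pixel_size_um,
                           max_diameter_um = 30, min_length_um = 5,
                           blur_sigma_px = 1, min_area_um2 = 25) {
  stopifnot(is.matrix(first_frame), length(first_frame) > 0,
            pixel_size_um > 0)
  px <- pixel_size_um
  rng <- range(first_frame)
  if (diff(rng) < 0.02) {
    if (rng[1] > 0.95 || rng[2] < 0.05) {
      warning("frame is saturated or black; no vessels detected")
    }
    return(list())
  }
  inv <- rng[2] - first_frame
  sm <- as.matrix(EBImage::gblur(EBImage::Image(inv), sigma = blur_sigma_px))
  smn <- (sm - min(sm)) / diff(range(sm))
  th <- EBImage::otsu(EBImage::Image(smn), range = c(0, 1))
  mask <- smn > th
  lab <- as.matrix(EBImage::bwlabel(EBImage::Image(mask)))
  nlab <- max(lab)
  if (nlab == 0) return(list())

  comps <- lapply(seq_len(nlab), function(l) which(lab == l, arr.ind = TRUE))
  ord <- order(vapply(comps, function(m) min(m[, 1]), numeric(1)),
               vapply(comps, function(m) min(m[, 2]), numeric(1)))
  out <- list()
  for (m in comps[ord]) {
    if (nrow(m) * px^2 < min_area_um2) next
    # Bin along the component's dominant image axis: local SDF vessel runs
    # are single-valued there (within +/- 45 degrees of the axis), which
    # makes the transverse centre well defined per bin.  `a` is the
    # along-axis pixel index, `b` the across-axis index.
    vertical <- diff(range(m[, 1])) > diff(range(m[, 2]))
    if (vertical) { a <- m[, 1]; b <- m[, 2] } else {
      a <- m[, 2]; b <- m[, 1]
    }
    av <- sort(unique(a))
    if (length(av) < 4) next
    centers <- numeric(length(av))
    peaks <- numeric(length(av))
    halfspan <- numeric(length(av))
    for (i in seq_along(av)) {
      bi <- b[a == av[i]]
      lo <- max(min(bi) - 2L, 1L)
      hi <- min(max(bi) + 2L, if (vertical) ncol(smn) else nrow(smn))
      colv <- if (vertical) smn[av[i], lo:hi] else smn[lo:hi, av[i]]
      wgt <- pmax(colv - th, 0)
      peaks[i] <- max(colv)
      centers[i] <- if (sum(wgt) > 0)
        sum(wgt * (lo:hi)) / sum(wgt) else mean(bi)
      halfspan[i] <- (max(bi) - min(bi) + 1) / 2
    }
    # drop axial end ramps: columns whose peak falls below half the
    # component's typical contrast belong to the vessel tip, not its body
    body <- peaks >= 0.5 * stats::median(peaks)
    runs <- rle(body)
    if (!any(runs$values)) next
    ends <- cumsum(runs$lengths)
    imax <- which.max(runs$lengths * runs$values)
    sel <- (ends[imax] - runs$lengths[imax] + 1):ends[imax]
    av <- av[sel]; centers <- centers[sel]; halfspan <- halfspan[sel]
    if (length(av) < 4) next
    # smooth the centre track: per-bin jitter is pixel noise, real
    # centerlines are smooth at the multi-micrometre scale
    if (length(av) >= 8) {
      dfree <- max(4, min(14, ceiling(diff(range(av)) * px / 8)))
      dfree <- min(dfree, length(av) - 1)
      sp <- stats::smooth.spline(av, centers, df = dfree)
      ag <- seq(min(av), max(av), by = 0.5 / px)
      cg <- stats::predict(sp, ag)$y
    } else {
      ag <- av; cg <- stats::runmed(centers, 3, endrule = "keep")
    }
    if (vertical) { cxs <- cg; cys <- ag } else { cxs <- ag; cys <- cg }
    rs <- resample_polyline((cxs - 0.5) * px, (cys - 0.5) * px,
                            spacing = 0.5)
    if (nrow(rs) < 4) next
    tang <- polyline_tangents(rs$x_um, rs$y_um)
    r0 <- min(max(stats::median(halfspan) * px, 1.5), 40)
    prof <- profile_track(first_frame, px, rs$x_um, rs$y_um,
                          -tang[, 2], tang[, 1], r0)
    wmed <- stats::median(prof$width_um, na.rm = TRUE)
    if (is.finite(wmed) && abs(wmed / 2 - r0) > 0.25 * r0) {
      # reprobe with a window matched to the measured calibre
      r0 <- min(max(wmed / 2, 1.5), 40)
      prof <- profile_track(first_frame, px, rs$x_um, rs$y_um,
                            -tang[, 2], tang[, 1], r0)
    }
    diam <- prof$width_um
    # trim unmeasurable ends, interpolate interior gaps
    keep <- which(!is.na(diam))
    if (length(keep) < 4) next
    rs <- rs[min(keep):max(keep), , drop = FALSE]
    diam <- diam[min(keep):max(keep)]
    if (anyNA(diam)) {
      diam <- stats::approx(rs$arc_um[!is.na(diam)], diam[!is.na(diam)],
                            xout = rs$arc_um, rule = 2)$y
    }
    if (stats::median(diam) >= max_diameter_um) next
    drop_pt <- diam >= max_diameter_um
    if (any(drop_pt)) {
      keep <- which(!drop_pt)
      rs <- rs[min(keep):max(keep), , drop = FALSE]
      diam <- diam[min(keep):max(keep)]
    }
    rs$arc_um <- rs$arc_um - rs$arc_um[1]
    if (max(rs$arc_um) < min_length_um) next
    if (rs$x_um[nrow(rs)] < rs$x_um[1] ||
        (abs(rs$x_um[nrow(rs)] - rs$x_um[1]) < 1e-9 &&
         rs$y_um[nrow(rs)] < rs$y_um[1])) {
      rs <- rs[rev(seq_len(nrow(rs))), , drop = FALSE]
      diam <- rev(diam)
      rs$arc_um <- max(rs$arc_um) - rs$arc_um
    }
    cl <- data.frame(arc_um = rs$arc_um, x_um = rs$x_um, y_um = rs$y_um,
                     diameter_um = diam)
    attr(cl, "pixel_size_um") <- px
    class(cl) <- c("centerline", "data.frame")
    out[[length(out) + 1L]] <- cl
  }
  out
}

centerline_length <- function(centerline) max(centerline$arc_um)

#' Partition a centerline into 10-um major segments
#'
#' Consecutive, non-overlapping 10 um spans are taken from the start of the
#' centerline; a trailing remainder shorter than 10 um is discarded.  Each
#' segment carries 20 minor markers at 0.5 um spacing (marker k sits at the
#' centre of minor span k) with interpolated position, tangent and local
#' diameter.
#'
#' @param centerline A `centerline` from [detect_vessels()] (any data.frame
#'   with `arc_um`, `x_um`, `y_um`, `diameter_um` works).
#' @param pixel_size_um Pixel calibration (used only for tolerance
#'   bookkeeping; the centerline is already in micrometres).
#' @param segment_length_um,n_minor Segment geometry; the instrument
#'   convention is 10 um segments with 20 half-micrometre minor markers.
#' @return A list of `major_segment` objects; empty when the centerline is
#'   shorter than one segment.
#' @export
partition_segments <- function(centerline, pixel_size_um = 1,
                               segment_length_um = 10, n_minor = 20) {
  stopifnot(all(c("arc_um", "x_um", "y_um", "diameter_um") %in%
                  names(centerline)))
  L <- centerline_length(centerline)
  n_seg <- floor((L + 1e-6) / segment_length_um)
  if (n_seg < 1) return(list())
  minor <- segment_length_um / n_minor
  arc <- centerline$arc_um
  lapply(seq_len(n_seg), function(k) {
    s <- (k - 1) * segment_length_um + minor / 2 + (0:(n_minor - 1)) * minor
    xi <- stats::approx(arc, centerline$x_um, xout = s)$y
    yi <- stats::approx(arc, centerline$y_um, xout = s)$y
    di <- stats::approx(arc, centerline$diameter_um, xout = s)$y
    h <- 1.0   # tangent window (um); wider than the marker spacing for
               # stability against residual centerline jitter
    sm <- pmax(s - h, 0); sp <- pmin(s + h, L)
    tx <- stats::approx(arc, centerline$x_um, xout = sp)$y -
      stats::approx(arc, centerline$x_um, xout = sm)$y
    ty <- stats::approx(arc, centerline$y_um, xout = sp)$y -
      stats::approx(arc, centerline$y_um, xout = sm)$y
    tl <- sqrt(tx^2 + ty^2); tl[tl == 0] <- 1
    tx <- tx / tl; ty <- ty / tl
    markers <- data.frame(arc_um = s, x_um = xi, y_um = yi,
                          tx = tx, ty = ty, nx = -ty, ny = tx,
                          diameter_um = di)
    structure(list(segment_id = k,
                   arc_start_um = (k - 1) * segment_length_um,
                   length_um = segment_length_um,
                   markers = markers,
                   diameter_um = mean(di),
                   orientation = atan2(mean(ty), mean(tx)),
                   contrast_fraction = NA_real_,
                   valid = NA,
                   reason = NA_character_),
              class = "major_segment")
  })
}

#' Classify a segment's validity from minor-marker contrast
#'
#' Each of the segment's 20 minor markers is probed with a transverse
#' intensity profile on the (min-max normalised) frame; a marker has
#' sufficient contrast when the relative profile depth
#' `(background - minimum) / background` reaches `contrast_threshold`, with
#' the local background taken as the median of an annulus 2-4 vessel radii
#' out.  The segment is valid when strictly more than 60% of its markers are
#' sufficient.  Min-max normalisation makes the decision invariant to global
#' affine rescaling of the frame intensities.
#'
#' @param frame Frame the segment was defined on.
#' @param segment A `major_segment` from [partition_segments()].
#' @param pixel_size_um Pixel calibration.
#' @param contrast_threshold Minimum relative profile depth, default 0.3.
#' @param validity_fraction Fraction of sufficient markers that must be
#'   exceeded (strictly), default 0.6.
#' @return The segment with `contrast_fraction`, `valid` and `reason`
#'   filled.  Segments whose probing window leaves the frame are invalid
#'   with reason `"outside_frame"`.
#' @export
assess_validity <- function(frame, segment, pixel_size_um,
                            contrast_threshold = 0.3,
                            validity_fraction = 0.6) {
  stopifnot(inherits(segment, "major_segment"), pixel_size_um > 0)
  rngf <- range(frame)
  if (diff(rngf) <= 0) {
    segment$valid <- FALSE
    segment$reason <- "flat_frame"
    return(segment)
  }
  fn <- (frame - rngf[1]) / diff(rngf)
  mk <- segment$markers
  r <- max(segment$diameter_um / 2, 1.5)
  off <- seq(-4 * r, 4 * r, by = pixel_size_um / 2)
  grid <- transverse_grid(mk$x_um, mk$y_um, mk$nx, mk$ny, off)
  if (!all(in_frame(frame, grid$x, grid$y, pixel_size_um))) {
    segment$valid <- FALSE
    segment$reason <- "outside_frame"
    return(segment)
  }
  vals <- matrix(bilinear_sample(fn, grid$x, grid$y, pixel_size_um),
                 nrow = nrow(mk))
  annulus <- abs(off) >= 2 * r & abs(off) <= 4 * r
  core <- abs(off) <= 1.5 * r
  bg <- apply(vals[, annulus, drop = FALSE], 1, stats::median)
  lo <- apply(vals[, core, drop = FALSE], 1, min)
  depth_rel <- (bg - lo) / pmax(bg, 1e-9)
  sufficient <- depth_rel >= contrast_threshold
  segment$contrast_fraction <- mean(sufficient)
  segment$valid <- segment$contrast_fraction > validity_fraction
  segment$reason <- if (segment$valid) NA_character_ else "low_contrast"
  segment
}

#' Valid vessel density
#'
#' Valid vessel density is the total centerline length of valid 10-um
#' segments per unit field area: `10 * n_valid / field_area_mm2`, in um/mm^2.
#'
#' @param n_valid Number of valid major segments.
#' @param field_area_mm2 Field area in mm^2 (must be positive).
#' @return Density in um per mm^2.
#' @examples
#' compute_vvd(20, 1.0)   # 200
#' compute_vvd(17, 0.98)  # 173.4694
#' @export
compute_vvd <- function(n_valid, field_area_mm2) {
  stopifnot(n_valid >= 0, is.finite(field_area_mm2))
  if (field_area_mm2 <= 0) stop("field_area_mm2 must be positive")
  10 * n_valid / field_area_mm2
}

#' Per-site validity report
#'
#' @param segments List of assessed `major_segment`s (after
#'   [assess_validity()]).
#' @param field_area_mm2 Field area in mm^2.
#' @param site_id Optional site label.
#' @return One-row data.frame: `site_id`, `n_segments_total`,
#'   `n_segments_valid`, `field_area_mm2`, `vvd_um_per_mm2`.
#' @export
validity_report <- function(segments, field_area_mm2,
                            site_id = NA_character_) {
  n_total <- length(segments)
  n_valid <- sum(vapply(segments, function(s) isTRUE(s$valid), logical(1)))
  data.frame(site_id = site_id,
             n_segments_total = n_total,
             n_segments_valid = n_valid,
             field_area_mm2 = field_area_mm2,
             vvd_um_per_mm2 = compute_vvd(n_valid, field_area_mm2))
}

#' Frame quality control: motion and focus
#'
#' Each frame's rigid displacement from the stack's pixelwise median frame
#' is estimated by FFT cross-correlation (after demeaning), and its
#' sharpness as the mean squared finite-difference gradient.  Frames moving
#' further than `max_shift_px` or duller than `min_sharpness` are rejected;
#' downstream analysis uses accepted frames only.
#'
#' @param stack A [frame_stack()].
#' @param max_shift_px Maximum tolerated displacement, pixels.
#' @param min_sharpness Absolute sharpness floor; default (`NULL`) adapts to
#'   half the median sharpness across frames.
#' @return A data.frame with one row per frame: `frame`, `shift_px`,
#'   `sharpness`, `accepted`.  When every frame is rejected the result
#'   carries `attr(, "unanalyzable") = TRUE` and a warning is raised.
#' @export
frame_qc <- function(stack, max_shift_px = 5, min_sharpness = NULL) {
  stopifnot(inherits(stack, "frame_stack"))
  nf <- n_frames(stack)
  d <- dim(stack$frames)
  ref <- if (nf <= 2) get_frame(stack, 1) else
    apply(stack$frames, c(1, 2), stats::median)
  refc <- ref - mean(ref)
  fref <- stats::fft(refc)
  # wrapped displacement of every cross-correlation bin
  dy <- ifelse(seq_len(d[1]) - 1L > d[1] / 2, seq_len(d[1]) - 1L - d[1],
               seq_len(d[1]) - 1L)
  dx <- ifelse(seq_len(d[2]) - 1L > d[2] / 2, seq_len(d[2]) - 1L - d[2],
               seq_len(d[2]) - 1L)
  win <- round(max_shift_px) + 3
  near <- outer(abs(dy) <= win, abs(dx) <= win, "&")
  shift <- numeric(nf)
  sharp <- numeric(nf)
  for (i in seq_len(nf)) {
    fr <- get_frame(stack, i)
    cc <- Re(stats::fft(Conj(fref) * stats::fft(fr - mean(fr)),
                        inverse = TRUE))
    # search near zero displacement first: periodic vessel layouts carry
    # correlation side lobes at the vessel spacing that would otherwise
    # alias the estimate; a distant peak only wins when it clearly
    # dominates (a genuinely displaced frame)
    pk_near <- which(cc == max(cc[near]) & near, arr.ind = TRUE)[1, ]
    pk_glob <- arrayInd(which.max(cc), dim(cc))[1, ]
    pk <- if (max(cc) > 1.25 * max(cc[near])) pk_glob else pk_near
    dyx <- c(dy[pk[1]], dx[pk[2]])
    shift[i] <- sqrt(sum(dyx^2))
    gx <- diff(t(fr)); gy <- diff(fr)
    sharp[i] <- (sum(gx^2) + sum(gy^2)) / length(fr)
  }
  if (is.null(min_sharpness)) min_sharpness <- 0.5 * stats::median(sharp)
  qc <- data.frame(frame = seq_len(nf), shift_px = shift, sharpness = sharp,
                   accepted = shift <= max_shift_px & sharp >= min_sharpness)
  if (!any(qc$accepted)) {
    warning("all frames rejected by quality control; recording unanalyzable")
    attr(qc, "unanalyzable") <- TRUE
  }
  qc
}
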