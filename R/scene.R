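# Ground-truthed synthetic sidestream dark-field scenes.
#
# A scene is a short video clip (default 40 frames) of dark, mildly curved
# vessel bands on a bright background.  Each vessel has a true perfused
# diameter Dperf, a true median RBC column width P50 and a true perfused
# boundary region PBR linked by the identity Dperf = P50 + 2 * PBR.  Per
# frame, the rendered column width and its lateral position are drawn from an
# excursion law bounded by Dperf, so that the downstream width-distribution
# estimators can be checked against analytic truth.

#' Parameters of a synthetic videomicroscopy scene
#'
#' @param n_vessels Number of vessels rendered in the field.
#' @param vessel_diameter_range_um Range the true perfused diameters are drawn
#'   from (uniformly) when `dperf_um` is not given.
#' @param true_pbr_um True perfused boundary region (glycocalyx-exclusion
#'   half-width, micrometres); the true median column width of each vessel is
#'   `Dperf - 2 * true_pbr_um` and must stay positive.
#' @param dperf_um Optional vector of explicit true perfused diameters, one
#'   per vessel (overrides `vessel_diameter_range_um`).
#' @param vessel_length_um Optional axial vessel length(s), micrometres;
#'   default fills the frame width minus a margin.
#' @param n_frames Frames per recording (the instrument convention is 40).
#' @param frame_shape_px Frame shape `c(height, width)` in pixels.
#' @param pixel_size_um Pixel calibration, micrometres per pixel.
#' @param background_level Background intensity in (0, 1].
#' @param vessel_depth Fractional contrast depth of a vessel in (0, 1]: the
#'   column core renders at `background_level * (1 - vessel_depth)`.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise
#'   (frames are clipped to `[0, 1]` afterwards).
#' @param excursion_model Law of the per-frame column width: `"uniform"`
#'   (default) draws widths uniformly on `[P50 - 2 PBR, P50 + 2 PBR]`, whose
#'   median is P50 and whose maximum is Dperf and whose linear cumulative
#'   distribution matches the straight-line perfused-diameter extrapolation;
#'   `"triangular"` draws from the symmetric triangular law with median P50
#'   and support `[P50 - 2 PBR, Dperf]`.  In both laws the column centre is
#'   uniform in the band `(Dperf - width) / 2` either side of the centerline.
#' @param motion_jitter_px Maximum per-frame rigid translation (integer
#'   pixels, uniform on `-motion_jitter_px:motion_jitter_px` in x and y).
#' @param curvature_amp_px Amplitude of the mild sinusoidal centerline
#'   curvature, pixels (0 renders straight tubes).
#' @param edge_softness_px Length of the linear intensity ramp at the vessel
#'   edge, pixels.  The rendered half-depth width equals the modelled column
#'   width exactly for any ramp; column widths must exceed the ramp length
#'   for the trapezoidal profile to keep its plateau.
#' @param seed Integer seed; identical parameters and seed give bit-identical
#'   scenes.
#' @return An object of class `scene_params`.
#' @seealso [generate_scene()]
#' @export
scene_params <- function(n_vessels = 3,
                         vessel_diameter_range_um = c(8, 22),
                         true_pbr_um = 2.39,
                         dperf_um = NULL,
                         vessel_length_um = NULL,
                         n_frames = 40,
                         frame_shape_px = c(240, 240),
                         pixel_size_um = 1,
                         background_level = 0.85,
                         vessel_depth = 0.5,
                         noise_sd = 0.02,
                         excursion_model = c("uniform", "triangular"),
                         motion_jitter_px = 0,
                         curvature_amp_px = 1,
                         edge_softness_px = 2,
                         seed = 1L) {
  excursion_model <- match.arg(excursion_model)
  stopifnot(n_vessels >= 1, n_frames >= 1, pixel_size_um > 0,
            length(frame_shape_px) == 2, all(frame_shape_px >= 8),
            true_pbr_um >= 0,
            background_level > 0, background_level <= 1,
            vessel_depth > 0, vessel_depth <= 1,
            noise_sd >= 0, noise_sd <= 1,
            motion_jitter_px >= 0, edge_softness_px > 0)
  if (!is.null(dperf_um)) {
    stopifnot(length(dperf_um) == n_vessels, all(dperf_um > 0))
  } else {
    stopifnot(length(vessel_diameter_range_um) == 2,
              vessel_diameter_range_um[1] > 0,
              diff(vessel_diameter_range_um) >= 0)
  }
  p50_min <- (if (is.null(dperf_um)) vessel_diameter_range_um[1]
              else min(dperf_um)) - 2 * true_pbr_um
  if (p50_min <= 0) {
    stop("true median column width Dperf - 2 * PBR must stay positive ",
         "for every vessel")
  }
  structure(list(n_vessels = as.integer(n_vessels),
                 vessel_diameter_range_um = vessel_diameter_range_um,
                 true_pbr_um = true_pbr_um,
                 dperf_um = dperf_um,
                 vessel_length_um = vessel_length_um,
                 n_frames = as.integer(n_frames),
                 frame_shape_px = as.integer(frame_shape_px),
                 pixel_size_um = pixel_size_um,
                 background_level = background_level,
                 vessel_depth = vessel_depth,
                 noise_sd = noise_sd,
                 excursion_model = excursion_model,
                 motion_jitter_px = as.integer(motion_jitter_px),
                 curvature_amp_px = curvature_amp_px,
                 edge_softness_px = edge_softness_px,
                 seed = as.integer(seed)),
            class = "scene_params")
}

#' Calibrated grayscale frame stack
#'
#' The raw analysis unit: `n_frames` co-registered grayscale frames with a
#' pixel calibration.  Intensities are expected in `[0, 1]` with vessels dark
#' on a bright background.
#'
#' @param frames A `H x W x T` numeric array, a single matrix, or a list of
#'   equally sized matrices.
#' @param pixel_size_um Pixel calibration, micrometres per pixel.
#' @param subject_id,site_id Optional labels carried through the pipeline.
#' @return An object of class `frame_stack`.
#' @export
frame_stack <- function(frames, pixel_size_um, subject_id = NA_character_,
                        site_id = NA_character_) {
  if (is.list(frames)) {
    dims <- vapply(frames, dim, integer(2))
    if (ncol(dims) > 1 && any(dims != dims[, 1])) {
      stop("all frames must have the same shape")
    }
    frames <- array(unlist(frames, use.names = FALSE),
                    dim = c(dims[1, 1], dims[2, 1], length(frames)))
  } else if (is.matrix(frames)) {
    frames <- array(frames, dim = c(dim(frames), 1L))
  }
  stopifnot(is.array(frames), length(dim(frames)) == 3, dim(frames)[3] >= 1,
            pixel_size_um > 0)
  structure(list(frames = frames, pixel_size_um = pixel_size_um,
                 subject_id = subject_id, site_id = site_id),
            class = "frame_stack")
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frame(s) of %d x %d px (%.3g um/px)\n",
              d[3], d[1], d[2], x$pixel_size_um))
  invisible(x)
}

n_frames <- function(stack) dim(stack$frames)[3]

get_frame <- function(stack, i) stack$frames[, , i]

field_area_mm2 <- function(stack) {
  d <- dim(stack$frames)
  d[1] * d[2] * stack$pixel_size_um^2 / 1e6
}

# Per-frame column widths for one vessel under the configured excursion law.
draw_widths <- function(model, n, p50, pbr) {
  if (pbr == 0) return(rep(p50, n))
  s <- 2 * pbr
  switch(model,
         uniform = stats::runif(n, p50 - s, p50 + s),
         triangular = p50 + s * (stats::runif(n) + stats::runif(n) - 1))
}

#' Render a synthetic scene with known ground truth
#'
#' Draws per-frame column widths and lateral positions for each vessel under
#' the configured excursion law, renders the frames (trapezoidal transverse
#' profile whose full width at half depth equals the modelled column width),
#' adds Gaussian noise and optional rigid jitter, and returns the stack
#' together with the generating truth.
#'
#' @param params A [scene_params()] object.
#' @return A list with elements `stack` (a [frame_stack()]) and `truth`, a
#'   `scene_truth` list holding the per-vessel table (`dperf_um`, `p50_um`,
#'   `pbr_um`, planned segment count), the drawn per-frame widths, the clean
#'   centerlines and the field area in mm^2.
#' @examples
#' sc <- generate_scene(scene_params(n_vessels = 1, dperf_um = 11.8,
#'                                   true_pbr_um = 2.4, n_frames = 4,
#'                                   frame_shape_px = c(64, 120),
#'                                   noise_sd = 0, seed = 7))
#' range(sc$stack$frames)
#' sc$truth$vessels
#' @export
generate_scene <- function(params) {
  stopifnot(inherits(params, "scene_params"))
  set.seed(params$seed)
  px <- params$pixel_size_um
  H <- params$frame_shape_px[1]
  W <- params$frame_shape_px[2]
  nv <- params$n_vessels
  nf <- params$n_frames
  jit <- params$motion_jitter_px

  dperf <- params$dperf_um
  if (is.null(dperf)) {
    dperf <- stats::runif(nv, params$vessel_diameter_range_um[1],
                          params$vessel_diameter_range_um[2])
  }
  pbr <- rep(params$true_pbr_um, nv)
  p50 <- dperf - 2 * pbr
  if (any(p50 <= 0)) stop("Dperf - 2 * PBR must be positive for every vessel")

  # geometry: horizontal strips tall enough to keep each vessel's background
  # annulus (out to 4 radii) clear of its neighbours, plus jitter headroom
  margin_x_um <- 5 * px
  len <- params$vessel_length_um
  if (is.null(len)) len <- W * px - 2 * margin_x_um
  len <- rep(len, length.out = nv)
  half_win_um <- 4 * (dperf / 2) + (jit + 2 + params$edge_softness_px) * px
  strip_um <- 2 * half_win_um
  if (sum(strip_um) > H * px) {
    stop("degenerate geometry: vessels (with their background annuli) are ",
         "wider than the frame; enlarge frame_shape_px or reduce n_vessels")
  }
  if (any(len + 2 * margin_x_um > W * px + 1e-9)) {
    stop("degenerate geometry: vessel longer than the frame")
  }
  slack <- (H * px - sum(strip_um)) / nv
  row_center_um <- cumsum(strip_um + slack) - (strip_um + slack) / 2
  x0 <- margin_x_um + (W * px - 2 * margin_x_um - len) / 2
  x1 <- x0 + len

  amp_um <- params$curvature_amp_px * px
  phase <- stats::runif(nv, 0, 2 * pi)
  wavelength <- pmax(2 * len, 1)

  widths <- lapply(seq_len(nv), function(v) {
    draw_widths(params$excursion_model, nf, p50[v], pbr[v])
  })
  offsets <- lapply(seq_len(nv), function(v) {
    stats::runif(nf, -1, 1) * (dperf[v] - widths[[v]]) / 2
  })
  if (jit > 0) {
    dx <- sample(-jit:jit, nf, replace = TRUE)
    dy <- sample(-jit:jit, nf, replace = TRUE)
  } else {
    dx <- dy <- rep(0L, nf)
  }

  e_um <- params$edge_softness_px * px
  ax_um <- px     # axial end ramp: half depth exactly at the nominal ends
  y_um <- (seq_len(H) - 0.5) * px
  x_um <- (seq_len(W) - 0.5) * px

  center_y <- function(v, x) {
    row_center_um[v] + amp_um * sin(2 * pi * (x - x0[v]) / wavelength[v] +
                                    phase[v])
  }
  # cosine of the local tangent angle: widths and lateral excursions are
  # defined perpendicular to the centerline, the raster is vertical
  cos_theta <- function(v, x) {
    slope <- amp_um * (2 * pi / wavelength[v]) *
      cos(2 * pi * (x - x0[v]) / wavelength[v] + phase[v])
    1 / sqrt(1 + slope^2)
  }

  frames <- array(params$background_level, dim = c(H, W, nf))
  for (f in seq_len(nf)) {
    fr <- matrix(1, H, W)      # accumulated transmission (1 - drop)
    for (v in seq_len(nv)) {
      xs <- x_um - dx[f] * px
      axial <- pmin(pmax(pmin(xs - x0[v], x1[v] - xs) / ax_um + 0.5, 0), 1)
      cols <- which(axial > 0)
      if (!length(cols)) next
      w <- widths[[v]][f]
      ct <- cos_theta(v, xs[cols])
      cc <- center_y(v, xs[cols]) + offsets[[v]][f] / ct + dy[f] * px
      rows <- which(y_um >= min(cc) - (w / 2 + e_um) / min(ct) &
                    y_um <= max(cc) + (w / 2 + e_um) / min(ct))
      if (!length(rows)) next
      # perpendicular distance to the centerline (first order): the drawn
      # column width is the half-depth width measured across the vessel
      D <- abs(outer(y_um[rows], cc, "-")) *
        rep(ct, each = length(rows))
      drop <- params$vessel_depth *
        pmin(pmax((w / 2 + e_um / 2 - D) / e_um, 0), 1) *
        rep(axial[cols], each = length(rows))
      fr[rows, cols] <- fr[rows, cols] * (1 - drop)
    }
    frame <- params$background_level * fr
    if (params$noise_sd > 0) {
      frame <- frame + stats::rnorm(H * W, sd = params$noise_sd)
      frame <- pmin(pmax(frame, 0), 1)
    }
    frames[, , f] <- frame
  }

  centerlines <- lapply(seq_len(nv), function(v) {
    xs <- seq(x0[v], x1[v], by = 0.5)
    data.frame(x_um = xs, y_um = center_y(v, xs))
  })
  n_seg <- as.integer(floor((len + 1e-6) / 10))
  vessels <- data.frame(vessel = seq_len(nv),
                        row_center_um = row_center_um,
                        x0_um = x0, x1_um = x1, length_um = len,
                        dperf_um = dperf, p50_um = p50, pbr_um = pbr,
                        n_segments = n_seg)
  truth <- structure(list(vessels = vessels,
                          centerlines = centerlines,
                          widths_um = widths,
                          n_segments_total = sum(n_seg),
                          field_area_mm2 = H * W * px^2 / 1e6,
                          params = params),
                     class = "scene_truth")
  list(stack = frame_stack(frames, px), truth = truth)
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf("<scene_truth> %d vessel(s), %d planned 10-um segments, field %.4f mm^2\n",
              nrow(x$vessels), x$n_segments_total, x$field_area_mm2))
  print(x$vessels[, c("vessel", "dperf_um", "p50_um", "pbr_um",
                      "length_um", "n_segments")], row.names = FALSE)
  invisible(x)
}

#' Write a scene (frames + truth) to disk
#'
#' Frames go to a multi-page 32-bit float TIFF, the per-vessel truth to a CSV
#' and the scalar truth (field area, segment count, calibration) to a JSON
#' sidecar.
#'
#' @param scene A list as returned by [generate_scene()].
#' @param dir Output directory (created if needed).
#' @param basename File basename, default `"scene"`.
#' @return Invisibly, the paths written.
#' @export
write_scene <- function(scene, dir, basename = "scene") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tif <- file.path(dir, paste0(basename, ".tif"))
  csv <- file.path(dir, paste0(basename, "_truth.csv"))
  js <- file.path(dir, paste0(basename, "_truth.json"))
  write_recording(scene$stack, tif)
  utils::write.csv(scene$truth$vessels, csv, row.names = FALSE)
  jsonlite::write_json(list(pixel_size_um = scene$stack$pixel_size_um,
                            field_area_mm2 = scene$truth$field_area_mm2,
                            n_segments_total = scene$truth$n_segments_total),
                       js, auto_unbox = TRUE, digits = NA)
  invisible(c(tif = tif, truth_csv = csv, truth_json = js))
}
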