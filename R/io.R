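# Recording IO and run configuration.

#' Analysis run configuration
#'
#' Collects every tunable of the pipeline with its default.  The resolved
#' configuration is written alongside results by [run_pipeline()].
#'
#' @param pixel_size_um Pixel calibration, micrometres per pixel (required).
#' @param n_frames_required Frames a recording is expected to contain
#'   (default 40); shorter recordings are analysed with a warning.
#' @param contrast_threshold Minimum relative minor-marker profile depth for
#'   sufficient contrast ([assess_validity()]).
#' @param validity_fraction Fraction of sufficient minor markers a valid
#'   segment must exceed (strictly).
#' @param snr_threshold Minimum depth-to-noise ratio for a filled column.
#' @param max_diameter_um Upper vessel-diameter limit for detection.
#' @param dperf_fit_lo,dperf_fit_hi,dperf_extrapolate_to Perfused-diameter
#'   regression window and target fraction.
#' @param max_shift_px,min_sharpness Frame quality-control thresholds.
#' @param coverage,n_boot Tolerance-interval settings.
#' @param seed Integer seed for every stochastic step.
#' @param field_area_mm2 Optional override of the field area used for valid
#'   vessel density (default: full frame area).
#' @param out_dir Output directory for [run_pipeline()].
#' @return An object of class `run_config`.
#' @export
run_config <- function(pixel_size_um, n_frames_required = 40,
                       contrast_threshold = 0.3, validity_fraction = 0.6,
                       snr_threshold = 3, max_diameter_um = 30,
                       dperf_fit_lo = 0.25, dperf_fit_hi = 0.75,
                       dperf_extrapolate_to = 1.0, max_shift_px = 5,
                       min_sharpness = NULL, coverage = 0.95, n_boot = 2500,
                       seed = 1L, field_area_mm2 = NULL, out_dir = NULL) {
  stopifnot(pixel_size_um > 0, n_frames_required >= 1,
            contrast_threshold > 0, validity_fraction > 0,
            snr_threshold > 0, max_diameter_um > 0,
            dperf_fit_lo >= 0, dperf_fit_hi > dperf_fit_lo,
            dperf_extrapolate_to >= dperf_fit_hi, max_shift_px > 0,
            coverage > 0, coverage < 1, n_boot >= 1)
  structure(list(pixel_size_um = pixel_size_um,
                 n_frames_required = as.integer(n_frames_required),
                 contrast_threshold = contrast_threshold,
                 validity_fraction = validity_fraction,
                 snr_threshold = snr_threshold,
                 max_diameter_um = max_diameter_um,
                 dperf_fit_lo = dperf_fit_lo, dperf_fit_hi = dperf_fit_hi,
                 dperf_extrapolate_to = dperf_extrapolate_to,
                 max_shift_px = max_shift_px, min_sharpness = min_sharpness,
                 coverage = coverage, n_boot = as.integer(n_boot),
                 seed = as.integer(seed), field_area_mm2 = field_area_mm2,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file whose keys are
#'   [run_config()] arguments (`pixel_size_um` is mandatory).
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported config format (use YAML or JSON): ", path)
  }
  unknown <- setdiff(names(cfg), names(formals(run_config)))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  }
  if (!"pixel_size_um" %in% names(cfg)) {
    stop("config is missing the mandatory pixel_size_um calibration")
  }
  do.call(run_config, cfg)
}

read_error <- function(msg, path) {
  stop(errorCondition(paste0(msg, ": ", path),
                      class = c("glyx_read_error", "error")))
}

to_gray <- function(frame) {
  if (is.matrix(frame)) return(frame)
  if (length(dim(frame)) == 3) {
    warning("colour input converted to grayscale by luminance")
    ch <- dim(frame)[3]
    if (ch >= 3) {
      return(0.2126 * frame[, , 1] + 0.7152 * frame[, , 2] +
               0.0722 * frame[, , 3])
    }
    return(frame[, , 1])
  }
  stop("unsupported frame dimensionality")
}

#' Read a recording into a frame stack
#'
#' Supported containers: multi-page TIFF (8/16-bit integer or 32-bit float
#' grayscale; colour converted by luminance with a warning) and directories
#' of numbered PNG/BMP-style frame sequences (PNG supported).  Uncompressed
#' AVI is not supported and is rejected with an explicit message.  Frames
#' are normalised to `[0, 1]`; a recording with fewer frames than
#' `n_frames_required` is read with a warning.
#'
#' @param path Path to a TIFF file or a directory of PNG frames.
#' @param pixel_size_um Pixel calibration; mandatory (may come from
#'   `config`).
#' @param config Optional [run_config()] supplying the calibration and the
#'   required frame count.
#' @param n_frames_required Expected frame count (default from config or
#'   40).
#' @param subject_id,site_id Labels attached to the stack.
#' @return A [frame_stack()].
#' @export
read_recording <- function(path, pixel_size_um = NULL, config = NULL,
                           n_frames_required = NULL,
                           subject_id = NA_character_,
                           site_id = NA_character_) {
  if (is.null(pixel_size_um) && !is.null(config)) {
    pixel_size_um <- config$pixel_size_um
  }
  if (is.null(n_frames_required)) {
    n_frames_required <- if (!is.null(config)) config$n_frames_required
      else 40L
  }
  if (is.null(pixel_size_um)) {
    stop("missing pixel-size calibration: supply pixel_size_um directly ",
         "or through a run_config")
  }
  if (grepl("\\.avi$", path, ignore.case = TRUE)) {
    stop("AVI containers are not supported; convert the recording to ",
         "multi-page TIFF or a PNG frame sequence")
  }
  if (!file.exists(path)) read_error("recording not found", path)
  frames <- if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.png$", full.names = TRUE,
                             ignore.case = TRUE))
    if (!length(files)) read_error("no PNG frames in directory", path)
    lapply(files, function(f) {
      fr <- try(png::readPNG(f), silent = TRUE)
      if (inherits(fr, "try-error")) read_error("unreadable PNG frame", f)
      to_gray(fr)
    })
  } else {
    raw <- try(tiff::readTIFF(path, all = TRUE), silent = TRUE)
    if (inherits(raw, "try-error")) read_error("unreadable TIFF", path)
    lapply(raw, to_gray)
  }
  dims <- vapply(frames, dim, integer(2))
  if (ncol(dims) > 1 && any(dims != dims[, 1])) {
    read_error("mixed frame sizes in recording", path)
  }
  mx <- max(vapply(frames, max, numeric(1)))
  if (mx > 1) frames <- lapply(frames, function(f) f / mx)
  if (length(frames) < n_frames_required) {
    warning(sprintf("recording has fewer than required frames (%d < %d)",
                    length(frames), n_frames_required))
  }
  frame_stack(frames, pixel_size_um, subject_id = subject_id,
              site_id = site_id)
}

#' Write a frame stack to a multi-page TIFF
#'
#' Frames are stored as 32-bit float grayscale, so intensities round-trip
#' exactly at single precision.
#'
#' @param stack A [frame_stack()].
#' @param path Output path (`.tif`).
#' @return The path, invisibly.
#' @export
write_recording <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  frames <- lapply(seq_len(n_frames(stack)), function(i) get_frame(stack, i))
  tiff::writeTIFF(frames, path, bits.per.sample = 32L)
  invisible(path)
}
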