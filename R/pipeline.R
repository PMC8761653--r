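# End-to-end orchestration: recording -> segments -> PBR -> cohort tables.

site_na_row <- function(site_id, n_total = 0L, n_valid = 0L, area = NA_real_,
                        reason = "unanalyzable") {
  out <- data.frame(site_id = site_id, vvd_um_per_mm2 = NA_real_,
                    pct_rbc_filling = NA_real_, median_p50_um = NA_real_,
                    dperf_um = NA_real_, pbr_5_25 = NA_real_,
                    pbr_5_9 = NA_real_, pbr_10_19 = NA_real_,
                    pbr_20_25 = NA_real_, n_segments_total = n_total,
                    n_segments_valid = n_valid)
  attr(out, "reason") <- reason
  out
}

#' Analyse one recording
#'
#' Runs the full single-recording pipeline: frame quality control, vessel
#' detection on the first accepted frame, partitioning into 10-um segments,
#' contrast validity classification, per-frame column measurement of the
#' valid segments, and the site summary.
#'
#' @param stack A [frame_stack()].
#' @param config A [run_config()].
#' @return List: `site` (one-row [summarize_site()] result), `qc`
#'   (per-frame flags), `segments` (per-segment table: position, contrast
#'   fraction, validity, P50/Dperf/PBR/class), `profiles` (the
#'   `segment_profile` list).
#' @export
analyze_recording <- function(stack, config) {
  stopifnot(inherits(stack, "frame_stack"), inherits(config, "run_config"))
  px <- stack$pixel_size_um
  area <- if (!is.null(config$field_area_mm2)) config$field_area_mm2 else
    field_area_mm2(stack)
  qc <- frame_qc(stack, max_shift_px = config$max_shift_px,
                 min_sharpness = config$min_sharpness)
  if (isTRUE(attr(qc, "unanalyzable"))) {
    return(list(site = site_na_row(stack$site_id, area = area), qc = qc,
                segments = NULL, profiles = list()))
  }
  accepted <- qc$frame[qc$accepted]
  first <- get_frame(stack, accepted[1])
  centerlines <- detect_vessels(first, px,
                                max_diameter_um = config$max_diameter_um)
  segments <- list()
  for (v in seq_along(centerlines)) {
    segs <- partition_segments(centerlines[[v]], px)
    for (s in segs) {
      s$vessel_id <- v
      s$segment_id <- sprintf("v%02d_s%03d", v, s$segment_id)
      segments[[length(segments) + 1L]] <- s
    }
  }
  segments <- lapply(segments, function(s) {
    assess_validity(first, s, px,
                    contrast_threshold = config$contrast_threshold,
                    validity_fraction = config$validity_fraction)
  })
  vr <- validity_report(segments, area, site_id = stack$site_id)
  valid_segs <- Filter(function(s) isTRUE(s$valid), segments)
  profiles <- lapply(valid_segs, function(s) {
    segment_profile(stack, s, snr_threshold = config$snr_threshold,
                    accepted_frames = accepted,
                    dperf_fit_lo = config$dperf_fit_lo,
                    dperf_fit_hi = config$dperf_fit_hi,
                    dperf_extrapolate_to = config$dperf_extrapolate_to)
  })
  seg_table <- do.call(rbind, lapply(segments, function(s) {
    data.frame(segment_id = s$segment_id,
               x_um = mean(s$markers$x_um), y_um = mean(s$markers$y_um),
               diameter_um = s$diameter_um,
               contrast_fraction = s$contrast_fraction,
               valid = isTRUE(s$valid),
               reason = s$reason)
  }))
  if (!is.null(seg_table)) {
    prof_ids <- vapply(profiles, function(p) p$segment_id, character(1))
    m <- match(seg_table$segment_id, prof_ids)
    seg_table$p50_um <- vapply(seq_along(m), function(i)
      if (is.na(m[i])) NA_real_ else profiles[[m[i]]]$p50_um, numeric(1))
    seg_table$dperf_um <- vapply(seq_along(m), function(i)
      if (is.na(m[i])) NA_real_ else profiles[[m[i]]]$dperf_um, numeric(1))
    seg_table$pbr_um <- vapply(seq_along(m), function(i)
      if (is.na(m[i])) NA_real_ else profiles[[m[i]]]$pbr_um, numeric(1))
    seg_table$diameter_class <- vapply(seq_along(m), function(i)
      if (is.na(m[i])) NA_character_ else profiles[[m[i]]]$diameter_class,
      character(1))
  }
  site <- summarize_site(profiles, vr,
                         fit_lo = config$dperf_fit_lo,
                         fit_hi = config$dperf_fit_hi,
                         extrapolate_to = config$dperf_extrapolate_to)
  list(site = site, qc = qc, segments = seg_table, profiles = profiles)
}

round_um <- function(df, digits = 2) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- round(df[[nm]], digits)
  }
  df
}

write_csv_plain <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "")
}

#' Run the full pipeline over a set of recordings
#'
#' Reads (or takes in-memory) one recording per subject and site, analyses
#' each ([analyze_recording()]), aggregates sites into per-subject means,
#' and — when the cohort is large enough — computes the cohort tables
#' (summary statistics, tolerance intervals, variance components, covariate
#' screen).  Every subject in the input appears either in the outputs or in
#' the exclusion table with a reason.  Fully deterministic given
#' `config$seed`.
#'
#' @param recordings Either a data.frame with columns `subject_id`, `site`,
#'   `path` (recordings read with [read_recording()]), or a list of
#'   [frame_stack()]s with `subject_id`/`site_id` set.
#' @param config A [run_config()].
#' @param metadata Optional per-subject covariate data.frame
#'   (`subject_id` + covariates) for the covariate screen.
#' @param out_dir Output directory; when given, CSV tables (micrometre
#'   values to 2 decimals, missing values as empty fields), a JSON run
#'   manifest with the resolved configuration and a text log are written.
#' @return List: `site_results`, `subject_means`, `report` (see
#'   [cohort_report()]; `NULL` when the cohort is too small), `exclusions`,
#'   `log` (character vector).
#' @export
run_pipeline <- function(recordings, config, metadata = NULL,
                         out_dir = config$out_dir) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  log <- character(0)
  note <- function(...) {
    msg <- sprintf(...)
    log <<- c(log, paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), msg))
    invisible(NULL)
  }
  exclusions <- data.frame(subject_id = character(0), site = character(0),
                           reason = character(0))
  exclude <- function(subject, site, reason) {
    exclusions <<- rbind(exclusions,
                         data.frame(subject_id = subject, site = site,
                                    reason = reason))
    note("excluded subject %s site %s: %s", subject, site, reason)
  }

  if (is.data.frame(recordings)) {
    stopifnot(all(c("subject_id", "site", "path") %in% names(recordings)))
    items <- lapply(seq_len(nrow(recordings)), function(i) {
      as.list(recordings[i, c("subject_id", "site", "path")])
    })
  } else {
    items <- lapply(recordings, function(st) {
      stopifnot(inherits(st, "frame_stack"))
      list(subject_id = st$subject_id, site = st$site_id, stack = st)
    })
  }

  site_rows <- list()
  for (it in items) {
    stack <- if (!is.null(it$stack)) it$stack else {
      st <- tryCatch(read_recording(it$path, config = config,
                                    subject_id = it$subject_id,
                                    site_id = as.character(it$site)),
                     glyx_read_error = function(e) e)
      if (inherits(st, "glyx_read_error")) {
        exclude(it$subject_id, as.character(it$site), conditionMessage(st))
        next
      }
      st
    }
    res <- analyze_recording(stack, config)
    row <- res$site
    if (!is.null(attr(row, "reason"))) {
      exclude(it$subject_id, as.character(it$site), attr(row, "reason"))
      next
    }
    row <- cbind(data.frame(subject_id = it$subject_id,
                            site = as.character(it$site)),
                 row[, setdiff(names(row), "site_id"), drop = FALSE])
    note("subject %s site %s: %d/%d segments valid, %d frames accepted",
         it$subject_id, as.character(it$site), row$n_segments_valid,
         row$n_segments_total, sum(res$qc$accepted))
    site_rows[[length(site_rows) + 1L]] <- row
  }
  site_results <- do.call(rbind, site_rows)

  param_cols <- c("vvd_um_per_mm2", "pct_rbc_filling", "median_p50_um",
                  "dperf_um", "pbr_5_25", "pbr_5_9", "pbr_10_19",
                  "pbr_20_25")
  subject_means <- NULL
  report <- NULL
  if (!is.null(site_results) && nrow(site_results) > 0) {
    subject_means <- aggregate_subjects(site_results, param_cols)
    n_sub <- nrow(subject_means)
    if (n_sub >= 20) {
      report <- cohort_report(site_results, covariates = metadata,
                              parameters = param_cols,
                              coverage = config$coverage,
                              n_boot = config$n_boot, seed = config$seed)
    } else {
      note("cohort of %d subject(s) too small for cohort-level statistics",
           n_sub)
    }
  }
  if (!is.null(metadata)) {
    missing_sub <- setdiff(metadata$subject_id,
                           c(if (!is.null(subject_means))
                               subject_means$subject_id,
                             exclusions$subject_id))
    for (s in missing_sub) exclude(s, NA_character_, "no recordings supplied")
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(site_results)) {
      write_csv_plain(round_um(site_results), file.path(out_dir,
                                                        "site_results.csv"))
    }
    if (!is.null(subject_means)) {
      write_csv_plain(round_um(subject_means),
                      file.path(out_dir, "subject_means.csv"))
    }
    if (!is.null(report)) {
      write_csv_plain(round_um(report$summary),
                      file.path(out_dir, "cohort_summary.csv"))
      write_csv_plain(round_um(report$tolerance),
                      file.path(out_dir, "tolerance_intervals.csv"))
      write_csv_plain(round_um(report$variance, 4),
                      file.path(out_dir, "variance_components.csv"))
      if (!is.null(report$covariates)) {
        write_csv_plain(round_um(report$covariates[,
          setdiff(names(report$covariates), "tukey")], 4),
          file.path(out_dir, "covariates.csv"))
      }
    }
    write_csv_plain(exclusions, file.path(out_dir, "exclusions.csv"))
    manifest <- config
    class(manifest) <- NULL
    manifest$min_sharpness <- manifest$min_sharpness %||% NA
    jsonlite::write_json(list(config = manifest,
                              n_recordings = length(items),
                              n_sites_analyzed =
                                if (is.null(site_results)) 0L else
                                  nrow(site_results),
                              n_excluded = nrow(exclusions)),
                         file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    writeLines(log, file.path(out_dir, "run_log.txt"))
  }
  list(site_results = site_results, subject_means = subject_means,
       report = report, exclusions = exclusions, log = log)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
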