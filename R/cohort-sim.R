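# Synthetic cohorts with a controlled inter-/intra-individual variance
# partition, used to validate the cohort statistics (tolerance intervals,
# REML variance components, covariate screening).

#' Default population parameters for a healthy adult feline cohort
#'
#' Population mean, standard deviation and inter-individual fraction of total
#' variance for each microvascular parameter, matching published reference
#' values for healthy sedated cats measured sublingually.  These are the
#' conditions the cohort generator emulates by default.
#'
#' @return A data.frame with columns `name`, `mean`, `sd`, `inter_fraction`.
#' @export
default_cohort_parameters <- function() {
  data.frame(
    name = c("vvd_um_per_mm2", "pct_rbc_filling", "pbr_5_25", "pbr_5_9",
             "pbr_10_19", "pbr_20_25", "median_p50"),
    mean = c(173.00, 72.70, 2.39, 1.34, 2.70, 2.92, 7.00),
    sd = c(64.80, 6.16, 0.26, 0.15, 0.30, 0.57, 0.68),
    inter_fraction = c(0.5013, 0.3222, 0.2648, 0.2952, 0.2843, 0.0698,
                       0.3541))
}

#' Parameters of a synthetic cohort
#'
#' @param n_subjects Number of subjects (default 101).
#' @param n_sites Recording sites per subject (default 3; at least 2 are
#'   required for variance-component estimation).
#' @param parameters Data.frame with columns `name`, `mean`, `sd`,
#'   `inter_fraction`; one simulated measurement column per row.  Default:
#'   [default_cohort_parameters()].
#' @param covariate_effects Optional named list, one entry per parameter
#'   name, each a list of covariate effects added linearly to that parameter:
#'   numeric scalars for continuous covariates (slope per unit of the
#'   centred covariate, e.g. `list(weight_kg = -0.3)`) and named numeric
#'   vectors for categorical ones (per-level offsets, e.g.
#'   `list(sex = c(M = 0, F = 0.2))`).
#' @param seed Integer seed.
#' @return An object of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 101, n_sites = 3,
                          parameters = default_cohort_parameters(),
                          covariate_effects = list(), seed = 1L) {
  stopifnot(n_subjects >= 1, n_sites >= 2,
            is.data.frame(parameters),
            all(c("name", "mean", "sd", "inter_fraction") %in%
                  names(parameters)),
            all(parameters$sd >= 0),
            all(parameters$inter_fraction >= 0),
            all(parameters$inter_fraction <= 1))
  bad <- setdiff(names(covariate_effects), parameters$name)
  if (length(bad)) stop("covariate_effects for unknown parameter(s): ",
                        paste(bad, collapse = ", "))
  structure(list(n_subjects = as.integer(n_subjects),
                 n_sites = as.integer(n_sites),
                 parameters = parameters,
                 covariate_effects = covariate_effects,
                 seed = as.integer(seed)),
            class = "cohort_params")
}

#' Simulate a cohort with a known variance partition
#'
#' For each parameter with population mean `mu`, total SD `sigma` and
#' inter-individual fraction `f`, site-level values are drawn as
#' `y_ij = mu + a_i + e_ij` with `a_i ~ N(0, f * sigma^2)` between subjects
#' and `e_ij ~ N(0, (1 - f) * sigma^2)` within subjects.  Subject covariates
#' (age, weight, sex, neuter status, sedation vitals) are simulated once per
#' subject; configured covariate effects are added linearly.  When both
#' `pbr_5_25` and `median_p50` are simulated, a consistent
#' `dperf_um = 2 * pbr_5_25 + median_p50` column is derived rather than drawn
#' independently, preserving the structural identity.
#'
#' @param params A [cohort_params()] object.
#' @return A list of class `glyx_cohort` with `measurements` (one row per
#'   subject x site) and `subjects` (one row per subject: covariates).
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_subjects
  k <- params$n_sites
  ids <- sprintf("S%03d", seq_len(n))

  status <- sample(c("MN", "MI", "FS", "FI"), n, replace = TRUE,
                   prob = c(35, 11, 17, 38) / 101)
  subjects <- data.frame(
    subject_id = ids,
    age_months = pmin(pmax(round(stats::rnorm(n, 67, 46)), 11), 160),
    weight_kg = round(pmax(stats::rnorm(n, 3.58, 0.79), 1.5), 2),
    sex = substr(status, 1, 1),
    neutered = substr(status, 2, 2) %in% c("N", "S"),
    hr = round(stats::rnorm(n, 150, 20)),
    rr = round(pmax(stats::rnorm(n, 30, 8), 8)),
    spo2 = round(pmin(stats::rnorm(n, 97, 1.5), 100), 1),
    obp = round(stats::rnorm(n, 120, 15)))

  meas <- data.frame(subject_id = rep(ids, each = k),
                     site = rep(seq_len(k), times = n))
  pt <- params$parameters
  for (r in seq_len(nrow(pt))) {
    sigma2 <- pt$sd[r]^2
    a <- stats::rnorm(n, 0, sqrt(pt$inter_fraction[r] * sigma2))
    e <- stats::rnorm(n * k, 0, sqrt((1 - pt$inter_fraction[r]) * sigma2))
    y <- pt$mean[r] + rep(a, each = k) + e
    eff <- params$covariate_effects[[pt$name[r]]]
    if (!is.null(eff)) {
      for (cv in names(eff)) {
        val <- subjects[[cv]][match(meas$subject_id, subjects$subject_id)]
        if (is.numeric(eff[[cv]]) && is.null(names(eff[[cv]]))) {
          y <- y + eff[[cv]] * (val - mean(subjects[[cv]]))
        } else {
          y <- y + eff[[cv]][as.character(val)]
        }
      }
    }
    meas[[pt$name[r]]] <- y
  }
  if (all(c("pbr_5_25", "median_p50") %in% names(meas)) &&
      !"dperf_um" %in% names(meas)) {
    meas$dperf_um <- 2 * meas$pbr_5_25 + meas$median_p50
  }
  structure(list(measurements = meas, subjects = subjects, params = params),
            class = "glyx_cohort")
}

#' @export
print.glyx_cohort <- function(x, ...) {
  cat(sprintf("<glyx_cohort> %d subjects x %d sites, %d parameter(s)\n",
              x$params$n_subjects, x$params$n_sites,
              ncol(x$measurements) - 2L))
  invisible(x)
}

# Accept either a glyx_cohort or a bare measurements data.frame.
cohort_measurements <- function(cohort) {
  if (inherits(cohort, "glyx_cohort")) return(cohort$measurements)
  stopifnot(is.data.frame(cohort), "subject_id" %in% names(cohort))
  cohort
}
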