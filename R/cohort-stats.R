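# Cohort-level statistics: per-subject aggregation, nonparametric tolerance
# intervals with bootstrap confidence limits, one-way REML variance
# components, covariate screening and a normality report.

#' Per-subject means across recording sites
#'
#' @param cohort A `glyx_cohort` or a measurements data.frame (one row per
#'   subject x site, `subject_id` column plus numeric parameter columns).
#' @param parameters Character vector of parameter columns; default all
#'   numeric columns except `site`.
#' @return Data.frame with one row per subject: `subject_id`, `n_sites`
#'   (sites contributing) and the arithmetic mean of the available (non
#'   missing) site values per parameter.  Subjects with no non-missing value
#'   for any parameter are dropped with a message.
#' @export
aggregate_subjects <- function(cohort, parameters = NULL) {
  meas <- cohort_measurements(cohort)
  if (is.null(parameters)) {
    parameters <- setdiff(names(meas)[vapply(meas, is.numeric, logical(1))],
                          c("site", "site_index"))
  }
  stopifnot(all(parameters %in% names(meas)))
  ids <- unique(meas$subject_id)
  rows <- lapply(ids, function(id) {
    sub <- meas[meas$subject_id == id, parameters, drop = FALSE]
    n_ok <- vapply(sub, function(v) sum(!is.na(v)), integer(1))
    if (all(n_ok == 0)) return(NULL)
    out <- data.frame(subject_id = id, n_sites = max(n_ok))
    for (p in parameters) {
      out[[p]] <- if (n_ok[[p]] > 0) mean(sub[[p]], na.rm = TRUE) else
        NA_real_
    }
    out
  })
  dropped <- ids[vapply(rows, is.null, logical(1))]
  if (length(dropped)) {
    message("dropped subject(s) with all sites missing: ",
            paste(dropped, collapse = ", "))
  }
  do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
}

#' Nonparametric tolerance interval with bootstrap confidence limits
#'
#' The interval limits are the empirical quantiles at `(1 - coverage) / 2`
#' and `1 - (1 - coverage) / 2` of the per-subject values (linear
#' interpolation, type-7 convention); the 95% confidence interval of each
#' limit comes from `n_boot` nonparametric bootstrap resamples of the
#' subjects.  An order-statistic (Wilks) variant, which picks the extreme
#' order statistics guaranteeing the coverage with 95% confidence, is
#' available as `method = "wilks"`.
#'
#' @param values Numeric vector of per-subject means (n >= 20).
#' @param coverage Central fraction of the population to cover.
#' @param n_boot Bootstrap resamples for the limit CIs.
#' @param seed Integer seed (the point limits depend only on the sample;
#'   only the CIs are stochastic).
#' @param method `"quantile"` (default) or `"wilks"`.
#' @return A `tolerance_interval` list: `lower`, `upper`, `lower_ci`,
#'   `upper_ci` (length-2 vectors), `coverage`, `n`, `n_boot`, `seed`,
#'   `method`.
#' @export
tolerance_interval <- function(values, coverage = 0.95, n_boot = 2500,
                               seed = 1L, method = c("quantile", "wilks")) {
  method <- match.arg(method)
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 20) stop("need at least 20 subjects for a tolerance interval")
  stopifnot(coverage > 0, coverage < 1, n_boot >= 1)
  alpha <- (1 - coverage) / 2
  probs <- c(alpha, 1 - alpha)
  if (method == "quantile") {
    lims <- unname(stats::quantile(values, probs, type = 7))
  } else {
    # Wilks: symmetric extreme order statistics covering `coverage` of the
    # population with >= 95% confidence (falls back to the sample range)
    d <- 0
    repeat {
      cov_conf <- stats::pbeta(coverage, n - 2 * (d + 1) + 1, 2 * (d + 1))
      if (cov_conf > 0.95 || d + 1 > floor((n - 1) / 2)) break
      d <- d + 1
    }
    s <- sort(values)
    lims <- c(s[d + 1], s[n - d])
  }
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n)
  boot <- apply(idx, 2, function(i) stats::quantile(values[i], probs,
                                                    type = 7))
  lci <- unname(stats::quantile(boot[1, ], c(0.025, 0.975), type = 7))
  uci <- unname(stats::quantile(boot[2, ], c(0.025, 0.975), type = 7))
  structure(list(lower = lims[1], upper = lims[2],
                 lower_ci = lci, upper_ci = uci,
                 coverage = coverage, n = n, n_boot = n_boot, seed = seed,
                 method = method, quantile_type = 7),
            class = "tolerance_interval")
}

#' @export
print.tolerance_interval <- function(x, ...) {
  cat(sprintf("%.0f%% tolerance interval (n = %d, %s):\n", 100 * x$coverage,
              x$n, x$method))
  cat(sprintf("  lower %.4g (95%% CI %.4g-%.4g)\n", x$lower, x$lower_ci[1],
              x$lower_ci[2]))
  cat(sprintf("  upper %.4g (95%% CI %.4g-%.4g)\n", x$upper, x$upper_ci[1],
              x$upper_ci[2]))
  invisible(x)
}

# Profiled REML criterion (-2 log restricted likelihood, up to a constant)
# for the one-way random-intercept model y_ij = mu + a_i + e_ij.
reml_criterion <- function(sa2, se2, k, ybar, ss_within, N) {
  vi <- se2 + k * sa2
  wi <- k / vi
  mu <- sum(wi * ybar) / sum(wi)
  (N - length(k)) * log(se2) + sum(log(vi)) + ss_within / se2 +
    sum(wi * (ybar - mu)^2) + log(sum(wi))
}

#' REML inter-/intra-individual variance components
#'
#' Fits the one-way random-intercept model `y_ij = mu + a_i + e_ij` by
#' restricted maximum likelihood (closed-form profiled criterion, quasi
#' Newton optimisation started from the ANOVA method-of-moments estimates).
#' Standard errors come from the numerical Hessian of the REML criterion;
#' Wald 95% confidence intervals are unconstrained and may cross zero.
#' Point estimates are truncated at zero.  On balanced data with interior
#' estimates the result coincides with the closed-form balanced one-way
#' ANOVA estimators.
#'
#' @param cohort A `glyx_cohort` or measurements data.frame.
#' @param parameter Name of the measurement column to decompose.
#' @param subject_col Subject identifier column.
#' @return A `variance_decomposition` list: `parameter`,
#'   `inter_component`, `intra_component`, `inter_se`, `intra_se`,
#'   `inter_ci`, `intra_ci`, `pct_inter`, `pct_intra`, `n_subjects`,
#'   `n_obs`, `method` (`"REML"`, or `"moments"` on fallback).
#' @export
variance_components <- function(cohort, parameter,
                                subject_col = "subject_id") {
  meas <- cohort_measurements(cohort)
  stopifnot(parameter %in% names(meas), subject_col %in% names(meas))
  ok <- !is.na(meas[[parameter]]) & !is.na(meas[[subject_col]])
  y <- meas[[parameter]][ok]
  g <- factor(meas[[subject_col]][ok])
  k <- as.numeric(table(g))
  if (mean(k >= 2) < 0.8) {
    stop("variance components need >= 2 sites for >= 80% of subjects")
  }
  N <- length(y)
  nsub <- nlevels(g)
  ybar <- as.numeric(tapply(y, g, mean))
  ss_within <- sum((y - ybar[as.integer(g)])^2)

  # ANOVA method-of-moments start (exact for balanced designs)
  msw <- ss_within / (N - nsub)
  gm <- mean(y)
  msb <- sum(k * (ybar - gm)^2) / (nsub - 1)
  k0 <- (N - sum(k^2) / N) / (nsub - 1)
  mom <- c(sa2 = max((msb - msw) / k0, 0), se2 = msw)

  if (ss_within <= 1e-12 * max(1, sum(y^2))) {
    # replicates identical within every subject: intra variance is zero
    sa2 <- stats::var(ybar)
    out <- list(inter_component = sa2, intra_component = 0,
                inter_se = NA_real_, intra_se = NA_real_,
                inter_ci = c(NA_real_, NA_real_),
                intra_ci = c(NA_real_, NA_real_), method = "degenerate")
  } else {
    obj <- function(p) reml_criterion(p[1], p[2], k, ybar, ss_within, N)
    fit <- try(stats::optim(pmax(mom, c(0, 1e-8)), obj,
                            method = "L-BFGS-B",
                            lower = c(0, 1e-10 * mom[["se2"]] + 1e-12),
                            control = list(factr = 1e4)), silent = TRUE)
    if (inherits(fit, "try-error")) {
      warning("REML optimisation failed; falling back to ",
              "method-of-moments estimates")
      est <- mom
      V <- matrix(NA_real_, 2, 2)
      method <- "moments"
    } else {
      est <- fit$par
      H <- try(stats::optimHess(est, obj), silent = TRUE)
      V <- if (inherits(H, "try-error")) matrix(NA_real_, 2, 2) else
        tryCatch(2 * solve(H), error = function(e) matrix(NA_real_, 2, 2))
      method <- "REML"
    }
    se <- suppressWarnings(sqrt(diag(V)))
    out <- list(inter_component = max(est[1], 0),
                intra_component = max(est[2], 0),
                inter_se = se[1], intra_se = se[2],
                inter_ci = est[1] + c(-1, 1) * 1.96 * se[1],
                intra_ci = est[2] + c(-1, 1) * 1.96 * se[2],
                method = method)
  }
  tot <- out$inter_component + out$intra_component
  structure(c(list(parameter = parameter), out,
              list(pct_inter = 100 * out$inter_component / tot,
                   pct_intra = 100 * out$intra_component / tot,
                   n_subjects = nsub, n_obs = N)),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat(sprintf("Variance components for '%s' (%s, %d subjects, %d obs):\n",
              x$parameter, x$method, x$n_subjects, x$n_obs))
  cat(sprintf("  inter: %.4g (SE %.3g, 95%% CI %.3g-%.3g) = %.2f%% of total\n",
              x$inter_component, x$inter_se, x$inter_ci[1], x$inter_ci[2],
              x$pct_inter))
  cat(sprintf("  intra: %.4g (SE %.3g, 95%% CI %.3g-%.3g) = %.2f%% of total\n",
              x$intra_component, x$intra_se, x$intra_ci[1], x$intra_ci[2],
              x$pct_intra))
  invisible(x)
}

#' Screen covariates against microvascular parameters
#'
#' Continuous covariates are tested by simple linear regression (slope,
#' R-squared, two-sided p); categorical covariates by one-way ANOVA, with
#' Tukey pairwise comparisons run only when the ANOVA is significant at
#' `alpha`.  No multiple-testing correction is applied across the screen.
#'
#' @param subject_means Data.frame from [aggregate_subjects()].
#' @param covariates Data.frame with `subject_id` and covariate columns
#'   (numeric columns are treated as continuous, everything else as
#'   categorical).
#' @param parameters Parameter columns to screen; default all numeric
#'   columns of `subject_means` except `n_sites`.
#' @param alpha Significance threshold gating the Tukey step.
#' @param min_per_level Minimum subjects per categorical level; smaller
#'   levels are dropped from that test.
#' @return Data.frame with one row per parameter x covariate: `parameter`,
#'   `covariate`, `type`, `estimate` (slope; `NA` for categorical), `r2`,
#'   `p_value`, `significant`, and a `tukey` list-column of pairwise Tukey
#'   p-values (`NULL` unless categorical and significant).  Zero-variance
#'   covariates are skipped with a message.
#' @export
covariate_screen <- function(subject_means, covariates, parameters = NULL,
                             alpha = 0.05, min_per_level = 3) {
  stopifnot("subject_id" %in% names(subject_means),
            "subject_id" %in% names(covariates))
  if (is.null(parameters)) {
    parameters <- setdiff(
      names(subject_means)[vapply(subject_means, is.numeric, logical(1))],
      "n_sites")
  }
  df <- merge(subject_means, covariates, by = "subject_id")
  cov_names <- setdiff(names(covariates), "subject_id")
  rows <- list()
  for (p in parameters) {
    for (cv in cov_names) {
      x <- df[[cv]]
      y <- df[[p]]
      ok <- !is.na(x) & !is.na(y)
      x <- x[ok]; y <- y[ok]
      if (is.numeric(x)) {
        if (stats::sd(x) == 0) {
          message("skipping zero-variance covariate: ", cv)
          next
        }
        fit <- stats::lm(y ~ x)
        sm <- summary(fit)
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = p, covariate = cv, type = "continuous",
          estimate = unname(stats::coef(fit)[2]), r2 = sm$r.squared,
          p_value = sm$coefficients[2, 4])
        rows[[length(rows)]]$tukey <- list(NULL)
      } else {
        f <- factor(x)
        keep_lv <- names(which(table(f) >= min_per_level))
        sel <- f %in% keep_lv
        f <- droplevels(factor(x[sel]))
        ys <- y[sel]
        if (nlevels(f) < 2) {
          message("skipping covariate without >= 2 usable levels: ", cv)
          next
        }
        av <- stats::aov(ys ~ f)
        pv <- summary(av)[[1]][["Pr(>F)"]][1]
        r2 <- summary(stats::lm(ys ~ f))$r.squared
        tk <- if (is.finite(pv) && pv < alpha) {
          tt <- stats::TukeyHSD(av)$f
          stats::setNames(tt[, "p adj"], rownames(tt))
        } else NULL
        rows[[length(rows) + 1L]] <- data.frame(
          parameter = p, covariate = cv, type = "categorical",
          estimate = NA_real_, r2 = r2, p_value = pv)
        rows[[length(rows)]]$tukey <- list(tk)
      }
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(out)) out$significant <- out$p_value < alpha
  out
}

#' Kolmogorov-Smirnov normality report
#'
#' Lilliefors-corrected Kolmogorov-Smirnov test against a normal
#' distribution with estimated mean and SD.  Report-only: the result does
#' not gate any pipeline step.
#'
#' @param values Numeric vector (n >= 20).
#' @return List: `statistic`, `p_value`, `n`, `testable` (`FALSE` for a
#'   degenerate, constant sample).
#' @export
normality_check <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 20) stop("normality check needs n >= 20")
  if (stats::sd(values) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                n = length(values), testable = FALSE))
  }
  kt <- nortest::lillie.test(values)
  list(statistic = unname(kt$statistic), p_value = kt$p.value,
       n = length(values), testable = TRUE)
}

#' Cohort report: summary, tolerance intervals, variance components,
#' covariates
#'
#' Produces the standard cohort tables from site-level measurements:
#' per-parameter summary statistics of the per-subject means (mean, SD, SE,
#' min, max, normality p), tolerance intervals with bootstrap CIs, REML
#' inter-/intra-individual variance components, and (optionally) a
#' covariate screen.
#'
#' @param cohort A `glyx_cohort` or measurements data.frame.
#' @param covariates Optional covariate data.frame (`subject_id` + columns);
#'   taken from the cohort object when present.
#' @param parameters Parameter columns; default all numeric except `site`.
#' @param coverage,n_boot,seed Tolerance-interval settings.
#' @return List of data.frames: `summary`, `tolerance`, `variance`,
#'   `covariates` (`NULL` when no covariates were given), plus
#'   `subject_means`.
#' @export
cohort_report <- function(cohort, covariates = NULL, parameters = NULL,
                          coverage = 0.95, n_boot = 2500, seed = 1L) {
  meas <- cohort_measurements(cohort)
  if (is.null(covariates) && inherits(cohort, "glyx_cohort")) {
    covariates <- cohort$subjects
  }
  if (is.null(parameters)) {
    parameters <- setdiff(names(meas)[vapply(meas, is.numeric, logical(1))],
                          c("site", "site_index"))
  }
  sm <- aggregate_subjects(meas, parameters)
  summary_tab <- do.call(rbind, lapply(parameters, function(p) {
    v <- sm[[p]][!is.na(sm[[p]])]
    norm_p <- if (length(v) >= 20 && stats::sd(v) > 0)
      normality_check(v)$p_value else NA_real_
    data.frame(parameter = p, n = length(v), mean = mean(v),
               sd = stats::sd(v), se = stats::sd(v) / sqrt(length(v)),
               min = min(v), max = max(v), ks_normality_p = norm_p)
  }))
  tol_tab <- do.call(rbind, lapply(parameters, function(p) {
    v <- sm[[p]][!is.na(sm[[p]])]
    ti <- tolerance_interval(v, coverage = coverage, n_boot = n_boot,
                             seed = seed)
    data.frame(parameter = p, lower = ti$lower,
               lower_ci_lo = ti$lower_ci[1], lower_ci_hi = ti$lower_ci[2],
               upper = ti$upper,
               upper_ci_lo = ti$upper_ci[1], upper_ci_hi = ti$upper_ci[2])
  }))
  var_tab <- do.call(rbind, lapply(parameters, function(p) {
    vc <- variance_components(meas, p)
    data.frame(parameter = p,
               inter_component = vc$inter_component,
               inter_se = vc$inter_se,
               inter_ci_lo = vc$inter_ci[1], inter_ci_hi = vc$inter_ci[2],
               pct_inter = vc$pct_inter,
               intra_component = vc$intra_component,
               intra_se = vc$intra_se,
               intra_ci_lo = vc$intra_ci[1], intra_ci_hi = vc$intra_ci[2],
               pct_intra = vc$pct_intra)
  }))
  cov_tab <- if (!is.null(covariates)) {
    covariate_screen(sm, covariates, parameters)
  } else NULL
  list(summary = summary_tab, tolerance = tol_tab, variance = var_tab,
       covariates = cov_tab, subject_means = sm)
}
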