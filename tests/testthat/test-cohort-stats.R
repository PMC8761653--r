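# Per-subject aggregation, tolerance intervals, REML variance components,
# covariate screening, normality.

test_that("subjects aggregate as the mean of available sites", {
  m <- data.frame(subject_id = rep(c("a", "b", "c"), each = 3),
                  site = rep(1:3, 3),
                  y = c(2.3, 2.4, 2.5, 2.3, NA, 2.5, 1, 1, 1))
  out <- aggregate_subjects(m, "y")
  expect_equal(out$y, c(2.4, 2.4, 1))
  expect_equal(out$n_sites, c(3L, 2L, 3L))
  # a subject with all sites missing is dropped with a message
  m$y[m$subject_id == "c"] <- NA
  expect_message(out2 <- aggregate_subjects(m, "y"), "dropped")
  expect_equal(out2$subject_id, c("a", "b"))
})

test_that("tolerance limits equal sort-based interpolated quantiles", {
  ti <- tolerance_interval(1:100, seed = 1, n_boot = 50)
  expect_equal(ti$lower, quantile_oracle(1:100, 0.025), tolerance = 1e-12)
  expect_equal(ti$upper, quantile_oracle(1:100, 0.975), tolerance = 1e-12)
  expect_lte(ti$lower, ti$upper)
  expect_gte(ti$lower, 1); expect_lte(ti$upper, 100)
  # limits sit inside their own bootstrap CIs
  expect_gte(ti$lower, ti$lower_ci[1]); expect_lte(ti$lower, ti$lower_ci[2])
  expect_gte(ti$upper, ti$upper_ci[1]); expect_lte(ti$upper, ti$upper_ci[2])
})

test_that("a constant sample gives zero-width limits and CIs", {
  ti <- tolerance_interval(rep(3.2, 40), seed = 2, n_boot = 100)
  expect_equal(ti$lower, 3.2)
  expect_equal(ti$upper, 3.2)
  expect_equal(ti$lower_ci, c(3.2, 3.2))
  expect_equal(ti$upper_ci, c(3.2, 3.2))
})

test_that("large normal samples bracket +/- 1.96 sigma", {
  set.seed(5)
  x <- rnorm(10000)
  ti <- tolerance_interval(x, seed = 3, n_boot = 200)
  expect_equal(ti$lower, -1.96, tolerance = 0.1)
  expect_equal(ti$upper, 1.96, tolerance = 0.1)
})

test_that("tolerance limits are affine-equivariant and seed-stable", {
  set.seed(11)
  x <- rgamma(60, 3, 1)
  a <- 2.5; b <- -4
  t1 <- tolerance_interval(x, seed = 7)
  t2 <- tolerance_interval(a * x + b, seed = 7)
  expect_equal(t2$lower, a * t1$lower + b, tolerance = 1e-9)
  expect_equal(t2$upper, a * t1$upper + b, tolerance = 1e-9)
  # same seed: bit-reproducible; different seed: same limits, CIs move
  t1b <- tolerance_interval(x, seed = 7)
  expect_identical(t1[c("lower", "upper", "lower_ci", "upper_ci")],
                   t1b[c("lower", "upper", "lower_ci", "upper_ci")])
  t3 <- tolerance_interval(x, seed = 8)
  expect_identical(t3$lower, t1$lower)
  expect_identical(t3$upper, t1$upper)
  # on a large continuous sample the bootstrap CIs move with the seed
  set.seed(12)
  z <- rnorm(1000)
  z1 <- tolerance_interval(z, seed = 7, n_boot = 500)
  z2 <- tolerance_interval(z, seed = 8, n_boot = 500)
  expect_identical(z1$lower, z2$lower)
  expect_false(identical(c(z1$lower_ci, z1$upper_ci),
                         c(z2$lower_ci, z2$upper_ci)))
})

test_that("small samples are refused and the Wilks variant stays ordered", {
  expect_error(tolerance_interval(1:19), "at least 20")
  set.seed(21)
  x <- rnorm(120)
  tw <- tolerance_interval(x, seed = 4, method = "wilks", n_boot = 50)
  expect_lte(tw$lower, tw$upper)
  expect_gte(tw$lower, min(x)); expect_lte(tw$upper, max(x))
})

test_that("REML equals the balanced ANOVA moments estimator and lme4", {
  pars <- data.frame(name = "y", mean = 10, sd = 2, inter_fraction = 0.4)
  ch <- generate_cohort(cohort_params(n_subjects = 60, n_sites = 3,
                                      parameters = pars, seed = 11))
  vc <- variance_components(ch, "y")
  mom <- mom_oracle(ch$measurements$y, ch$measurements$subject_id)
  expect_equal(vc$inter_component, mom[["inter"]], tolerance = 1e-6)
  expect_equal(vc$intra_component, mom[["intra"]], tolerance = 1e-6)
  expect_equal(vc$pct_inter + vc$pct_intra, 100, tolerance = 1e-9)
  fit <- lme4::lmer(y ~ 1 + (1 | subject_id), data = ch$measurements,
                    REML = TRUE)
  v <- as.data.frame(lme4::VarCorr(fit))$vcov
  expect_equal(vc$inter_component, v[1], tolerance = 1e-5)
  expect_equal(vc$intra_component, v[2], tolerance = 1e-5)
})

test_that("REML handles unbalanced cohorts like lme4", {
  pars <- data.frame(name = "y", mean = 0, sd = 1, inter_fraction = 0.3)
  ch <- generate_cohort(cohort_params(n_subjects = 50, n_sites = 3,
                                      parameters = pars, seed = 13))
  m <- ch$measurements[-c(3, 7, 20, 44), ]   # drop a few sites
  vc <- variance_components(m, "y")
  fit <- lme4::lmer(y ~ 1 + (1 | subject_id), data = m, REML = TRUE)
  v <- as.data.frame(lme4::VarCorr(fit))$vcov
  expect_equal(vc$inter_component, v[1], tolerance = 1e-4)
  expect_equal(vc$intra_component, v[2], tolerance = 1e-4)
})

test_that("identical replicates give zero intra-individual variance", {
  m <- data.frame(subject_id = rep(sprintf("s%02d", 1:30), each = 3),
                  y = rep(rnorm(30, 5, 2), each = 3))
  vc <- variance_components(m, "y")
  expect_equal(vc$intra_component, 0)
  expect_equal(vc$inter_component,
               var(tapply(m$y, m$subject_id, mean)[unique(m$subject_id)]),
               tolerance = 1e-9)
  expect_equal(vc$pct_inter, 100)
})

test_that("variance fractions are recovered on cohort-sized simulations", {
  pct <- vapply(1:10, function(i) {
    pars <- data.frame(name = "y", mean = 173, sd = 79.5,
                       inter_fraction = 0.5)
    ch <- generate_cohort(cohort_params(n_subjects = 101, n_sites = 3,
                                        parameters = pars, seed = 500 + i))
    variance_components(ch, "y")$pct_inter
  }, numeric(1))
  expect_equal(mean(pct), 50, tolerance = 5)
})

test_that("covariate screening: exact fits, null groups, degenerate input", {
  set.seed(9)
  sm <- data.frame(subject_id = sprintf("s%02d", 1:40), n_sites = 3,
                   y = numeric(40))
  cov <- data.frame(subject_id = sm$subject_id,
                    x = rnorm(40), g = rep(c("A", "B"), 20),
                    z = rep(1, 40))
  sm$y <- 2 + 3 * cov$x                      # exactly linear
  expect_message(out <- suppressWarnings(covariate_screen(sm, cov, "y")),
                 "zero-variance")
  lin <- out[out$covariate == "x", ]
  expect_equal(lin$r2, 1, tolerance = 1e-9)
  expect_lt(lin$p_value, 1e-12)
  expect_equal(lin$estimate, 3, tolerance = 1e-9)
  expect_false("z" %in% out$covariate)
  # identical groups: ANOVA not significant, Tukey not run
  sm2 <- sm
  sm2$y <- rep(rnorm(20), 2)
  cov2 <- cov
  cov2$g <- rep(c("A", "B"), each = 20)
  sm2$y <- c(sm2$y[1:20], sm2$y[1:20])       # same values in both groups
  out2 <- covariate_screen(sm2, cov2[c("subject_id", "g")], "y")
  expect_gt(out2$p_value, 0.05)
  expect_null(out2$tukey[[1]])
})

test_that("Tukey comparisons appear only for significant ANOVA", {
  set.seed(10)
  sm <- data.frame(subject_id = sprintf("s%03d", 1:90), n_sites = 3,
                   y = c(rnorm(30, 0), rnorm(30, 0.1), rnorm(30, 3)))
  cov <- data.frame(subject_id = sm$subject_id,
                    g = rep(c("A", "B", "C"), each = 30))
  out <- covariate_screen(sm, cov, "y")
  expect_lt(out$p_value, 0.05)
  tk <- out$tukey[[1]]
  expect_equal(sort(names(tk)), c("B-A", "C-A", "C-B"))
  expect_lt(tk[["C-A"]], 0.05)
  expect_gt(tk[["B-A"]], 0.05)
})

test_that("the screen's type-I error sits near the nominal 5%", {
  set.seed(42)
  rej <- vapply(1:1000, function(i) {
    y <- rnorm(50)
    x <- rnorm(50)
    summary(stats::lm(y ~ x))$coefficients[2, 4] < 0.05
  }, logical(1))
  # independent simulation of the screen's continuous branch
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.075)
  set.seed(43)
  sm <- data.frame(subject_id = sprintf("s%02d", 1:50), n_sites = 3)
  rej2 <- vapply(1:200, function(i) {
    sm$y <- rnorm(50)
    cov <- data.frame(subject_id = sm$subject_id, x = rnorm(50))
    covariate_screen(sm, cov, "y")$significant
  }, logical(1))
  expect_lt(mean(rej2), 0.12)
})

test_that("normality check behaves under the null, power and degeneracy", {
  set.seed(6)
  pvals <- vapply(1:20, function(i) normality_check(rnorm(500))$p_value,
                  numeric(1))
  expect_gte(mean(pvals > 0.05), 0.9)
  set.seed(7)
  expect_lt(normality_check(rexp(500))$p_value, 0.05)
  const <- normality_check(rep(2, 50))
  expect_false(const$testable)
  expect_error(normality_check(rnorm(10)), "n >= 20")
})

test_that("cohort reports carry the reference-table structure", {
  ch <- generate_cohort(cohort_params(seed = 30))
  rep <- cohort_report(ch, n_boot = 200, seed = 5)
  expect_setequal(
    rep$summary$parameter,
    c("vvd_um_per_mm2", "pct_rbc_filling", "pbr_5_25", "pbr_5_9",
      "pbr_10_19", "pbr_20_25", "median_p50", "dperf_um"))
  expect_true(all(c("mean", "sd", "se", "min", "max") %in%
                    names(rep$summary)))
  expect_true(all(c("lower", "lower_ci_lo", "lower_ci_hi", "upper",
                    "upper_ci_lo", "upper_ci_hi") %in%
                    names(rep$tolerance)))
  expect_true(all(c("inter_component", "inter_se", "pct_inter",
                    "intra_component", "pct_intra") %in%
                    names(rep$variance)))
  expect_equal(rep$variance$pct_inter + rep$variance$pct_intra,
               rep(100, nrow(rep$variance)), tolerance = 1e-6)
  # the structural identity survives aggregation
  expect_equal(rep$subject_means$dperf_um,
               2 * rep$subject_means$pbr_5_25 + rep$subject_means$median_p50,
               tolerance = 1e-9)
  expect_true(all(rep$tolerance$lower <= rep$tolerance$upper))
})
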