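## A compact cohort for model-structure tests.
make_records <- function(seed = 2, delta = 0.4, n = 30, ...) {
  simulate_cohort_densities(
    cohort_sim_config(n_control = n, n_ssd = n, temporal_deficit = delta,
                      seed = seed, ...), "onh")
}

test_that("demographics tests match closed-form statistics", {
  ## sex table with counts (control M/F 17/22, case M/F 39/12):
  ## chi-square = N (ad - bc)^2 / (r1 r2 c1 c2) with no continuity correction
  cohort <- data.frame(
    subject = sprintf("P%02d", 1:90),
    diagnosis = rep(c("control", "ssd"), c(39, 51)),
    sex = c(rep(c("M", "F"), c(17, 22)), rep(c("M", "F"), c(39, 12))),
    age = c(rnorm(39, 36, 13), rnorm(51, 36, 11)))
  res <- demographics_table(cohort, continuous = "age", categorical = "sex")
  sexrow <- res[res$variable == "sex", ]
  closed <- 90 * (17 * 12 - 22 * 39)^2 / (39 * 51 * 56 * 34)
  expect_equal(sexrow$statistic, closed, tolerance = 1e-12)
  expect_equal(sexrow$p_value, stats::pchisq(closed, 1, lower.tail = FALSE),
               tolerance = 1e-12)

  ## chi-square equals the direct O/E oracle on random 2x2 tables
  set.seed(33)
  for (rep in 1:20) {
    tab <- matrix(sample(5:40, 4, TRUE), 2)
    coh <- data.frame(
      diagnosis = rep(rep(c("control", "ssd"), each = 2), times = as.vector(tab)),
      sex = rep(rep(c("M", "F"), 2), times = as.vector(tab)))
    r <- demographics_table(coh, continuous = character(0), categorical = "sex")
    expect_equal(r$statistic, oracle_chisq(t(tab)), tolerance = 1e-9)
  }

  ## identical groups: t = 0, p = 1
  coh2 <- data.frame(diagnosis = rep(c("control", "ssd"), each = 4),
                     age = rep(c(20, 30, 40, 50), 2))
  r2 <- demographics_table(coh2, continuous = "age", categorical = character(0))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)

  ## zero variance in both groups: warning, no p-value
  coh3 <- data.frame(diagnosis = rep(c("control", "ssd"), each = 4), ssi = 10)
  expect_warning(r3 <- demographics_table(coh3, continuous = "ssi",
                                          categorical = character(0)),
                 "no variation")
  expect_true(is.na(r3$p_value))
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  set.seed(19)
  for (rep in 1:200) {
    p <- runif(sample(1:10, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
  expect_error(bh_adjust(c(0.5, 1.2)), class = "invalid-pvals")
})

test_that("degenerate random effects reduce the mixed model to OLS", {
  d <- make_records(seed = 21, delta = 0.3, n = 20,
                    subject_sd = 0, eye_sd = 0, residual_sd = 0.01)
  fit <- suppressWarnings(fit_density_model(d, "onh"))
  d$quadrant <- factor(d$quadrant, levels = c("inferior", "nasal", "superior", "temporal"))
  d$diagnosis <- factor(d$diagnosis, levels = c("control", "ssd"))
  ols <- stats::lm(density ~ diagnosis * quadrant + ring + age + sex, data = d)
  fe <- lme4::fixef(fit)
  expect_equal(unname(fe[names(stats::coef(ols))]),
               unname(stats::coef(ols)), tolerance = 1e-6)
})

test_that("quadrant contrasts recover the planted temporal deficit with the right sign", {
  d <- make_records(seed = 22, delta = 0.4, n = 40)
  ana <- analyze_site(d, "onh")
  con <- ana$contrasts
  expect_setequal(con$quadrant, c("inferior", "nasal", "superior", "temporal"))
  ## control - SSD is positive when SSD density is lower
  tmp <- con[con$quadrant == "temporal", ]
  expect_gt(tmp$estimate, 0)
  expect_identical(con$quadrant[which.max(abs(con$estimate))], "temporal")
  expect_lt(tmp$p_adjusted, 0.05)
  expect_equal(tmp$estimate, 0.4 * 0.07, tolerance = 0.25)
  ## BH consistency within the table
  expect_equal(con$p_adjusted, oracle_bh(con$p_raw), tolerance = 1e-12)
  expect_true(all(con$p_adjusted >= con$p_raw - 1e-15))
  ## z approximation agrees closely at this sample size
  conz <- quadrant_contrasts(ana$fit, ddf = "z")
  expect_equal(conz$estimate, con$estimate, tolerance = 1e-9)
  expect_equal(conz$p_raw, con$p_raw, tolerance = 0.2)
})

test_that("ring collapse follows the ring-effect decision", {
  ## no planted ring effect: collapse, with density = mean(inner, outer)
  d <- make_records(seed = 23, delta = 0, n = 15, ring_offset = 0)
  fit <- fit_density_model(d, "onh")
  cd <- collapse_rings(fit, d)
  expect_true(attr(cd, "collapsed"))
  expect_gte(attr(cd, "ring_p"), 0.05)
  expect_true(all(cd$ring == "collapsed"))
  one <- d[d$subject == d$subject[1] & d$eye == "OD" & d$quadrant == "nasal", ]
  got <- cd$density[cd$subject == d$subject[1] & cd$eye == "OD" & cd$quadrant == "nasal"]
  expect_equal(got, mean(one$density), tolerance = 1e-12)

  ## a strong planted inner/outer offset blocks collapsing
  d2 <- make_records(seed = 24, delta = 0, n = 15, ring_offset = 0.05)
  fit2 <- fit_density_model(d2, "onh")
  cd2 <- collapse_rings(fit2, d2)
  expect_false(attr(cd2, "collapsed"))
  expect_lt(attr(cd2, "ring_p"), 0.05)
  expect_identical(nrow(cd2), nrow(d2))
})

test_that("age stratification isolates a young-only deficit and the age interaction", {
  cfg <- cohort_sim_config(n_control = 45, n_ssd = 45, temporal_deficit = 0.3,
                           deficit_old = 0, seed = 26)
  d <- simulate_cohort_densities(cfg, "onh")
  res <- age_stratified_analysis(d, "onh", cutoff = 30)
  py <- res$young$contrasts
  po <- res$old$contrasts
  expect_lt(py$p_adjusted[py$quadrant == "temporal"], 0.05)
  expect_gt(po$p_raw[po$quadrant == "temporal"], 0.05)
  ## pooled continuous-age interaction present
  expect_lt(res$age_interaction$p, 0.05)

  ## boundary: a subject aged exactly 30 lands in the young stratum
  d30 <- d
  d30$age[d30$subject == d30$subject[1]] <- 30
  r30 <- age_stratified_analysis(d30, "onh", cutoff = 30)
  nyoung <- length(unique(r30$young$records_used$subject))
  expect_true(d30$subject[1] %in% unique(r30$young$records_used$subject))
})

test_that("FAZ regression detects a planted group difference and reports group summaries", {
  set.seed(31)
  n <- 100   # 20% area shrink at sd 0.11: > 99% power at this n
  faz <- data.frame(
    diagnosis = rep(c("control", "ssd"), each = n),
    area_mm2 = c(rnorm(n, 0.32, 0.11), rnorm(n, 0.32 * 0.8, 0.11)),
    acircularity = c(rnorm(n, 1.32, 0.14), rnorm(n, 1.32, 0.14)))
  res <- faz_group_regression(faz)
  a <- res[res$metric == "area_mm2", ]
  expect_lt(a$coefficient, 0)
  expect_lt(a$p_value, 0.05)
  expect_equal(a$control_mean, mean(faz$area_mm2[faz$diagnosis == "control"]))
  expect_equal(a$control_sd, stats::sd(faz$area_mm2[faz$diagnosis == "control"]))
  ## null metric: coefficient near zero
  ac <- res[res$metric == "acircularity", ]
  expect_lt(abs(ac$coefficient), 3 * 0.14 * sqrt(2 / n))
  expect_error(faz_group_regression(faz[c(1:2, 61:90), ]), class = "invalid-cohort")
})

test_that("density-RNFL correlations recover a planted linear relationship", {
  cfg <- cohort_sim_config(n_control = 40, n_ssd = 40, temporal_deficit = 0,
                           rnfl_slope = 400, rnfl_sd = 4, seed = 28)
  d <- simulate_cohort_densities(cfg, "onh")
  res <- density_rnfl_correlation(d, cutoff = 30)
  expect_true(all(res$r[!is.na(res$r)] > 0))
  big <- res[res$n >= 30, ]
  expect_true(all(big$p_value < 0.05))
  ## symmetry of the correlation
  sub <- d[d$quadrant == "nasal" & d$diagnosis == "ssd" & d$age < 30, ]
  expect_equal(stats::cor(sub$density, sub$rnfl), stats::cor(sub$rnfl, sub$density))
  ## constant RNFL is flagged
  d2 <- d
  d2$rnfl <- 95
  r2 <- density_rnfl_correlation(d2)
  expect_true(all(is.na(r2$r)))
})
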