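#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validating wrapper around `stats::p.adjust(method = "BH")`: sort the
#' m p-values ascending, set `adj(i) = min_{j >= i} p(j) * m / j`, cap at 1,
#' and return in the original order. Used across the four quadrant contrasts
#' of each site (and nowhere wider).
#'
#' @param pvals numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(pvals) {
  if (!is.numeric(pvals) || anyNA(pvals) || any(pvals < 0 | pvals > 1))
    stop_octa("invalid-pvals", "p-values must be numeric in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Demographic group comparisons
#'
#' Compares the two diagnosis groups at subject level: Welch two-sample
#' t-tests for continuous variables and Pearson chi-square tests (no
#' continuity correction, df = (r-1)(c-1)) for categorical variables. A
#' continuous variable with zero variance in both groups (the degenerate
#' all-identical case) yields a warning and an NA p-value rather than a
#' spuriously extreme test.
#'
#' @param cohort data.frame with a `diagnosis` column (2 levels) and the
#'   variables below; rows are deduplicated by `subject` if present.
#' @param continuous,categorical character vectors of column names to test
#'   (missing columns are skipped).
#' @return data.frame with `variable`, `test`, `statistic`, `df`, `p_value`.
#' @export
demographics_table <- function(cohort,
                               continuous = c("age", "axial_length", "ssi"),
                               categorical = c("sex", "race", "ethnicity")) {
  stopifnot("diagnosis" %in% names(cohort))
  if ("subject" %in% names(cohort))
    cohort <- cohort[!duplicated(cohort$subject), , drop = FALSE]
  g <- factor(cohort$diagnosis)
  if (nlevels(g) != 2L)
    stop_octa("invalid-cohort", "demographics_table needs exactly 2 diagnosis groups")
  out <- list()
  for (v in intersect(continuous, names(cohort))) {
    x <- split(cohort[[v]], g)
    if (stats::var(x[[1]], na.rm = TRUE) == 0 && stats::var(x[[2]], na.rm = TRUE) == 0) {
      warning(sprintf("'%s': no variation in the data in either group; p-value omitted", v))
      out[[v]] <- data.frame(variable = v, test = "welch_t",
                             statistic = NA_real_, df = NA_real_,
                             p_value = NA_real_)
    } else {
      tt <- stats::t.test(x[[1]], x[[2]])
      out[[v]] <- data.frame(variable = v, test = "welch_t",
                             statistic = unname(tt$statistic),
                             df = unname(tt$parameter),
                             p_value = tt$p.value)
    }
  }
  for (v in intersect(categorical, names(cohort))) {
    tab <- table(cohort[[v]], g)
    tab <- tab[rowSums(tab) > 0, , drop = FALSE]
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    if (any(ct$expected < 1))
      warning(sprintf("'%s': expected cell counts < 1; chi-square approximation unreliable", v))
    out[[v]] <- data.frame(variable = v, test = "pearson_chisq",
                           statistic = unname(ct$statistic),
                           df = unname(ct$parameter),
                           p_value = ct$p.value)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

## Quadrant factor with the inferior reference level used throughout.
quadrant_factor <- function(x)
  factor(x, levels = c("inferior", "nasal", "superior", "temporal"))

#' Fit the diagnosis-by-quadrant mixed-effects density model
#'
#' Restricted-maximum-likelihood linear mixed model of regional skeletonized
#' vessel density with fixed effects diagnosis, quadrant, their interaction,
#' ring (ONH only, until collapsed), age and sex, and random intercepts for
#' subject and eye nested within subject — the simplest structure under
#' which laterality, quadrant and ring are repeated measurements on a
#' subject. The inferior quadrant is the reference level. A singular
#' random-effects fit triggers a warning and a refit with the subject
#' intercept only.
#'
#' @param records density records (see [simulate_cohort_densities()] or
#'   [extract_region_densities()]): columns `subject`, `eye`, `diagnosis`,
#'   `age`, `sex`, `quadrant`, `density`, and `ring` for ONH data.
#' @param site `"onh"` or `"macula"`; macula models never include ring.
#' @param adjust include age and sex covariates (default TRUE).
#' @return A `lmerModLmerTest` fit (Satterthwaite-ready), with attributes
#'   `singular` and `site`.
#' @export
fit_density_model <- function(records, site = c("onh", "macula"), adjust = TRUE) {
  site <- match.arg(site)
  d <- as.data.frame(records)
  need <- c("subject", "eye", "diagnosis", "quadrant", "density")
  if (!all(need %in% names(d)))
    stop_octa("invalid-records", "records must contain %s", paste(need, collapse = ", "))
  if (length(unique(d$diagnosis)) != 2L)
    stop_octa("invalid-records", "both diagnosis groups must be present")
  d <- d[d$quadrant %in% c("inferior", "nasal", "superior", "temporal"), ]
  d$quadrant <- quadrant_factor(d$quadrant)
  d$diagnosis <- factor(d$diagnosis, levels = c("control", "ssd"))
  use_ring <- site == "onh" && "ring" %in% names(d) &&
    length(unique(d$ring)) > 1L
  rhs <- "diagnosis * quadrant"
  if (use_ring) rhs <- paste(rhs, "+ ring")
  if (adjust) rhs <- paste(rhs, "+ age + sex")
  form <- stats::as.formula(paste("density ~", rhs,
                                  "+ (1 | subject) + (1 | subject:eye)"))
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fit <- lmerTest::lmer(form, data = d, REML = TRUE, control = ctrl)
  singular <- lme4::isSingular(fit, tol = 1e-4)
  if (singular) {
    warning("singular random-effects fit; refitting with subject-only intercept")
    form2 <- stats::as.formula(paste("density ~", rhs, "+ (1 | subject)"))
    fit <- lmerTest::lmer(form2, data = d, REML = TRUE, control = ctrl)
  }
  attr(fit, "singular") <- singular
  attr(fit, "site") <- site
  attr(fit, "use_ring") <- use_ring
  fit
}

#' Collapse inner and outer rings when no ring effect is found
#'
#' Implements the ring-collapse rule for ONH data: if the fitted model's ring
#' fixed effect has p >= alpha, inner and outer densities are averaged within
#' subject x eye x quadrant into `ring = "collapsed"` records; otherwise the
#' records pass through unchanged.
#'
#' @param fit the full model from [fit_density_model()].
#' @param records the records the model was fitted to.
#' @param alpha significance level for the ring effect (default 0.05).
#' @return The (possibly collapsed) records, with attributes `ring_p` and
#'   `collapsed`.
#' @export
collapse_rings <- function(fit, records, alpha = 0.05) {
  d <- as.data.frame(records)
  if (!("ring" %in% names(d)) || length(unique(d$ring)) < 2L) {
    attr(d, "ring_p") <- NA_real_; attr(d, "collapsed") <- FALSE
    return(d)
  }
  ct <- stats::coef(summary(fit))
  ringrow <- grep("^ring", rownames(ct))
  ring_p <- if (length(ringrow)) ct[ringrow[1], "Pr(>|t|)"] else NA_real_
  if (!is.na(ring_p) && ring_p < alpha) {
    attr(d, "ring_p") <- ring_p; attr(d, "collapsed") <- FALSE
    return(d)
  }
  agg <- stats::aggregate(density ~ subject + eye + quadrant, data = d, FUN = mean)
  cov_cols <- setdiff(names(d), c("density", "ring", "region", "n_px", "rnfl"))
  covs <- unique(d[, setdiff(cov_cols, c("quadrant")), drop = FALSE])
  covs <- covs[!duplicated(covs[, c("subject", "eye")]), , drop = FALSE]
  out <- merge(agg, covs, by = c("subject", "eye"), sort = TRUE)
  out$ring <- "collapsed"
  if ("rnfl" %in% names(d)) {
    ragg <- stats::aggregate(rnfl ~ subject + eye + quadrant, data = d, FUN = mean)
    out <- merge(out, ragg, by = c("subject", "eye", "quadrant"), sort = TRUE)
  }
  attr(out, "ring_p") <- ring_p
  attr(out, "collapsed") <- TRUE
  out
}

#' Post hoc control-minus-SSD quadrant contrasts
#'
#' Estimates the control - SSD marginal density difference at each quadrant
#' from the fitted model's fixed effects and covariance (for treatment coding
#' with control reference this is `-(beta_ssd + beta_ssd:quadrant)`), with
#' Satterthwaite degrees of freedom by default, and adjusts the four raw
#' p-values with [bh_adjust()]. A positive estimate means lower density in
#' the SSD group.
#'
#' @param fit a fit from [fit_density_model()].
#' @param ddf `"satterthwaite"` (default) or `"z"` for a normal approximation.
#' @return data.frame with `quadrant`, `estimate`, `se`, `df`, `p_raw`,
#'   `p_adjusted`.
#' @export
quadrant_contrasts <- function(fit, ddf = c("satterthwaite", "z")) {
  ddf <- match.arg(ddf)
  fe <- lme4::fixef(fit)
  quads <- c("inferior", "nasal", "superior", "temporal")
  res <- lapply(quads, function(q) {
    L <- numeric(length(fe)); names(L) <- names(fe)
    if (!("diagnosisssd" %in% names(fe)))
      stop_octa("rank-deficient-contrast", "diagnosis effect missing from fit")
    L["diagnosisssd"] <- -1
    iterm <- paste0("diagnosisssd:quadrant", q)
    if (iterm %in% names(fe)) L[iterm] <- -1
    if (ddf == "satterthwaite") {
      ct <- lmerTest::contest1D(fit, L)
      data.frame(quadrant = q, estimate = ct$Estimate, se = ct$`Std. Error`,
                 df = ct$df, p_raw = ct$`Pr(>|t|)`)
    } else {
      est <- sum(L * fe)
      se <- sqrt(drop(t(L) %*% as.matrix(stats::vcov(fit)) %*% L))
      z <- est / se
      data.frame(quadrant = q, estimate = est, se = se, df = Inf,
                 p_raw = 2 * stats::pnorm(-abs(z)))
    }
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- bh_adjust(out$p_raw)
  out
}

#' Diagnosis-by-quadrant interaction table
#'
#' The fixed-effect interaction rows of the fitted model against the inferior
#' reference quadrant, with BH adjustment across the three interaction terms
#' — the mixed-model-by-quadrant result table shape.
#'
#' @param fit a fit from [fit_density_model()].
#' @return data.frame with `term`, `estimate`, `p_raw`, `p_adjusted`.
#' @export
interaction_table <- function(fit) {
  ct <- stats::coef(summary(fit))
  rows <- grep("^diagnosisssd:quadrant", rownames(ct))
  df <- data.frame(term = sub("diagnosisssd:quadrant", "diagnosis_x_", rownames(ct)[rows]),
                   estimate = ct[rows, "Estimate"],
                   p_raw = ct[rows, "Pr(>|t|)"])
  df$p_adjusted <- bh_adjust(df$p_raw)
  rownames(df) <- NULL
  df
}

#' Full per-site density analysis
#'
#' Fits the full mixed model, applies the ring-collapse rule (ONH), refits on
#' collapsed records when applicable, and computes the interaction table and
#' post hoc quadrant contrasts with BH adjustment.
#'
#' @inheritParams fit_density_model
#' @inheritParams quadrant_contrasts
#' @param collapse_alpha threshold for the ring-collapse decision.
#' @return list with `fit`, `records_used`, `ring_p`, `collapsed`,
#'   `interactions`, `contrasts`, `singular`.
#' @export
analyze_site <- function(records, site = c("onh", "macula"), adjust = TRUE,
                         ddf = c("satterthwaite", "z"), collapse_alpha = 0.05) {
  site <- match.arg(site); ddf <- match.arg(ddf)
  fit <- fit_density_model(records, site, adjust)
  recs <- as.data.frame(records)
  if (site == "onh") {
    recs2 <- collapse_rings(fit, recs, alpha = collapse_alpha)
    if (isTRUE(attr(recs2, "collapsed")))
      fit <- fit_density_model(recs2, site, adjust)
    ring_p <- attr(recs2, "ring_p"); collapsed <- attr(recs2, "collapsed")
    recs <- recs2
  } else {
    ring_p <- NA_real_; collapsed <- FALSE
  }
  list(fit = fit, records_used = recs, ring_p = ring_p, collapsed = collapsed,
       interactions = interaction_table(fit),
       contrasts = quadrant_contrasts(fit, ddf),
       singular = isTRUE(attr(fit, "singular")))
}

#' Age-stratified density analysis
#'
#' Refits the full per-site analysis separately in the younger (age <=
#' cutoff) and older (age > cutoff) strata, and additionally fits the pooled
#' temporal-quadrant model with a continuous diagnosis-by-age interaction.
#'
#' @inheritParams analyze_site
#' @param cutoff stratum boundary in years; a subject aged exactly `cutoff`
#'   falls in the younger stratum.
#' @return list with `young`, `old` (each an [analyze_site()] result),
#'   `cutoff`, and `age_interaction` (`estimate`, `p`) from the pooled
#'   temporal model.
#' @export
age_stratified_analysis <- function(records, site = c("onh", "macula"),
                                    cutoff = 30, adjust = TRUE,
                                    ddf = c("satterthwaite", "z")) {
  site <- match.arg(site); ddf <- match.arg(ddf)
  d <- as.data.frame(records)
  young <- d[d$age <= cutoff, ]
  old <- d[d$age > cutoff, ]
  for (s in list(young, old))
    if (length(unique(s$diagnosis)) < 2L)
      stop_octa("empty-stratum", "both diagnoses must appear in each age stratum")
  res_y <- analyze_site(young, site, adjust, ddf)
  res_o <- analyze_site(old, site, adjust, ddf)
  ## pooled continuous-age interaction on the temporal response
  tmp <- d[d$quadrant == "temporal", ]
  tmp$diagnosis <- factor(tmp$diagnosis, levels = c("control", "ssd"))
  rhs <- "diagnosis * age"
  if ("sex" %in% names(tmp)) rhs <- paste(rhs, "+ sex")
  if ("ring" %in% names(tmp) && length(unique(tmp$ring)) > 1L)
    rhs <- paste(rhs, "+ ring")
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = lme4::.makeCC(action = "ignore", tol = 1e-4))
  fit_t <- lmerTest::lmer(stats::as.formula(
    paste("density ~", rhs, "+ (1 | subject) + (1 | subject:eye)")),
    data = tmp, REML = TRUE, control = ctrl)
  ct <- stats::coef(summary(fit_t))
  row <- grep("diagnosisssd:age", rownames(ct))
  age_int <- if (length(row))
    list(estimate = unname(ct[row, "Estimate"]), p = unname(ct[row, "Pr(>|t|)"]))
  else list(estimate = NA_real_, p = NA_real_)
  list(young = res_y, old = res_o, cutoff = cutoff, age_interaction = age_int)
}

#' Linear regression of FAZ metrics on diagnosis
#'
#' Per-eye FAZ size and acircularity regressed on diagnosis (control
#' reference), optionally adjusted for age and sex (off by default). Group
#' summaries are reported as mean +- SD per eye.
#'
#' @param faz data.frame with one row per eye: `diagnosis`, `area_mm2`,
#'   `acircularity`, optionally `age`, `sex`.
#' @param adjust include age and sex covariates.
#' @return data.frame with one row per metric: group means/SDs, the SSD
#'   regression coefficient and its p-value.
#' @export
faz_group_regression <- function(faz, adjust = FALSE) {
  d <- as.data.frame(faz)
  d$diagnosis <- factor(d$diagnosis, levels = c("control", "ssd"))
  if (any(table(d$diagnosis) < 3L))
    stop_octa("invalid-cohort", "need at least 3 eyes per group")
  one <- function(metric) {
    y <- d[[metric]]
    if (stats::var(y) == 0) stop_octa("constant-response", "%s is constant", metric)
    rhs <- "diagnosis"
    if (adjust) rhs <- paste(rhs, "+ age + sex")
    fit <- stats::lm(stats::as.formula(paste(metric, "~", rhs)), data = d)
    ct <- stats::coef(summary(fit))
    m <- tapply(y, d$diagnosis, mean); s <- tapply(y, d$diagnosis, stats::sd)
    data.frame(metric = metric,
               control_mean = m[["control"]], control_sd = s[["control"]],
               ssd_mean = m[["ssd"]], ssd_sd = s[["ssd"]],
               coefficient = ct["diagnosisssd", "Estimate"],
               p_value = ct["diagnosisssd", "Pr(>|t|)"])
  }
  out <- rbind(one("area_mm2"), one("acircularity"))
  rownames(out) <- NULL
  out
}

#' Per-quadrant density-RNFL correlations
#'
#' Pearson correlation between ONH vessel density and RNFL thickness in each
#' quadrant, within diagnosis group and age stratum (younger = age < cutoff,
#' older = age >= cutoff for this sub-analysis). Cells with fewer than 3
#' complete pairs or zero variance are flagged with NA.
#'
#' @param records density records with an `rnfl` column.
#' @param cutoff age stratum boundary (years).
#' @return data.frame with `diagnosis`, `age_group`, `quadrant`, `n`, `r`,
#'   `p_value`.
#' @export
density_rnfl_correlation <- function(records, cutoff = 30) {
  d <- as.data.frame(records)
  stopifnot(all(c("density", "rnfl", "quadrant", "diagnosis", "age") %in% names(d)))
  d <- d[stats::complete.cases(d[, c("density", "rnfl")]), ]
  d$age_group <- ifelse(d$age < cutoff, "younger", "older")
  cells <- expand.grid(diagnosis = unique(d$diagnosis),
                       age_group = c("younger", "older"),
                       quadrant = c("superior", "nasal", "inferior", "temporal"),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- d[d$diagnosis == cells$diagnosis[i] &
               d$age_group == cells$age_group[i] &
               d$quadrant == cells$quadrant[i], ]
    n <- nrow(sub)
    if (n < 3L || stats::var(sub$density) == 0 || stats::var(sub$rnfl) == 0)
      return(cbind(cells[i, ], n = n, r = NA_real_, p_value = NA_real_))
    ct <- stats::cor.test(sub$density, sub$rnfl, method = "pearson")
    cbind(cells[i, ], n = n, r = unname(ct$estimate), p_value = ct$p.value)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
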