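# Normative w-score modelling: hand-checked OLS, the CN-mean-zero
# property, truncation and min/max normalization.

test_that("three collinear control points recover slope 0.1 and intercept -5", {
  rec <- data.frame(
    participant_id = c("a", "b", "c"),
    group = factor("CN", levels = tractopo:::GROUP_LEVELS),
    age_at_mri = c(60, 70, 80), stringsAsFactors = FALSE
  )
  tt <- data.frame(participant_id = c("a", "b", "c"), tract = "X--Y",
                   gfa = c(1, 2, 3), present = TRUE, stringsAsFactors = FALSE)
  models <- fit_normative(tt, rec, covariates = "age_at_mri")
  m <- models[["X--Y"]]
  expect_equal(unname(m$coefficients["age_at_mri"]), 0.1, tolerance = 1e-12)
  expect_equal(unname(m$coefficients["(Intercept)"]), -5, tolerance = 1e-10)
  expect_lt(m$residual_sd, 1e-8)
  expect_true(m$degenerate)
  expect_identical(m$n_train, 3L)
})

test_that("w is 0 at the prediction and +1 one residual-SD above it", {
  set.seed(2)
  rec <- data.frame(
    participant_id = sprintf("c%02d", 1:20),
    group = factor("CN", levels = tractopo:::GROUP_LEVELS),
    age_at_mri = seq(55, 74, 1),
    sex = factor(rep(c("F", "M"), 10), levels = c("F", "M")),
    stringsAsFactors = FALSE
  )
  tt <- data.frame(participant_id = rec$participant_id, tract = "A--B",
                   gfa = 0.5 + 0.002 * rec$age_at_mri + rnorm(20, 0, 0.03),
                   present = TRUE, stringsAsFactors = FALSE)
  models <- fit_normative(tt, rec, c("age_at_mri", "sex"))
  m <- models[["A--B"]]
  pred <- m$coefficients["(Intercept)"] + m$coefficients["age_at_mri"] * 60
  probe <- data.frame(participant_id = c("n1", "n2"), tract = "A--B",
                      gfa = c(pred, pred + m$residual_sd),
                      present = TRUE, stringsAsFactors = FALSE)
  rec2 <- rbind(rec, data.frame(participant_id = c("n1", "n2"),
                                group = factor("CN", levels = tractopo:::GROUP_LEVELS),
                                age_at_mri = 60,
                                sex = factor("F", levels = c("F", "M"))))
  w <- wscore_transform(probe, models, rec2)
  expect_equal(w$w, c(0, 1), tolerance = 1e-10)
})

test_that("CN training w-scores average to zero per target and w is monotone", {
  coh <- default_cohort()
  run <- default_run()
  w <- wscore_transform(run$qc$tract_table, run$wscore$gfa_models, run$records)
  cn <- run$records$participant_id[run$records$group == "CN"]
  means <- tapply(w$w[w$participant_id %in% cn], w$target_id[w$participant_id %in% cn],
                  mean, na.rm = TRUE)
  expect_lt(max(abs(means), na.rm = TRUE), 1e-10)
  # monotone in the raw observation at fixed covariates
  m <- run$wscore$gfa_models[[1]]
  rec1 <- run$records[1, , drop = FALSE]
  vals <- seq(0.2, 0.8, 0.1)
  probe <- data.frame(participant_id = rec1$participant_id, tract = m$target_id,
                      gfa = vals, present = TRUE, stringsAsFactors = FALSE)
  ww <- wscore_transform(probe, run$wscore$gfa_models, run$records)
  expect_true(all(diff(ww$w) > 0))
})

test_that("a -1 SD generated shift appears as mean w near -1 on the shifted tracts", {
  probe <- generate_cohort(cohort_config(n_per_phenotype = c(CN = 45L, lvPPA = 67L),
                                         region_count = 60L, effect_spec = list(),
                                         p_within = 0.2, seed = 21))
  tracts <- probe$truth$presence_rank[1:15]
  cfg <- cohort_config(n_per_phenotype = c(CN = 45L, lvPPA = 67L), region_count = 60L,
                       effect_spec = list(list(phenotype = "lvPPA",
                                               tracts = tracts, shift = -1)),
                       p_within = 0.2, seed = 21)
  coh <- generate_cohort(cfg)
  qc <- run_qc(coh$matrices, coh$records, coh$template,
               phenotype_set = c("CN", "lvPPA"))
  models <- fit_normative(qc$tract_table, coh$records)
  w <- wscore_transform(qc$tract_table, models, coh$records)
  pat <- coh$records$participant_id[coh$records$phenotype == "lvPPA"]
  sel <- w$participant_id %in% pat & w$target_id %in% tracts & is.finite(w$w)
  # per-tract group means; their spread gives an SE that respects the
  # shared residual-SD estimate within each tract
  d_t <- tapply(w$w[sel], w$target_id[sel], mean)
  se <- sd(d_t) / sqrt(length(d_t))
  expect_lt(abs(mean(d_t) - (-1)), 2 * se + 0.05)
})

test_that("truncation clamps to pooled percentiles and preserves constant tables", {
  rec <- stat_records()
  # order-statistic clamp at generous test percentiles
  vals <- matrix(rep(c(-5, -1, 0, 1, 5), 18), nrow = 90, ncol = 1,
                 dimnames = list(NULL, "A--B"))
  wt <- wtable_from_matrix(vals, rec)
  tr <- suppressWarnings(wscore_truncate(wt, lower_pct = 20, upper_pct = 80))
  b <- attr(tr, "truncation_bounds")
  expect_equal(unname(b), unname(quantile(vals, c(.2, .8))))
  expect_true(all(tr$w >= b["lower"] & tr$w <= b["upper"]))
  # all-identical input unchanged
  wt2 <- wtable_from_matrix(matrix(1, 90, 1, dimnames = list(NULL, "A--B")), rec)
  expect_equal(suppressWarnings(wscore_truncate(wt2))$w, rep(1, 90))
})

test_that("truncation of a large normal sample respects the empirical 99.9th percentile", {
  set.seed(4)
  n <- 10000
  rec <- data.frame(participant_id = sprintf("p%05d", 1:n), stringsAsFactors = FALSE)
  wt <- wtable_from_matrix(matrix(rnorm(n), n, 1, dimnames = list(NULL, "T--U")), rec)
  tr <- wscore_truncate(wt)
  srt <- sort(wt$w)
  expect_lte(max(tr$w), srt[ceiling(0.999 * n) + 1])
  expect_gte(min(tr$w), srt[floor(0.001 * n)])
})

test_that("min/max normalization attains 0 and 1 and zeros out missing entries", {
  rec <- data.frame(participant_id = c("a", "b", "c"), stringsAsFactors = FALSE)
  wt <- wtable_from_matrix(matrix(c(2, 4, 6), 3, 1, dimnames = list(NULL, "A--B")), rec)
  nm <- wscore_minmax(wt)
  expect_equal(sort(nm$w), c(0, 0.5, 1))
  wt$w[2] <- NA
  nm2 <- wscore_minmax(wt)
  expect_equal(nm2$w[nm2$participant_id == "b"], 0) # missing -> 0
  expect_equal(min(nm2$w), 0); expect_equal(max(nm2$w), 1)
  wt$w <- c(3, 3, 3)
  expect_error(wscore_minmax(wt), "degenerate")
})

test_that("single-sex control sets drop the target with a warning", {
  rec <- data.frame(
    participant_id = sprintf("c%d", 1:8),
    group = factor("CN", levels = tractopo:::GROUP_LEVELS),
    age_at_mri = 60:67, sex = factor("F", levels = c("F", "M")),
    stringsAsFactors = FALSE
  )
  tt <- data.frame(participant_id = rec$participant_id, tract = "A--B",
                   gfa = rnorm(8, 0.5, 0.05), present = TRUE, stringsAsFactors = FALSE)
  expect_warning(models <- fit_normative(tt, rec, c("age_at_mri", "sex")),
                 "dropped")
  expect_length(models, 0)
})
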