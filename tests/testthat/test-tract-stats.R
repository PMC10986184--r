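# Tractwise contrast engine: BH adjustment against the hand step-up
# computation, the F = t^2 identity, Tukey post-hoc against a direct
# studentized-range oracle, and effect recovery on generated data.

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 7)), rep(1, 7))
  # hand computation for an uneven set: q_i = min_{j>=i} m p_(j) / j
  p <- c(0.002, 0.01, 0.04, 0.04, 0.9)
  hand <- rev(cummin(rev(5 * p / seq_len(5))))
  expect_equal(bh_adjust(p), pmin(hand, 1))
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(numeric(0)), "empty")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("with two groups the factor F equals the squared pooled t statistic", {
  set.seed(8)
  rec <- stat_records(c(CN = 25L, `non-amnestic` = 20L))
  y <- rnorm(45) + 0.8 * (rec$group == "non-amnestic")
  wt <- wtable_from_matrix(matrix(y, 45, 1, dimnames = list(NULL, "A--B")), rec)
  res <- fit_tractwise(wt, rec, contrast_spec("group", covariates = character(0)),
                       posthoc = FALSE)
  tt <- t.test(y ~ rec$group == "non-amnestic", var.equal = TRUE)
  expect_equal(res$tracts$F, unname(tt$statistic)^2, tolerance = 1e-8)
  expect_equal(res$tracts$p, tt$p.value, tolerance = 1e-8)
})

test_that("zero-variance tracts are flagged, not reported as discoveries", {
  rec <- stat_records(c(CN = 10L, amnestic = 10L))
  wt <- wtable_from_matrix(matrix(1, 20, 2, dimnames = list(NULL, c("A--B", "C--D"))), rec)
  res <- fit_tractwise(wt, rec, contrast_spec("group", character(0)), posthoc = FALSE)
  expect_true(all(is.na(res$tracts$F)))
  expect_false(any(res$tracts$significant))
})

test_that("tracts with an entirely missing factor level are skipped", {
  rec <- stat_records(c(CN = 10L, amnestic = 10L))
  vals <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("A--B", "C--D")))
  wt <- wtable_from_matrix(vals, rec)
  wt$w[wt$target_id == "C--D" & rep(rec$group, 2)[wt$target_id == "C--D"] == "amnestic"] <- NA
  res <- fit_tractwise(wt, rec, contrast_spec("group", character(0)), posthoc = FALSE)
  expect_identical(res$skipped, "C--D")
  expect_identical(res$tracts$tract, "A--B")
})

test_that("Tukey p equals the plain t-test p for two levels", {
  set.seed(9)
  d <- data.frame(y = rnorm(30), g = factor(rep(c("a", "b"), 15)))
  fit <- lm(y ~ g, data = d)
  tab <- tukey_posthoc(fit, "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(tab$p_tukey, tt$p.value, tolerance = 1e-10)
})

test_that("Tukey adjustment matches a direct studentized-range evaluation", {
  # fixed 3 x 5 dataset
  d <- data.frame(
    y = c(5.1, 4.9, 5.4, 5.0, 5.2,
          5.8, 6.1, 5.7, 6.0, 5.9,
          5.3, 5.5, 5.2, 5.6, 5.4),
    g = factor(rep(c("g1", "g2", "g3"), each = 5))
  )
  fit <- lm(y ~ g, data = d)
  tab <- tukey_posthoc(fit, "g")
  means <- tapply(d$y, d$g, mean)
  mse <- sum(resid(fit)^2) / fit$df.residual
  se <- sqrt(mse * (1 / 5 + 1 / 5))
  for (pair in list(c("g1", "g2"), c("g1", "g3"), c("g2", "g3"))) {
    tstat <- (means[pair[1]] - means[pair[2]]) / se
    p_oracle <- ptukey(abs(tstat) * sqrt(2), nmeans = 3, df = fit$df.residual,
                       lower.tail = FALSE)
    row <- tab[tab$contrast == paste(pair, collapse = " - "), ]
    expect_equal(row$t_ratio, unname(tstat), tolerance = 1e-10)
    expect_equal(row$p_tukey, unname(p_oracle), tolerance = 1e-10)
  }
})

test_that("groups with exactly identical values give Tukey p of 1", {
  set.seed(10)
  base <- rnorm(100)
  d <- data.frame(y = rep(base, 3), g = factor(rep(c("a", "b", "c"), each = 100)))
  tab <- tukey_posthoc(lm(y ~ g, data = d), "g")
  expect_true(all(tab$p_tukey > 1 - 1e-10))
  expect_true(all(abs(tab$estimate) < 1e-12))
})

test_that("an injected non-amnestic deficit is detected with the correct sign", {
  # Table-2-sized groups; -1 SD effect on 20 tracts among 200
  set.seed(11)
  rec <- stat_records(c(CN = 45L, amnestic = 41L, `non-amnestic` = 67L))
  n <- nrow(rec)
  vals <- matrix(rnorm(n * 200), n, 200,
                 dimnames = list(NULL, tract_id(sprintf("L_%03d", 1:200),
                                                sprintf("R_%03d", 1:200))))
  hit <- colnames(vals)[1:20]
  vals[rec$group == "non-amnestic", hit] <- vals[rec$group == "non-amnestic", hit] - 1
  wt <- wtable_from_matrix(vals, rec)
  res <- fit_tractwise(wt, rec, contrast_spec("group", "mmse"))
  sig <- res$tracts$tract[res$tracts$significant]
  expect_gte(sum(hit %in% sig), 16) # >= 80% detected
  # Tukey contrast sign: CN minus non-amnestic positive on injected tracts
  ph <- res$posthoc[res$posthoc$tract %in% hit &
                      res$posthoc$contrast == "CN - (non-amnestic)", ]
  expect_true(all(ph$estimate > 0))
  # false positives controlled
  expect_lte(sum(!sig %in% hit), 5)
})

test_that("global microstructure contrasts recover the generating group shift", {
  coh <- default_cohort()
  res <- global_micro_contrast(coh$micro, impute_missing_meta(coh$records))
  expect_setequal(res$tracts$tract, c("mean_fa", "mean_md", "mean_iso"))
  expect_true(all(res$tracts$q >= res$tracts$p))
  fa <- res$tracts[res$tracts$tract == "mean_fa", ]
  expect_true(fa$significant)
  ph <- res$posthoc[res$posthoc$tract == "mean_fa" &
                      res$posthoc$contrast == "amnestic - (non-amnestic)", ]
  delta <- coh$config$micro_means$fa[["amnestic"]] - coh$config$micro_means$fa[["non-amnestic"]]
  expect_lt(abs(ph$estimate - delta), 2 * ph$SE)
  expect_error(global_micro_contrast(coh$micro[, 1:3], coh$records), "missing metric")
})

test_that("a global-null simulation keeps the family-wise discovery rate near alpha", {
  # 100 replicates x 100 tracts, groups 15/15/20: any-discovery rate <= ~alpha
  set.seed(12)
  rec <- stat_records(c(CN = 15L, amnestic = 15L, `non-amnestic` = 20L))
  n <- nrow(rec)
  ids <- tract_id(sprintf("L_%03d", 1:100), sprintf("R_%03d", 1:100))
  hits <- vapply(1:100, function(rep) {
    vals <- matrix(rnorm(n * 100), n, 100, dimnames = list(NULL, ids))
    res <- fit_tractwise(wtable_from_matrix(vals, rec), rec,
                         contrast_spec("group", character(0)), posthoc = FALSE)
    any(res$tracts$significant)
  }, logical(1))
  expect_lte(mean(hits), 0.05 + 2 * sqrt(0.05 * 0.95 / 100))
})
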