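# Synthetic cohort generator: determinism, structural invariants,
# calibration against its own generating parameters, and metadata
# imputation rules.

test_that("identical seeds reproduce the cohort exactly; different seeds differ", {
  cfg <- cohort_config(
    n_per_phenotype = c(CN = 10L, aAD = 8L, lvPPA = 6L, PCA = 4L, bvAD = 3L, CBS = 3L),
    region_count = 30L, seed = 42, effect_spec = list()
  )
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  cfg2 <- cfg; cfg2$seed <- 43L
  c2 <- generate_cohort(cfg2)
  expect_false(identical(a$matrices, c2$matrices))
})

test_that("group is a pure function of phenotype and metadata invariants hold", {
  coh <- default_cohort()
  r <- coh$records
  expect_identical(r$group, phenotype_to_group(r$phenotype))
  expect_true(all(is.na(r$disease_duration[r$phenotype == "CN"])))
  expect_true(all(r$mmse >= 0 & r$mmse <= 30, na.rm = TRUE))
  expect_true(all(r$icv > 0))
  expect_identical(unname(table(r$phenotype)[tractopo:::PHENOTYPE_LEVELS]),
                   table(factor(c(rep("CN", 45), rep("aAD", 41), rep("lvPPA", 32),
                                  rep("PCA", 17), rep("bvAD", 10), rep("CBS", 8)),
                                levels = tractopo:::PHENOTYPE_LEVELS)) |> unname())
})

test_that("generated matrices are symmetric with masked diagonal and GFA in [0,1]", {
  coh <- default_cohort()
  for (id in sample(names(coh$matrices), 10)) {
    expect_true(validate_connectivity_matrix(coh$matrices[[id]], id))
  }
  expect_true(all(is.na(diag(coh$matrices[[1]]))))
})

test_that("zero-noise, zero-effect cohort reproduces the control baseline exactly", {
  cfg <- cohort_config(
    n_per_phenotype = c(CN = 5L, aAD = 5L), region_count = 20L,
    effect_spec = list(), noise_sd = 0, age_effect = 0, sex_effect = 0,
    low_coverage_regions = 0L, seed = 3
  )
  coh <- generate_cohort(cfg)
  base <- coh$truth$baseline
  for (id in names(coh$matrices)) {
    long <- tractopo:::matrix_to_long(coh$matrices[[id]])
    expect_equal(long$gfa, unname(base[long$tract]))
  }
})

test_that("negative noise_sd is rejected, as are bad effect and region settings", {
  expect_error(cohort_config(noise_sd = -0.1), "non-negative")
  expect_error(cohort_config(region_count = 3), ">= 4")
  expect_error(cohort_config(effect_spec = list(list(phenotype = "XXX", n = 5L, shift = -1))),
               "invalid phenotype")
  expect_error(cohort_config(effect_spec = list(list(phenotype = "PCA", shift = -1))),
               "selector")
})

test_that("tract presence frequencies are calibrated to presence_mean", {
  coh <- default_cohort() # 153 participants, > 400 tracts
  pres <- sapply(coh$matrices, function(m) {
    reg <- tractopo:::tract_regions(coh$truth$universe)
    !is.na(m[cbind(reg$region_a, reg$region_b)])
  })
  ok_tracts <- !coh$truth$universe %in% coh$truth$suppressed_tracts
  tract_presence <- rowMeans(pres)[ok_tracts]
  expect_gt(length(tract_presence), 400)
  expect_lt(abs(mean(tract_presence) - coh$config$presence_mean), 0.05)
})

test_that("configured effect shifts are realized in the generated group means", {
  # -1 control-SD shift on a named 10-tract set, large groups
  base_cfg <- cohort_config(n_per_phenotype = c(CN = 200L, lvPPA = 200L),
                            region_count = 40L, effect_spec = list(),
                            p_within = 0.25, seed = 5)
  probe <- generate_cohort(base_cfg)
  tracts <- probe$truth$presence_rank[1:10]
  cfg <- cohort_config(n_per_phenotype = c(CN = 200L, lvPPA = 200L),
                       region_count = 40L,
                       effect_spec = list(list(phenotype = "lvPPA",
                                               tracts = tracts, shift = -1)),
                       p_within = 0.25, seed = 5)
  coh <- generate_cohort(cfg)
  r <- coh$records
  reg <- tractopo:::tract_regions(tracts)
  vals <- sapply(coh$matrices, function(m) m[cbind(reg$region_a, reg$region_b)])
  cn_mean <- rowMeans(vals[, r$phenotype == "CN"], na.rm = TRUE)
  pa_mean <- rowMeans(vals[, r$phenotype == "lvPPA"], na.rm = TRUE)
  # per-tract difference in control-SD units
  d <- (pa_mean - cn_mean) / cfg$noise_sd
  expect_true(all(abs(d - (-1)) < 0.5))
  expect_lt(abs(mean(d) - (-1)), 0.1)
})

test_that("grey-matter volumes are positive and coupled to incident-tract GFA", {
  coh <- default_cohort()
  expect_true(all(coh$volumes$gm_volume > 0))
  expect_identical(nrow(coh$volumes), 153L * 152L)
})

test_that("template is nonzero exactly on the emittable tracts", {
  coh <- default_cohort()
  tm <- coh$template
  ut <- upper.tri(tm)
  labs <- rownames(tm)
  idx <- which(ut & tm > 0, arr.ind = TRUE)
  nonzero <- tract_id(labs[idx[, 1]], labs[idx[, 2]])
  expect_setequal(nonzero, coh$truth$universe)
})

test_that("forced islands appear in exactly the configured scans", {
  cfg <- cohort_config(n_per_phenotype = c(CN = 60L, aAD = 50L, lvPPA = 43L),
                       region_count = 60L, effect_spec = list(),
                       island_spec = c(L_010 = 40L), seed = 9)
  coh <- generate_cohort(cfg)
  freq <- detect_islands(coh$matrices)
  forced <- coh$truth$forced_islands[["L_010"]]
  expect_length(forced, 40L)
  # every forced participant really has the region isolated
  iso <- vapply(coh$matrices[forced], function(m) all(is.na(m["L_010", ])), logical(1))
  expect_true(all(iso))
  expect_gte(freq[["L_010"]], 40 / 153)
})

test_that("MMSE and duration imputation follows the stratum-mean rules", {
  rec <- data.frame(
    participant_id = sprintf("s%d", 1:6),
    phenotype = factor(c("CN", "CN", "CN", "aAD", "lvPPA", "PCA"),
                       levels = tractopo:::PHENOTYPE_LEVELS),
    mmse = c(29L, 30L, NA, 22L, NA, 24L),
    disease_duration = c(NA, NA, NA, 2, 4, NA),
    stringsAsFactors = FALSE
  )
  rec$group <- phenotype_to_group(rec$phenotype)
  out <- impute_missing_meta(rec)
  expect_equal(out$mmse[3], 29.5)                    # mean of remaining CN
  expect_equal(out$mmse[5], 23)                      # mean over all patients
  expect_equal(out$disease_duration[6], 3)           # mean of other patients
  expect_true(all(is.na(out$disease_duration[1:3]))) # CN stays missing
  expect_identical(which(out$mmse_imputed), c(3L, 5L))
  expect_identical(which(out$duration_imputed), 6L)
})

test_that("imputation is the identity on complete data and fails on empty strata", {
  rec <- data.frame(
    participant_id = c("a", "b"), phenotype = factor(c("CN", "aAD"),
      levels = tractopo:::PHENOTYPE_LEVELS),
    mmse = c(30L, 20L), disease_duration = c(NA, 3),
    stringsAsFactors = FALSE
  )
  rec$group <- phenotype_to_group(rec$phenotype)
  out <- impute_missing_meta(rec)
  expect_equal(out$mmse, rec$mmse)
  expect_false(any(out$mmse_imputed))
  rec2 <- rec; rec2$mmse <- c(NA_integer_, 20L)
  rec2b <- rec; rec2b$mmse <- c(30L, NA_integer_)
  expect_error(impute_missing_meta(rec2), "all CN MMSE")
  expect_error(impute_missing_meta(rec2b), "all patient MMSE")
})
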