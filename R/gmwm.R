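# Grey-matter / white-matter coupling: regional mean WM w-scores modelled
# on GM volume w-scores with a moderator (group, phenotype, or APOE e4
# copy number) and a random intercept per participant.

#' Mean white-matter w-score per region
#'
#' For every participant and region, the mean w-score over all retained,
#' non-missing tracts incident to the region; each tract contributes to
#' both of its endpoint regions. Regions with zero usable tracts for a
#' participant are omitted.
#'
#' @param wtable `wscore_table` of tract w-scores (unnormalized).
#' @return Data frame `participant_id`, `region_label`, `mean_wm_w`,
#'   `n_tracts_used`.
#' @export
summarize_region_wm <- function(wtable) {
  ok <- is.finite(wtable$w)
  reg <- tract_regions(wtable$target_id[ok])
  long <- data.frame(
    participant_id = rep(wtable$participant_id[ok], 2L),
    region_label = c(reg$region_a, reg$region_b),
    w = rep(wtable$w[ok], 2L),
    stringsAsFactors = FALSE
  )
  key <- paste(long$participant_id, long$region_label, sep = "\r")
  sums <- rowsum(cbind(w = long$w, n = 1), key)
  parts <- strsplit(rownames(sums), "\r", fixed = TRUE)
  out <- data.frame(
    participant_id = vapply(parts, `[[`, character(1), 1L),
    region_label = vapply(parts, `[[`, character(1), 2L),
    mean_wm_w = sums[, "w"] / sums[, "n"],
    n_tracts_used = as.integer(sums[, "n"]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$participant_id, out$region_label), ]
  rownames(out) <- NULL
  out
}

#' Mixed-effects model of GM-WM coupling
#'
#' Fits `mean_wm_w ~ moderator * gm_w + (1 | participant)` by REML with
#' Satterthwaite denominator degrees of freedom for the ANOVA F tests.
#' The moderator is `group`, `phenotype`, or `apoe_e4_count` (treated as a
#' factor with levels 0/1/2). For the APOE moderator, two additional
#' models are fitted to separate genotype from diagnostic group: one with
#' additive effects of group, APOE copy number and GM w-score, and one
#' with all two- and three-way interactions.
#'
#' @param region_wm Output of [summarize_region_wm()].
#' @param gm_wtable `wscore_table` of regional GM volume w-scores.
#' @param records Participant metadata.
#' @param moderator `"group"`, `"phenotype"`, or `"apoe_e4_count"`.
#' @return Object of class `gmwm_result`: `fixed` (coefficient table),
#'   `anova` (F table with Satterthwaite df), `var_explained_fixed`
#'   (fraction of outcome variance explained by the fixed-effect fit,
#'   computed as the squared correlation between fixed-effect fitted
#'   values and observations), `ranef_variance`, `n_obs`, `model`, and for
#'   the APOE moderator `group_adjusted` / `full_factorial` companions.
#' @export
fit_gmwm <- function(region_wm, gm_wtable, records,
                     moderator = c("group", "phenotype", "apoe_e4_count")) {
  moderator <- match.arg(moderator)
  d <- merge(region_wm,
             data.frame(participant_id = gm_wtable$participant_id,
                        region_label = gm_wtable$target_id,
                        gm_w = gm_wtable$w, stringsAsFactors = FALSE),
             by = c("participant_id", "region_label"))
  rec_cols <- c("participant_id", "group", "phenotype", "apoe_e4_count")
  d <- merge(d, records[, intersect(rec_cols, names(records))], by = "participant_id")
  d$.mod <- if (moderator == "apoe_e4_count") {
    factor(d$apoe_e4_count, levels = 0:2)
  } else droplevels(as.factor(d[[moderator]]))
  d <- d[stats::complete.cases(d[, c("mean_wm_w", "gm_w", ".mod")]), , drop = FALSE]
  if (nlevels(droplevels(d$.mod)) < 2L) stop("moderator needs >= 2 levels with data")
  d$.mod <- droplevels(d$.mod)

  out <- fit_gmwm_one(mean_wm_w ~ .mod * gm_w + (1 | participant_id), d)
  out$moderator <- moderator
  if (moderator == "apoe_e4_count" && "group" %in% names(d)) {
    out$group_adjusted <- fit_gmwm_one(
      mean_wm_w ~ group + .mod + gm_w + (1 | participant_id), d)
    out$full_factorial <- fit_gmwm_one(
      mean_wm_w ~ group * .mod * gm_w + (1 | participant_id), d)
  }
  class(out) <- "gmwm_result"
  out
}

# Fit one random-intercept model and extract the reported tables.
fit_gmwm_one <- function(formula, d) {
  m <- lmerTest::lmer(formula, data = d, REML = TRUE,
                      control = lme4::lmerControl(check.conv.singular = "ignore"))
  cf <- as.data.frame(coef(summary(m)))
  fixed <- data.frame(term = rownames(cf), coefficient = cf[, "Estimate"],
                      SE = cf[, "Std. Error"], df = cf[, "df"],
                      t = cf[, "t value"], p = cf[, "Pr(>|t|)"],
                      stringsAsFactors = FALSE)
  rownames(fixed) <- NULL
  an <- as.data.frame(anova(m, type = 3, ddf = "Satterthwaite"))
  anova_tab <- data.frame(term = rownames(an), F = an[, "F value"],
                          df1 = an[, "NumDF"], df2 = an[, "DenDF"],
                          p = an[, "Pr(>F)"], stringsAsFactors = FALSE)
  rownames(anova_tab) <- NULL
  X <- stats::model.matrix(m)
  fitted_fixed <- drop(X %*% lme4::fixef(m))
  y <- stats::model.response(stats::model.frame(m))
  vc <- as.data.frame(lme4::VarCorr(m))
  list(
    fixed = fixed, anova = anova_tab,
    var_explained_fixed = cor(fitted_fixed, y)^2,
    ranef_variance = vc$vcov[vc$grp == "participant_id"][1L],
    n_obs = nrow(d), model = m
  )
}

#' Simulate data from the GM-WM coupling model itself
#'
#' Generates region-level data directly from the random-intercept model
#' that [fit_gmwm()] fits: `wm = intercept_g + u_i + slope_g * gm + e`,
#' with `gm ~ N(0, 1)` regional GM w-scores, `u_i ~ N(0, ranef_sd^2)` per
#' participant, and `e ~ N(0, noise_sd^2)`. Used for parameter-recovery
#' checks of the mixed-model machinery with known ground truth.
#'
#' @param n_per_group Named integer vector of participants per group.
#' @param n_regions Regions per participant.
#' @param intercepts,slopes Named numeric vectors per group.
#' @param ranef_sd SD of the participant random intercept (0 allowed).
#' @param noise_sd Residual SD.
#' @param seed Integer seed.
#' @return List with `region_wm`, `gm_wtable`, `records` ready for
#'   [fit_gmwm()], plus the generating `truth`.
#' @export
simulate_gmwm_data <- function(n_per_group = c(CN = 45L, amnestic = 41L, `non-amnestic` = 67L),
                               n_regions = 148L,
                               intercepts = c(CN = 0, amnestic = -0.12, `non-amnestic` = -0.24),
                               slopes = c(CN = 0.03, amnestic = 0.08, `non-amnestic` = 0.08),
                               ranef_sd = 0.3, noise_sd = 1, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  groups <- rep(names(n_per_group), times = n_per_group)
  n_sub <- length(groups)
  ids <- sprintf("sim-%03d", seq_len(n_sub))
  regions <- default_region_labels(n_regions)
  u <- rnorm(n_sub, 0, ranef_sd)
  rows <- lapply(seq_len(n_sub), function(i) {
    gm <- rnorm(n_regions)
    wm <- intercepts[groups[i]] + u[i] + slopes[groups[i]] * gm +
      rnorm(n_regions, 0, noise_sd)
    data.frame(participant_id = ids[i], region_label = regions,
               mean_wm_w = wm, n_tracts_used = 1L, gm_w = gm,
               stringsAsFactors = FALSE)
  })
  long <- do.call(rbind, rows)
  gm_wtable <- structure(
    data.frame(participant_id = long$participant_id,
               target_id = long$region_label, w = long$gm_w,
               stringsAsFactors = FALSE),
    class = c("wscore_table", "data.frame"), modality = "volume"
  )
  records <- data.frame(
    participant_id = ids,
    phenotype = factor(ifelse(groups == "CN", "CN",
                              ifelse(groups == "amnestic", "aAD", "lvPPA")),
                       levels = PHENOTYPE_LEVELS),
    group = factor(groups, levels = GROUP_LEVELS),
    stringsAsFactors = FALSE
  )
  list(
    region_wm = long[, c("participant_id", "region_label", "mean_wm_w", "n_tracts_used")],
    gm_wtable = gm_wtable, records = records,
    truth = list(intercepts = intercepts, slopes = slopes,
                 ranef_sd = ranef_sd, noise_sd = noise_sd, ranef = u)
  )
}
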