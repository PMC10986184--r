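# Mass-univariate tractwise contrasts: per tract, an OLS of the w-score on
# a factor of interest (group or phenotype) plus covariates; a Type II
# ANOVA F for the factor (factor adjusted for covariates and vice versa);
# Benjamini-Hochberg across tracts; Tukey-adjusted pairwise contrasts at
# covariate-adjusted (estimated marginal) means for significant tracts.

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with enforced monotonicity, capped at 1; ties are
#' handled by stable sort so output ordering is deterministic.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Numeric vector of q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Contrast specification for tractwise and generic linear contrasts
#'
#' @param factor Factor of interest: `"group"`, `"phenotype"`, or the name
#'   of any factor column in the records.
#' @param covariates Covariate column names (default `"mmse"`, adjusting
#'   for within-group variation in disease progression).
#' @param fdr_alpha FDR threshold for the omnibus ANOVA (default 0.05).
#' @param posthoc_alpha Tukey-adjusted threshold for pairwise tests.
#' @return Object of class `contrast_spec`.
#' @export
contrast_spec <- function(factor = "group", covariates = "mmse",
                          fdr_alpha = 0.05, posthoc_alpha = 0.05) {
  stopifnot(fdr_alpha > 0, fdr_alpha < 1, posthoc_alpha > 0, posthoc_alpha < 1)
  structure(list(factor = factor, covariates = covariates,
                 fdr_alpha = fdr_alpha, posthoc_alpha = posthoc_alpha),
            class = "contrast_spec")
}

# Type II F statistic for `fac` from RSS of full vs covariate-only fits.
# X_cov: covariate design incl. intercept; F_lev: 0/1 factor dummies.
type2_factor_F <- function(y, X_cov, F_lev) {
  X_full <- cbind(X_cov, F_lev)
  q_full <- qr(X_full)
  q_red <- qr(X_cov)
  rss_full <- sum(qr.resid(q_full, y)^2)
  rss_red <- sum(qr.resid(q_red, y)^2)
  df1 <- q_full$rank - q_red$rank
  df2 <- length(y) - q_full$rank
  if (df1 < 1L || df2 < 1L) return(c(F = NA, df1 = df1, df2 = df2, p = NA))
  ms_res <- rss_full / df2
  if (ms_res <= .Machine$double.eps * max(1, rss_red)) {
    # Degenerate: zero residual variance
    return(c(F = NA, df1 = df1, df2 = df2, p = NA))
  }
  Fv <- ((rss_red - rss_full) / df1) / ms_res
  c(F = Fv, df1 = df1, df2 = df2, p = pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Mass-univariate tractwise contrasts
#'
#' For every tract: rows with missing w-scores are excluded tract-by-tract;
#' an OLS of w on the factor of interest plus covariates is fitted; the
#' factor's Type II ANOVA F and p are computed; p-values are
#' Benjamini-Hochberg adjusted across all tested tracts; and for
#' FDR-significant tracts, Tukey-adjusted pairwise contrasts of estimated
#' marginal means are reported. Tracts in which any factor level is
#' entirely missing are skipped and listed in `skipped`.
#'
#' @param wtable A `wscore_table` of tract w-scores.
#' @param records Participant metadata (factor + covariate columns).
#' @param spec A [contrast_spec()].
#' @param posthoc Compute Tukey post-hoc tables for significant tracts.
#' @return Object of class `tract_stat_result`: `tracts` (per-tract data
#'   frame with `n_used`, `F`, `df1`, `df2`, `p`, `q`, `significant`),
#'   `posthoc` (pairwise contrast data frame), `skipped`, `spec`.
#' @export
fit_tractwise <- function(wtable, records, spec = contrast_spec(),
                          posthoc = TRUE) {
  fac_all <- droplevels(as.factor(records[[spec$factor]]))
  if (nlevels(fac_all) < 2L) stop("factor of interest needs >= 2 levels")
  rec_idx <- match(wtable$participant_id, records$participant_id)
  if (anyNA(rec_idx)) stop("records missing for some participants")
  covs <- spec$covariates
  cov_mat <- if (length(covs)) {
    do.call(cbind, lapply(covs, function(cv) {
      v <- records[[cv]]
      if (is.null(v)) stop("covariate absent from records: ", cv)
      if (cv == "sex") as.numeric(records$sex == "M") else as.numeric(v)
    }))
  } else NULL

  w <- wtable$w
  idx_list <- split(seq_along(w), wtable$target_id)
  tids <- sort(names(idx_list))
  res_rows <- vector("list", length(tids))
  skipped <- character(0)
  per_tract <- list()
  for (k in seq_along(tids)) {
    sel <- idx_list[[tids[k]]]
    sel <- sel[is.finite(w[sel])]
    ridx <- rec_idx[sel]
    ok <- if (is.null(cov_mat)) rep(TRUE, length(ridx)) else
      stats::complete.cases(cov_mat[ridx, , drop = FALSE])
    sel <- sel[ok]; ridx <- ridx[ok]
    fac <- factor(fac_all[ridx], levels = levels(fac_all))
    if (any(table(fac) == 0L)) { skipped <- c(skipped, tids[k]); next }
    X_cov <- if (is.null(cov_mat)) matrix(1, length(sel), 1L) else
      cbind(1, cov_mat[ridx, , drop = FALSE])
    F_lev <- model.matrix(~fac)[, -1L, drop = FALSE]
    st <- type2_factor_F(w[sel], X_cov, F_lev)
    res_rows[[k]] <- data.frame(
      tract = tids[k], n_used = length(sel), F = st[["F"]],
      df1 = st[["df1"]], df2 = st[["df2"]], p = st[["p"]],
      stringsAsFactors = FALSE
    )
    per_tract[[tids[k]]] <- list(sel = sel, ridx = ridx)
  }
  tracts <- do.call(rbind, res_rows[!vapply(res_rows, is.null, logical(1))])
  if (is.null(tracts) || !nrow(tracts)) stop("no testable tracts")
  tracts$q <- NA_real_
  testable <- is.finite(tracts$p)
  if (any(testable)) tracts$q[testable] <- bh_adjust(tracts$p[testable])
  tracts$significant <- !is.na(tracts$q) & tracts$q < spec$fdr_alpha
  rownames(tracts) <- NULL

  ph <- NULL
  if (posthoc && any(tracts$significant)) {
    ph_rows <- lapply(tracts$tract[tracts$significant], function(tid) {
      info <- per_tract[[tid]]
      d <- data.frame(w = w[info$sel],
                      .fac = factor(fac_all[info$ridx], levels = levels(fac_all)))
      for (j in seq_along(covs)) {
        d[[covs[j]]] <- if (covs[j] == "sex") as.numeric(records$sex == "M")[info$ridx]
          else as.numeric(records[[covs[j]]])[info$ridx]
      }
      fml <- stats::as.formula(paste("w ~ .fac", if (length(covs))
        paste("+", paste(covs, collapse = " + ")) else ""))
      fit <- lm(fml, data = d)
      tab <- tukey_posthoc(fit, ".fac")
      cbind(tract = tid, tab)
    })
    ph <- do.call(rbind, ph_rows)
    rownames(ph) <- NULL
  }
  structure(list(tracts = tracts, posthoc = ph, skipped = skipped, spec = spec),
            class = "tract_stat_result")
}

#' Tukey-adjusted pairwise contrasts of estimated marginal means
#'
#' All pairwise differences between factor levels at the covariate means,
#' with p-values adjusted via the studentized-range distribution using the
#' model's residual degrees of freedom.
#'
#' @param fit An `lm` fit containing the factor.
#' @param factor_name Name of the factor term in the model.
#' @return Data frame with `contrast`, `estimate`, `SE`, `df`, `t_ratio`,
#'   `p_tukey`.
#' @export
tukey_posthoc <- function(fit, factor_name) {
  emm <- emmeans::emmeans(fit, specs = factor_name)
  tab <- as.data.frame(emmeans::contrast(emm, method = "pairwise", adjust = "tukey"))
  data.frame(contrast = as.character(tab$contrast), estimate = tab$estimate,
             SE = tab$SE, df = tab$df, t_ratio = tab$t.ratio,
             p_tukey = tab$p.value, stringsAsFactors = FALSE)
}

#' Group contrasts of global white-matter microstructure
#'
#' Runs the tractwise contrast engine on the three global metrics (mean
#' FA, MD, isotropic diffusion) with covariates age, sex and MMSE;
#' Benjamini-Hochberg adjustment is applied across the three metrics, and
#' Tukey post-hoc tests are reported for significant metrics.
#'
#' @param micro Data frame `participant_id`, `mean_fa`, `mean_md`,
#'   `mean_iso`.
#' @param records Participant metadata.
#' @param factor Factor of interest (default `"group"`).
#' @param covariates Covariates (default age, sex, MMSE).
#' @param fdr_alpha FDR threshold across the three metrics.
#' @return `tract_stat_result` whose `tracts` table has one row per metric.
#' @export
global_micro_contrast <- function(micro, records, factor = "group",
                                  covariates = c("age_at_mri", "sex", "mmse"),
                                  fdr_alpha = 0.05) {
  metrics <- c("mean_fa", "mean_md", "mean_iso")
  miss <- setdiff(metrics, names(micro))
  if (length(miss)) stop("missing metric column(s): ", paste(miss, collapse = ", "))
  long <- data.frame(
    participant_id = rep(micro$participant_id, times = 3L),
    target_id = rep(metrics, each = nrow(micro)),
    w = c(micro$mean_fa, micro$mean_md, micro$mean_iso),
    stringsAsFactors = FALSE
  )
  class(long) <- c("wscore_table", "data.frame")
  fit_tractwise(long, records,
                contrast_spec(factor = factor, covariates = covariates,
                              fdr_alpha = fdr_alpha))
}
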