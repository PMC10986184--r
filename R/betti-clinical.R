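# Clinical relevance of individual topological metrics: regressions of
# global cognition (MMSE, all participants) and disease duration
# (patients only) on each Betti metric plus age and sex; and simple
# Pearson correlations with global WM microstructure.

#' Regress a clinical outcome on each Betti metric
#'
#' One ordinary least-squares model per metric (`betti0`, `betti1`,
#' `ratio`): `outcome ~ metric + age_at_mri + sex`, at alpha = 0.05
#' uncorrected. MMSE models use all participants; disease-duration models
#' are restricted to patients (the cognitively normal group has no
#' disease duration).
#'
#' @param metrics Data frame from [subnetwork_betti_at()] (columns
#'   `participant_id`, `betti0`, `betti1`, `ratio`).
#' @param records Participant metadata.
#' @param outcome `"mmse"` or `"duration"`.
#' @return Long coefficient data frame: `metric`, `term`, `coefficient`,
#'   `SE`, `t`, `p`, `n`; singular fits are reported with `NA` statistics
#'   and `singular = TRUE`.
#' @export
regress_clinical <- function(metrics, records, outcome = c("mmse", "duration")) {
  outcome <- match.arg(outcome)
  d <- merge(metrics, records, by = "participant_id")
  d$.y <- if (outcome == "mmse") d$mmse else d$disease_duration
  if (outcome == "duration") d <- d[d$group != "CN", , drop = FALSE]
  rows <- lapply(c("betti0", "betti1", "ratio"), function(mname) {
    dd <- d[stats::complete.cases(d[, c(".y", mname, "age_at_mri", "sex")]), , drop = FALSE]
    if (nrow(dd) < 5L) stop("fewer than 5 complete cases for ", mname)
    dd$.m <- dd[[mname]]
    fit <- lm(.y ~ .m + age_at_mri + sex, data = dd)
    cf <- coef(summary(fit))
    singular <- !".m" %in% rownames(cf)
    terms <- rownames(cf)
    terms[terms == ".m"] <- mname
    out <- data.frame(metric = mname, term = terms,
                      coefficient = cf[, 1L], SE = cf[, 2L],
                      t = cf[, 3L], p = cf[, 4L], n = nrow(dd),
                      singular = singular, stringsAsFactors = FALSE)
    if (singular) warning("singular design for metric ", mname)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "outcome") <- outcome
  out
}

#' Pearson correlations of Betti metrics with global microstructure
#'
#' Simple two-sided Pearson correlations of each Betti metric with each
#' global white-matter microstructure metric (FA, MD, isotropic
#' diffusion).
#'
#' @param metrics Data frame from [subnetwork_betti_at()].
#' @param micro Data frame `participant_id`, `mean_fa`, `mean_md`,
#'   `mean_iso`.
#' @return Data frame `metric`, `micro_metric`, `r`, `p`, `n`.
#' @export
correlate_microstructure <- function(metrics, micro) {
  d <- merge(metrics, micro, by = "participant_id")
  rows <- list()
  for (mname in c("betti0", "betti1", "ratio")) {
    for (uname in c("mean_fa", "mean_md", "mean_iso")) {
      ok <- stats::complete.cases(d[, c(mname, uname)])
      if (sum(ok) < 3L) stop("fewer than 3 complete pairs for ", mname, " vs ", uname)
      ct <- cor.test(d[[mname]][ok], d[[uname]][ok], method = "pearson")
      rows[[paste(mname, uname)]] <- data.frame(
        metric = mname, micro_metric = uname,
        r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
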