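# Normative w-score modelling: per-target ordinary least squares fitted in
# the cognitively normal group only, then applied to everyone.
#
#   w = (observed - predicted_from_CN) / residual_sd_CN
#
# Higher w means greater GFA/volume than expected for a CN individual with
# the same covariates; lower w means greater degeneration than expected.

# Build the long (participant_id, target_id, value) view of either a tract
# table or a regional volume table.
as_target_long <- function(values) {
  if (all(c("tract", "gfa") %in% names(values))) {
    data.frame(participant_id = values$participant_id, target_id = values$tract,
               value = values$gfa, stringsAsFactors = FALSE)
  } else if (all(c("region_label", "gm_volume") %in% names(values))) {
    data.frame(participant_id = values$participant_id, target_id = values$region_label,
               value = values$gm_volume, stringsAsFactors = FALSE)
  } else {
    stop("values must be a tract table (tract/gfa) or a volume table (region_label/gm_volume)")
  }
}

# Design matrix for the normative model: intercept + numeric covariates,
# with sex encoded as an indicator for male (reference level F).
normative_design <- function(records, covariates) {
  cols <- lapply(covariates, function(cv) {
    if (cv == "sex") as.numeric(records$sex == "M") else {
      v <- records[[cv]]
      if (is.null(v)) stop("covariate absent from records: ", cv)
      as.numeric(v)
    }
  })
  X <- cbind(`(Intercept)` = 1, do.call(cbind, setNames(cols, covariates)))
  X
}

#' Fit normative (control-group) regression models per target
#'
#' One ordinary least-squares model per tract or region, fitted on the
#' cognitively normal participants only. The residual SD uses
#' `df = n_train - p` where `p` is the number of fitted parameters.
#' Targets with a singular design or too few controls are dropped with a
#' warning; targets with a numerically perfect fit are kept but flagged
#' `degenerate`.
#'
#' @param values Tract table (from [build_tract_table()]) or regional
#'   volume table (columns `participant_id`, `region_label`, `gm_volume`).
#' @param records Participant metadata (needs `participant_id`, `group`,
#'   and the covariate columns).
#' @param covariates Covariate names; the conventional sets are
#'   `c("age_at_mri", "sex")` for tract GFA and
#'   `c("icv", "age_at_mri", "sex")` for grey-matter volumes.
#' @return Named list of class `normative_models`; each element has
#'   `target_id`, `covariates`, `coefficients`, `residual_sd`, `n_train`,
#'   `degenerate`.
#' @export
fit_normative <- function(values, records, covariates = c("age_at_mri", "sex")) {
  long <- as_target_long(values)
  cn_ids <- records$participant_id[records$group == "CN"]
  long <- long[long$participant_id %in% cn_ids & !is.na(long$value), , drop = FALSE]
  if (!nrow(long)) stop("no control-group observations to fit on")
  rec_idx <- match(long$participant_id, records$participant_id)
  X_all <- normative_design(records[rec_idx, , drop = FALSE], covariates)
  p <- ncol(X_all)

  models <- list()
  dropped <- character(0)
  for (tid in sort(unique(long$target_id))) {
    sel <- long$target_id == tid
    y <- long$value[sel]
    X <- X_all[sel, , drop = FALSE]
    if (length(y) < p + 1L) { dropped <- c(dropped, tid); next }
    qx <- qr(X)
    if (qx$rank < p) { dropped <- c(dropped, tid); next }
    beta <- qr.coef(qx, y)
    res <- y - drop(X %*% beta)
    rsd <- sqrt(sum(res^2) / (length(y) - p))
    models[[tid]] <- list(
      target_id = tid, covariates = covariates,
      coefficients = setNames(beta, colnames(X)),
      residual_sd = rsd, n_train = length(y),
      degenerate = rsd < 1e-8
    )
  }
  if (length(dropped)) {
    warning(length(dropped), " target(s) dropped (singular design or too few controls): ",
            paste(head(dropped, 5), collapse = ", "))
  }
  structure(models, class = "normative_models", covariates = covariates)
}

#' Transform observations to w-scores
#'
#' Applies fitted normative models to all participants (including the
#' controls they were trained on). Missing observations stay missing.
#' Degenerate models (residual SD ~ 0) yield `NA` w-scores.
#'
#' @inheritParams fit_normative
#' @param models A `normative_models` object from [fit_normative()].
#' @param modality Label stored on the result (`"gfa"` or `"volume"`).
#' @return Data frame of class `wscore_table` with `participant_id`,
#'   `target_id`, `w`; attributes record the modality.
#' @export
wscore_transform <- function(values, models, records,
                             modality = c("gfa", "volume")) {
  modality <- match.arg(modality)
  long <- as_target_long(values)
  covariates <- attr(models, "covariates")
  have <- long$target_id %in% names(models)
  if (!any(have)) stop("no targets with fitted models")
  rec_idx <- match(long$participant_id, records$participant_id)
  if (anyNA(rec_idx)) stop("records missing for some participants")
  X <- normative_design(records[rec_idx, , drop = FALSE], covariates)
  w <- rep(NA_real_, nrow(long))
  for (tid in unique(long$target_id[have])) {
    mdl <- models[[tid]]
    sel <- which(long$target_id == tid)
    if (mdl$degenerate) next
    pred <- drop(X[sel, , drop = FALSE] %*% mdl$coefficients)
    w[sel] <- (long$value[sel] - pred) / mdl$residual_sd
  }
  out <- data.frame(participant_id = long$participant_id,
                    target_id = long$target_id, w = w,
                    stringsAsFactors = FALSE)
  out <- out[order(out$participant_id, out$target_id), ]
  rownames(out) <- NULL
  structure(out, class = c("wscore_table", "data.frame"), modality = modality)
}

#' Truncate w-scores at pooled distribution percentiles
#'
#' Clamps w-scores to the \[`lower_pct`, `upper_pct`\] percentiles of the
#' pooled per-modality distribution (all participants x all targets),
#' protecting regressions from extreme outliers. Percentiles use linear
#' interpolation between order statistics (type 7).
#'
#' @param wtable A `wscore_table`.
#' @param lower_pct,upper_pct Percentile bounds (defaults 0.1 and 99.9).
#' @return The truncated `wscore_table`, with attributes
#'   `truncation_bounds` (named numeric, `lower`/`upper`).
#' @export
wscore_truncate <- function(wtable, lower_pct = 0.1, upper_pct = 99.9) {
  v <- wtable$w
  fin <- is.finite(v)
  if (!any(fin)) stop("empty w-score table")
  if (sum(fin) < 1000L) {
    warning("fewer than 1000 finite w-scores; extreme percentiles are unstable")
  }
  bounds <- quantile(v[fin], probs = c(lower_pct, upper_pct) / 100,
                     type = 7, names = FALSE)
  wtable$w <- pmin(pmax(v, bounds[1L]), bounds[2L])
  attr(wtable, "truncation_bounds") <- c(lower = bounds[1L], upper = bounds[2L])
  wtable
}

#' Min/max normalize w-scores for topological analysis
#'
#' Rescales finite w-scores so the global minimum maps to 0 and the global
#' maximum to 1; afterwards, missing entries are set to 0, tying them with
#' the global minimum so absent tracts never enter a graph filtration.
#'
#' @param wtable A `wscore_table`.
#' @return `wscore_table` with values in \[0, 1\] and no missing entries;
#'   attributes `norm_min` / `norm_max` record the constants.
#' @export
wscore_minmax <- function(wtable) {
  v <- wtable$w
  fin <- is.finite(v)
  if (!any(fin)) stop("empty w-score table")
  lo <- min(v[fin]); hi <- max(v[fin])
  if (hi <= lo) stop("degenerate w-score range; cannot min/max normalize")
  v <- (v - lo) / (hi - lo)
  v[!is.finite(v)] <- 0
  wtable$w <- v
  attr(wtable, "norm_min") <- lo
  attr(wtable, "norm_max") <- hi
  attr(wtable, "normalized") <- TRUE
  wtable
}
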