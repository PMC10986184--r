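# Internal constants of the volume model (covariate effects the w-score
# stage is expected to remove).
GM_ICV_BETA <- 0.004   # mm^3 volume per mm^3 intracranial volume
GM_AGE_BETA <- -15     # mm^3 per year of age
GM_SEX_BETA <- 250     # mm^3, male relative to female
ICV_MEAN <- 1.45e6     # mm^3

# Phenotype-level demographic targets used by the generator.
PHEN_AGE_MEAN <- c(CN = 64, aAD = 67, lvPPA = 63, PCA = 58, bvAD = 61, CBS = 58)
PHEN_MMSE_MEAN <- c(CN = 29.2, aAD = 22.9, lvPPA = 23.5, PCA = 23.0, bvAD = 19.5, CBS = 19.5)
PHEN_MMSE_SD <- c(CN = 0.9, aAD = 3.5, lvPPA = 4.0, PCA = 4.0, bvAD = 4.0, CBS = 4.5)
PHEN_FEMALE_P <- c(CN = 0.578, aAD = 0.488, lvPPA = 0.50, PCA = 0.706, bvAD = 0.20, CBS = 0.625)
PHEN_APOE_P <- list(
  CN = c(8, 2, 2), aAD = c(6, 18, 6), lvPPA = c(20, 11, 0),
  PCA = c(10, 4, 3), bvAD = c(5, 5, 0), CBS = c(1, 2, 1)
)

#' Generate a complete synthetic cohort
#'
#' Draws participant metadata, sparse symmetric tractwise GFA connectivity
#' matrices, regional grey-matter volumes, global white-matter
#' microstructure scalars and a population-template connectivity matrix,
#' all with the statistical structure the downstream pipeline assumes.
#' Deterministic given `config$seed`.
#'
#' The returned `truth` element records the generating quantities
#' (tract universe, per-tract baselines and presence probabilities,
#' realized phenotype shifts, forced islands) so that tests can compare
#' pipeline estimates against ground truth.
#'
#' @param config A [cohort_config()] object.
#' @return Object of class `cohort`: a list with elements `records`,
#'   `matrices` (named list of symmetric GFA matrices with `NA` for
#'   missing tracts), `volumes`, `micro`, `template`, `config`, `truth`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(config$seed)

  labels <- default_region_labels(config$region_count)
  hemi <- substr(labels, 1L, 1L)
  records <- generate_records(config)
  severity <- setNames(records$.severity, records$participant_id)
  records$.severity <- NULL
  n_sub <- nrow(records)

  ## --- tract universe with hemispheric block structure ---------------
  pairs <- utils::combn(length(labels), 2L)
  within <- hemi[pairs[1L, ]] == hemi[pairs[2L, ]]
  p_edge <- ifelse(within, config$p_within, config$p_between)
  keep <- runif(ncol(pairs)) < p_edge
  if (sum(keep) < 4L) stop("tract universe degenerate; raise p_within/p_between")
  # every region gets at least 4 within-block tracts, so only the
  # designated low-coverage regions recur as islands
  deg <- tabulate(c(pairs[1L, keep], pairs[2L, keep]), nbins = length(labels))
  for (ri in which(deg < 4L)) {
    cand <- which((pairs[1L, ] == ri | pairs[2L, ] == ri) & within & !keep)
    need <- min(4L - deg[ri], length(cand))
    if (need > 0L) {
      add <- sample(cand, need)
      keep[add] <- TRUE
      deg <- tabulate(c(pairs[1L, keep], pairs[2L, keep]), nbins = length(labels))
    }
  }
  ua <- labels[pairs[1L, keep]]
  ub <- labels[pairs[2L, keep]]
  universe <- tract_id(ua, ub)
  ord <- order(universe)
  universe <- universe[ord]
  ua <- ua[ord]; ub <- ub[ord]
  n_tracts <- length(universe)

  baseline <- setNames(runif(n_tracts, 0.3, 0.7), universe)

  ## --- per-tract presence probabilities (Beta across tracts) ---------
  m <- config$presence_mean; s <- config$presence_sd
  if (s > 0 && s^2 < m * (1 - m)) {
    t0 <- m * (1 - m) / s^2 - 1
    prob <- rbeta(n_tracts, m * t0, (1 - m) * t0)
  } else {
    prob <- rep(m, n_tracts)
  }
  prob <- setNames(pmin(pmax(prob, 0.01), 1), universe)

  # Suppress coverage for the designated low-coverage regions so they
  # recur as islands (the regions quality control is meant to drop).
  low_cov <- character(0)
  if (config$low_coverage_regions > 0L) {
    k <- config$low_coverage_regions
    left <- labels[hemi == "L"]; right <- labels[hemi == "R"]
    low_cov <- c(utils::tail(left, ceiling(k / 2)), utils::tail(right, floor(k / 2)))
    hit <- ua %in% low_cov | ub %in% low_cov
    prob[hit] <- prob[hit] * 0.04
  }
  suppressed <- universe[ua %in% low_cov | ub %in% low_cov]

  ## --- resolve effect_spec into per-phenotype shift vectors ----------
  rank_ids <- universe[setdiff(order(-prob, universe), which(universe %in% suppressed))]
  rank_ids <- rank_ids[!rank_ids %in% suppressed]
  shifts <- lapply(setNames(nm = PHENOTYPE_LEVELS), function(p) numeric(0))
  for (eff in config$effect_spec) {
    ids <- if (!is.null(eff$tracts)) {
      missing_ids <- setdiff(eff$tracts, universe)
      if (length(missing_ids)) stop("effect_spec names tracts outside the universe: ",
                                    paste(head(missing_ids, 3), collapse = ", "))
      eff$tracts
    } else {
      off <- if (is.null(eff$offset)) 0L else eff$offset
      if (off + eff$n > length(rank_ids)) stop("effect_spec selector exceeds tract universe")
      rank_ids[(off + 1L):(off + eff$n)]
    }
    phens <- switch(eff$phenotype,
      "amnestic" = "aAD",
      "non-amnestic" = c("lvPPA", "PCA", "bvAD", "CBS"),
      eff$phenotype
    )
    for (p in phens) {
      cur <- shifts[[p]]
      add <- setNames(rep(eff$shift, length(ids)), ids)
      for (id in ids) cur[id] <- if (id %in% names(cur)) cur[id] + add[id] else add[id]
      shifts[[p]] <- cur
    }
  }

  ## --- presence draws -------------------------------------------------
  grp <- as.character(records$group)
  pres_prob <- matrix(rep(prob, each = n_sub), nrow = n_sub)
  if (config$presence_group_coupling != 0) {
    pat <- grp != "CN"
    pres_prob[pat, ] <- pmin(pmax(pres_prob[pat, ] + config$presence_group_coupling, 0), 1)
  }
  present <- matrix(runif(n_sub * n_tracts) < pres_prob, nrow = n_sub,
                    dimnames = list(records$participant_id, universe))

  forced_islands <- list()
  if (!is.null(config$island_spec)) {
    for (r in names(config$island_spec)) {
      cnt <- config$island_spec[[r]]
      if (!r %in% labels) stop("island_spec names unknown region: ", r)
      who <- sample(records$participant_id, cnt)
      hit <- ua == r | ub == r
      present[who, hit] <- FALSE
      forced_islands[[r]] <- sort(who)
    }
  }

  ## --- GFA values ------------------------------------------------------
  age_dev <- records$age_at_mri - 65
  male <- as.integer(records$sex == "M")
  shift_mat <- matrix(0, nrow = n_sub, ncol = n_tracts,
                      dimnames = list(records$participant_id, universe))
  for (p in PHENOTYPE_LEVELS) {
    sv <- shifts[[p]]
    if (length(sv)) {
      rows <- which(records$phenotype == p)
      if (length(rows)) shift_mat[rows, names(sv)] <-
          matrix(rep(sv, each = length(rows)), nrow = length(rows))
    }
  }
  sev_scale <- pmax(1 + config$severity_effect * severity, 0)
  values <- matrix(rep(baseline, each = n_sub), nrow = n_sub) +
    outer(config$age_effect * age_dev + config$sex_effect * male, rep(1, n_tracts)) +
    shift_mat * sev_scale * config$noise_sd +
    matrix(rnorm(n_sub * n_tracts, 0, config$noise_sd), nrow = n_sub)
  values <- pmin(pmax(values, 0), 1)
  values[!present] <- NA_real_

  ia <- match(ua, labels); ib <- match(ub, labels)
  matrices <- lapply(seq_len(n_sub), function(i) {
    mat <- matrix(NA_real_, config$region_count, config$region_count,
                  dimnames = list(labels, labels))
    v <- values[i, ]
    idx_a <- cbind(ia, ib); idx_b <- cbind(ib, ia)
    mat[idx_a] <- v; mat[idx_b] <- v
    mat
  })
  names(matrices) <- records$participant_id

  ## --- grey-matter volumes --------------------------------------------
  gm_baseline <- setNames(runif(config$region_count, 2500, 15000), labels)
  denom <- if (config$noise_sd > 0) config$noise_sd else 1
  expect_v <- matrix(rep(baseline, each = n_sub), nrow = n_sub) +
    outer(config$age_effect * age_dev + config$sex_effect * male, rep(1, n_tracts))
  dev <- (values - expect_v) / denom  # control-SD units, NA where absent
  slopes <- config$gm_coupling_slopes[grp]
  vol_list <- lapply(seq_along(labels), function(ri) {
    hit <- which(ia == ri | ib == ri)
    reg_dev <- if (length(hit)) rowMeans(dev[, hit, drop = FALSE], na.rm = TRUE) else rep(0, n_sub)
    reg_dev[!is.finite(reg_dev)] <- 0
    vol <- gm_baseline[ri] +
      GM_ICV_BETA * (records$icv - ICV_MEAN) +
      GM_AGE_BETA * age_dev + GM_SEX_BETA * male +
      config$gm_scale * slopes * reg_dev +
      rnorm(n_sub, 0, config$gm_scale)
    pmax(vol, 50)
  })
  volumes <- data.frame(
    participant_id = rep(records$participant_id, times = length(labels)),
    region_label = rep(labels, each = n_sub),
    gm_volume = unlist(vol_list, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  volumes <- volumes[order(volumes$participant_id, volumes$region_label), ]
  rownames(volumes) <- NULL

  ## --- global microstructure -------------------------------------------
  micro <- data.frame(
    participant_id = records$participant_id,
    mean_fa = pmin(pmax(config$micro_means$fa[grp] + rnorm(n_sub, 0, config$micro_sds["fa"]), 0), 1),
    mean_md = pmax(config$micro_means$md[grp] + rnorm(n_sub, 0, config$micro_sds["md"]), 1e-6),
    mean_iso = pmax(config$micro_means$iso[grp] + rnorm(n_sub, 0, config$micro_sds["iso"]), 0),
    stringsAsFactors = FALSE
  )
  rownames(micro) <- NULL

  ## --- template: nonzero exactly on the emittable tracts ---------------
  template <- matrix(0, config$region_count, config$region_count,
                     dimnames = list(labels, labels))
  template[cbind(ia, ib)] <- baseline
  template[cbind(ib, ia)] <- baseline
  diag(template) <- NA_real_

  structure(list(
    records = records, matrices = matrices, volumes = volumes, micro = micro,
    template = template, config = config,
    truth = list(
      universe = universe, baseline = baseline, presence_prob = prob,
      shifts = shifts, suppressed_tracts = suppressed, severity = severity,
      low_coverage_regions = low_cov, forced_islands = forced_islands,
      presence_rank = rank_ids, gm_baseline = gm_baseline
    )
  ), class = "cohort")
}

# Participant metadata for one cohort (internal; RNG already seeded).
generate_records <- function(config) {
  rows <- list()
  idx <- 0L
  for (p in PHENOTYPE_LEVELS) {
    n <- config$n_per_phenotype[p]
    if (is.na(n) || n == 0L) next
    n <- as.integer(n)
    age <- round(pmin(pmax(rnorm(n, PHEN_AGE_MEAN[p], 7), 45), 90), 1)
    sex <- ifelse(runif(n) < PHEN_FEMALE_P[p], "F", "M")
    # latent disease severity couples MMSE to degeneration within patients
    severity <- if (p == "CN") rep(0, n) else rnorm(n)
    mmse_raw <- PHEN_MMSE_MEAN[p] - config$mmse_severity_slope * severity +
      rnorm(n, 0, PHEN_MMSE_SD[p] * 0.7)
    mmse <- as.integer(pmin(pmax(round(mmse_raw),
                                 if (p == "CN") 27L else 0L), 30L))
    duration <- if (p == "CN") rep(NA_real_, n) else round(pmax(stats::rgamma(n, 2, scale = 1.75), 0.2), 1)
    icv <- round(rnorm(n, ICV_MEAN, 1.0e5) + 8e4 * (sex == "M"))
    apoe <- sample(0:2, n, replace = TRUE, prob = PHEN_APOE_P[[p]] + 0.5)
    df <- data.frame(
      participant_id = sprintf("sub-%03d", idx + seq_len(n)),
      phenotype = factor(p, levels = PHENOTYPE_LEVELS),
      age_at_mri = age, sex = factor(sex, levels = c("F", "M")),
      mmse = mmse, disease_duration = duration, icv = icv,
      apoe_e4_count = as.integer(apoe),
      biomarker_confirmed = if (p == "CN") NA else TRUE,
      .severity = severity,
      stringsAsFactors = FALSE
    )
    # Structured missingness (counts per phenotype).
    km <- config$missing_mmse[p]
    if (!is.null(km) && !is.na(km) && km > 0) df$mmse[sample(n, min(km, n))] <- NA_integer_
    kd <- config$missing_duration[p]
    if (!is.null(kd) && !is.na(kd) && kd > 0 && p != "CN") {
      df$disease_duration[sample(n, min(kd, n))] <- NA_real_
    }
    ka <- config$missing_apoe[p]
    if (!is.null(ka) && !is.na(ka) && ka > 0) df$apoe_e4_count[sample(n, min(ka, n))] <- NA_integer_
    kb <- config$unconfirmed_biomarkers[p]
    if (!is.null(kb) && !is.na(kb) && kb > 0 && p != "CN") {
      df$biomarker_confirmed[sample(n, min(kb, n))] <- FALSE
    }
    rows[[p]] <- df
    idx <- idx + n
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$group <- phenotype_to_group(out$phenotype)
  out[, c("participant_id", "phenotype", "group", "age_at_mri", "sex", "mmse",
          "disease_duration", "icv", "apoe_e4_count", "biomarker_confirmed",
          ".severity")]
}

#' Impute missing MMSE and disease duration
#'
#' Missing CN MMSE scores are imputed as the mean of the remaining CN
#' sample; missing patient MMSE scores as the mean MMSE across all
#' patients (amnestic and non-amnestic); missing patient disease duration
#' as the mean duration among all other patients. Each filled cell is
#' flagged (`mmse_imputed`, `duration_imputed`).
#'
#' @param records Participant metadata data frame (see [generate_cohort()]).
#' @return `records` with imputed values and logical imputation flags.
#' @export
impute_missing_meta <- function(records) {
  records$mmse_imputed <- FALSE
  records$duration_imputed <- FALSE
  is_cn <- records$group == "CN"

  miss_cn <- is_cn & is.na(records$mmse)
  if (any(miss_cn)) {
    donor <- records$mmse[is_cn & !is.na(records$mmse)]
    if (!length(donor)) stop("cannot impute: all CN MMSE values are missing")
    records$mmse[miss_cn] <- mean(donor)
    records$mmse_imputed[miss_cn] <- TRUE
  }
  miss_pat <- !is_cn & is.na(records$mmse)
  if (any(miss_pat)) {
    donor <- records$mmse[!is_cn & !is.na(records$mmse)]
    if (!length(donor)) stop("cannot impute: all patient MMSE values are missing")
    records$mmse[miss_pat] <- mean(donor)
    records$mmse_imputed[miss_pat] <- TRUE
  }
  miss_dur <- !is_cn & is.na(records$disease_duration)
  if (any(miss_dur)) {
    donor <- records$disease_duration[!is_cn & !is.na(records$disease_duration)]
    if (!length(donor)) stop("cannot impute: all patient durations are missing")
    records$disease_duration[miss_dur] <- mean(donor)
    records$duration_imputed[miss_dur] <- TRUE
  }
  records
}
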