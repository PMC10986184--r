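#' Island frequency per region
#'
#' A region is an "island" in a scan when it has no defined connection to
#' any other region. Returns, for every region, the fraction of
#' participants in which it was an island.
#'
#' @param matrices Named list of symmetric connectivity matrices with `NA`
#'   for missing tracts (consistent region labels).
#' @return Named numeric vector, region label -> island fraction.
#' @export
detect_islands <- function(matrices) {
  stopifnot(length(matrices) >= 1L)
  labs <- rownames(matrices[[1L]])
  counts <- numeric(length(labs))
  for (m in matrices) {
    if (!identical(rownames(m), labs)) {
      stop("inconsistent region labels across participants")
    }
    deg <- rowSums(!is.na(m)) # diagonal is NA, so off-diagonal only
    counts <- counts + (deg == 0L)
  }
  setNames(counts / length(matrices), labs)
}

#' Exclude regions that recur as islands
#'
#' Drops every region whose island frequency is strictly greater than
#' `threshold` (the boundary value is retained) and re-indexes all
#' matrices, which remain symmetric.
#'
#' @inheritParams detect_islands
#' @param threshold Island-frequency cut-off in \[0, 1\] (default 0.25,
#'   i.e. "more than 25% of scans").
#' @return List with `matrices` (regions dropped) and `excluded`
#'   (character vector of dropped region labels).
#' @export
exclude_regions <- function(matrices, threshold = 0.25) {
  stopifnot(threshold >= 0, threshold <= 1)
  freq <- detect_islands(matrices)
  excluded <- names(freq)[freq > threshold]
  keep <- setdiff(names(freq), excluded)
  if (!length(keep)) stop("all regions excluded at threshold ", threshold)
  out <- lapply(matrices, function(m) m[keep, keep, drop = FALSE])
  list(matrices = out, excluded = excluded, island_frequency = freq)
}

#' Coverage ("50% rule") tract filter
#'
#' A tract is retained only if it is present in at least `min_fraction`
#' (inclusive) of the participants of **every** phenotype in
#' `phenotype_set`. The default phenotype set omits the amnestic group,
#' mirroring the original coverage rule; a message flags this so users can
#' opt in to including `aAD`.
#'
#' @inheritParams detect_islands
#' @param records Participant metadata with `participant_id`, `phenotype`.
#' @param phenotype_set Phenotypes over which the rule is enforced.
#' @param min_fraction Minimum presence fraction (inclusive), in (0, 1\].
#' @param quiet Suppress the informational message about the phenotype set.
#' @return Character vector of retained tract identifiers (sorted).
#' @export
coverage_filter <- function(matrices, records,
                            phenotype_set = c("CN", "lvPPA", "PCA", "bvAD", "CBS"),
                            min_fraction = 0.5, quiet = FALSE) {
  stopifnot(length(phenotype_set) >= 1L, min_fraction > 0, min_fraction <= 1)
  if (!quiet && !"aAD" %in% phenotype_set) {
    message("coverage_filter: phenotype set omits 'aAD'; pass it explicitly to include the amnestic group in the 50% rule")
  }
  pres <- presence_by_phenotype(matrices, records, phenotype_set)
  keep <- rownames(pres)[apply(pres >= min_fraction, 1L, all)]
  sort(keep)
}

# Presence fraction of every candidate tract per phenotype (rows: tracts,
# cols: phenotypes).
presence_by_phenotype <- function(matrices, records, phenotype_set) {
  labs <- rownames(matrices[[1L]])
  ut <- upper.tri(matrices[[1L]])
  idx <- which(ut, arr.ind = TRUE)
  ids <- tract_id(labs[idx[, 1L]], labs[idx[, 2L]])
  pres <- vapply(matrices, function(m) !is.na(m[ut]), logical(length(ids)))
  out <- matrix(NA_real_, nrow = length(ids), ncol = length(phenotype_set),
                dimnames = list(ids, phenotype_set))
  for (p in phenotype_set) {
    who <- records$participant_id[records$phenotype == p]
    if (!length(who)) stop("phenotype with zero participants: ", p)
    if (!all(who %in% colnames(pres))) stop("matrices missing for some participants of ", p)
    out[, p] <- rowMeans(pres[, who, drop = FALSE])
  }
  out
}

#' Template tract filter
#'
#' Retains a tract only if the population-template connectivity matrix has
#' a defined, strictly positive value for it.
#'
#' @param tracts Character vector of tract identifiers.
#' @param template Symmetric template connectivity matrix.
#' @return Filtered (sorted) tract identifier vector.
#' @export
template_filter <- function(tracts, template) {
  reg <- tract_regions(tracts)
  labs <- rownames(template)
  miss <- setdiff(unique(c(reg$region_a, reg$region_b)), labs)
  if (length(miss)) stop("tract endpoints absent from template: ", paste(miss, collapse = ", "))
  vals <- template[cbind(match(reg$region_a, labs), match(reg$region_b, labs))]
  sort(tracts[!is.na(vals) & vals > 0])
}

#' Long tract table for retained tracts
#'
#' One row per participant x retained tract; tracts missing for a
#' participant are kept with `present = FALSE` (and `NA` GFA) so that
#' downstream analyses can exclude them tract-by-tract.
#'
#' @inheritParams detect_islands
#' @param retained Character vector of retained tract identifiers.
#' @return Data frame with `participant_id`, `tract`, `region_a`,
#'   `region_b`, `gfa`, `present`, sorted by participant then tract.
#' @export
build_tract_table <- function(matrices, retained) {
  stopifnot(length(retained) >= 1L)
  retained <- sort(retained)
  reg <- tract_regions(retained)
  labs <- rownames(matrices[[1L]])
  cell <- cbind(match(reg$region_a, labs), match(reg$region_b, labs))
  if (anyNA(cell)) stop("retained tracts reference regions absent from the matrices")
  rows <- lapply(names(matrices), function(id) {
    g <- matrices[[id]][cell]
    data.frame(
      participant_id = id, tract = retained,
      region_a = reg$region_a, region_b = reg$region_b,
      gfa = g, present = !is.na(g), stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$tract), ]
  rownames(out) <- NULL
  out
}

#' Run the full connectome quality-control chain
#'
#' Applies, in order: island-based region exclusion (strict > threshold),
#' the phenotype coverage rule (inclusive >= `min_fraction`), and the
#' template filter; then builds the long tract table.
#'
#' @inheritParams coverage_filter
#' @param template Template connectivity matrix (`NULL` skips the filter).
#' @param island_threshold Island-frequency exclusion threshold.
#' @return List of class `qc_result`: `tract_table`, `matrices` (region
#'   filtered), and `report` (island frequencies, excluded regions,
#'   per-phenotype coverage, retained tracts, template-excluded tracts).
#' @export
run_qc <- function(matrices, records, template = NULL,
                   island_threshold = 0.25,
                   phenotype_set = c("CN", "lvPPA", "PCA", "bvAD", "CBS"),
                   min_fraction = 0.5, quiet = TRUE) {
  ex <- exclude_regions(matrices, island_threshold)
  covered <- coverage_filter(ex$matrices, records, phenotype_set, min_fraction,
                             quiet = quiet)
  if (!is.null(template)) {
    keep_reg <- rownames(ex$matrices[[1L]])
    templ <- template[keep_reg, keep_reg, drop = FALSE]
    retained <- template_filter(covered, templ)
  } else {
    retained <- covered
  }
  if (!length(retained)) stop("no tracts retained by quality control")
  pres <- presence_by_phenotype(ex$matrices, records,
                                intersect(PHENOTYPE_LEVELS, unique(as.character(records$phenotype))))
  coverage <- pres[retained, , drop = FALSE]
  report <- list(
    island_frequency = ex$island_frequency,
    excluded_regions = ex$excluded,
    retained_tracts = retained,
    template_excluded = setdiff(covered, retained),
    coverage = coverage,
    overall_coverage = rowMeans(coverage[, , drop = FALSE])
  )
  # mean presence across retained tracts, pooled over all participants
  ut_pres <- vapply(ex$matrices, function(m) {
    reg <- tract_regions(retained)
    labs <- rownames(m)
    !is.na(m[cbind(match(reg$region_a, labs), match(reg$region_b, labs))])
  }, logical(length(retained)))
  report$tract_presence <- rowMeans(ut_pres)
  names(report$tract_presence) <- retained
  report$mean_presence <- mean(report$tract_presence)
  structure(list(
    tract_table = build_tract_table(ex$matrices, retained),
    matrices = ex$matrices,
    report = report
  ), class = "qc_result")
}
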