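#' @keywords internal
"_PACKAGE"

#' @importFrom stats anova aggregate coef complete.cases cor cor.test lm
#'   lm.fit model.matrix na.omit p.adjust pf predict qnorm quantile rbeta
#'   rbinom rnorm runif sd setNames var vcov
#' @importFrom utils head read.csv write.csv
NULL

# Separator used in canonical tract identifiers ("regionA--regionB").
TRACT_SEP <- "--"

#' Canonical tract identifier for a pair of regions
#'
#' Tracts are undirected, so region pairs are stored in canonical
#' (lexicographic) order and joined with `"--"`.
#'
#' @param region_a,region_b Character vectors of region labels.
#' @return Character vector of tract identifiers.
#' @export
tract_id <- function(region_a, region_b) {
  stopifnot(length(region_a) == length(region_b))
  if (any(region_a == region_b)) stop("a tract cannot connect a region to itself")
  lo <- pmin(region_a, region_b)
  hi <- pmax(region_a, region_b)
  paste(lo, hi, sep = TRACT_SEP)
}

#' Split tract identifiers back into their two region labels
#'
#' @param id Character vector of tract identifiers from [tract_id()].
#' @return Data frame with columns `region_a` and `region_b`
#'   (`region_a < region_b`).
#' @export
tract_regions <- function(id) {
  parts <- strsplit(id, TRACT_SEP, fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed tract identifier: ", id[bad][1])
  data.frame(
    region_a = vapply(parts, `[[`, character(1), 1L),
    region_b = vapply(parts, `[[`, character(1), 2L),
    stringsAsFactors = FALSE
  )
}

#' Candidate tract universe for a parcellation
#'
#' All unordered region pairs of a parcellation, in canonical order. For a
#' 152-region parcellation this universe has `choose(152, 2) = 11476`
#' members.
#'
#' @param regions Character vector of region labels, or a single integer
#'   (number of regions; labels are generated).
#' @return Character vector of tract identifiers, sorted.
#' @export
all_tract_pairs <- function(regions) {
  if (is.numeric(regions) && length(regions) == 1L) {
    regions <- default_region_labels(as.integer(regions))
  }
  regions <- sort(unique(regions))
  n <- length(regions)
  if (n < 2L) return(character(0))
  idx <- utils::combn(n, 2L)
  sort(tract_id(regions[idx[1L, ]], regions[idx[2L, ]]))
}

# Region labels used by the synthetic generator: two hemispheric blocks.
default_region_labels <- function(n) {
  stopifnot(n >= 2L)
  n_left <- ceiling(n / 2)
  c(sprintf("L_%03d", seq_len(n_left)), sprintf("R_%03d", seq_len(n - n_left)))
}

# Convert a symmetric connectivity matrix (NA = missing) to a long data
# frame of upper-triangle cells.
matrix_to_long <- function(mat, drop_missing = TRUE) {
  labs <- rownames(mat)
  ut <- upper.tri(mat)
  idx <- which(ut, arr.ind = TRUE)
  out <- data.frame(
    region_a = labs[idx[, 1L]],
    region_b = labs[idx[, 2L]],
    gfa = mat[ut],
    stringsAsFactors = FALSE
  )
  out$tract <- tract_id(out$region_a, out$region_b)
  if (drop_missing) out <- out[!is.na(out$gfa), , drop = FALSE]
  out[order(out$tract), c("tract", "region_a", "region_b", "gfa")]
}

# Validate a connectivity matrix: symmetric values and missingness, NA
# diagonal, defined values in [0, 1]. Errors name the offending cell.
validate_connectivity_matrix <- function(mat, id = "matrix") {
  labs <- rownames(mat)
  if (is.null(labs) || !identical(labs, colnames(mat))) {
    stop(id, ": row and column labels must be present and identical")
  }
  same <- (mat == t(mat)) | (is.na(mat) & is.na(t(mat)))
  same[is.na(same)] <- FALSE
  diag(same) <- TRUE
  if (!all(same)) {
    bad <- which(!same, arr.ind = TRUE)[1L, ]
    stop(sprintf("%s: asymmetric at cell [%s, %s]", id, labs[bad[1L]], labs[bad[2L]]))
  }
  if (!all(is.na(diag(mat)))) stop(id, ": diagonal must be undefined (NA)")
  vals <- mat[!is.na(mat)]
  if (length(vals) && (min(vals) < 0 || max(vals) > 1)) {
    stop(id, ": defined GFA values must lie in [0, 1]")
  }
  invisible(TRUE)
}

# Shared factor level sets.
PHENOTYPE_LEVELS <- c("CN", "aAD", "lvPPA", "PCA", "bvAD", "CBS")
GROUP_LEVELS <- c("CN", "amnestic", "non-amnestic")

#' Diagnostic group implied by clinical phenotype
#'
#' `aAD` maps to the amnestic group; `lvPPA`, `PCA`, `bvAD` and `CBS` to
#' the non-amnestic group; `CN` stays `CN`.
#'
#' @param phenotype Character or factor vector of phenotype codes.
#' @return Factor with levels `CN`, `amnestic`, `non-amnestic`.
#' @export
phenotype_to_group <- function(phenotype) {
  phenotype <- as.character(phenotype)
  bad <- setdiff(unique(phenotype), PHENOTYPE_LEVELS)
  if (length(bad)) stop("unknown phenotype: ", paste(bad, collapse = ", "))
  grp <- ifelse(phenotype == "CN", "CN",
    ifelse(phenotype == "aAD", "amnestic", "non-amnestic")
  )
  factor(grp, levels = GROUP_LEVELS)
}
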