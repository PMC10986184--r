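# Exact topological inference: the difference between two group-mean
# Betti curves is summarized by their Kolmogorov-Smirnov distance D, and
# an exact p-value is obtained by treating the two curves as a pair of
# exchangeable monotone walks from (0,0) to (q,q) on a Cartesian grid and
# counting, with exact integer arithmetic, the walks that stay strictly
# within the band |x - y| < ceil(D). For q = 148 the total path count
# C(2q, q) far exceeds double precision, so counts are carried in
# arbitrary-precision limbs.

BIG_BASE <- 1e15 # limb base; limb sums stay exact in doubles (< 2^53)

#' Count banded monotone lattice paths exactly
#'
#' Number of monotone paths (unit right/up steps) from (0,0) to (q,q)
#' whose deviation satisfies max |x - y| < `band`, counted by dynamic
#' programming over the offset walk in arbitrary-precision integer limbs
#' (base 1e15, least-significant first). `band = q + 1` is unconstrained
#' and yields the central binomial coefficient C(2q, q).
#'
#' @param q Grid size (>= 1).
#' @param band Strict deviation bound (>= 1).
#' @return Limb vector of class `bigint_limbs`.
#' @export
count_banded_paths <- function(q, band) {
  stopifnot(q >= 1, band >= 1)
  band <- min(band, q + 1) # |x - y| <= q always
  n_states <- 2L * band - 1L       # offsets -(band-1) .. band-1
  L <- max(2L, ceiling(2 * q * log10(2) / 15) + 2L)
  M <- matrix(0, nrow = n_states, ncol = L)
  mid <- band # row index of offset 0
  M[mid, 1L] <- 1
  zero <- rep(0, L)
  for (step in seq_len(2L * q)) {
    up <- rbind(M[-1L, , drop = FALSE], zero)     # from offset j+1
    down <- rbind(zero, M[-n_states, , drop = FALSE]) # from offset j-1
    M <- up + down
    carry <- 0
    for (cidx in seq_len(L)) {
      v <- M[, cidx] + carry
      carry <- floor(v / BIG_BASE)
      M[, cidx] <- v - carry * BIG_BASE
    }
    if (any(carry != 0)) stop("limb overflow; increase L") # unreachable by sizing
  }
  structure(M[mid, ], class = "bigint_limbs")
}

# Exact double conversion (valid while the value fits a double).
bigint_to_double <- function(limbs) {
  v <- 0
  for (cidx in rev(seq_along(limbs))) v <- v * BIG_BASE + limbs[cidx]
  v
}

# Exact limb subtraction a - b (requires a >= b).
bigint_sub <- function(a, b) {
  L <- max(length(a), length(b))
  a <- c(a, rep(0, L - length(a)))
  b <- c(b, rep(0, L - length(b)))
  out <- numeric(L)
  borrow <- 0
  for (i in seq_len(L)) {
    v <- a[i] - b[i] - borrow
    borrow <- if (v < 0) 1 else 0
    out[i] <- v + borrow * BIG_BASE
  }
  if (borrow != 0) stop("bigint_sub: negative result")
  out
}

# Natural log of a limb-encoded non-negative integer (-Inf for zero).
bigint_log <- function(limbs) {
  h <- max(which(limbs != 0), 0L)
  if (h == 0L) return(-Inf)
  mant <- limbs[h]
  if (h >= 2L) mant <- mant + limbs[h - 1L] / BIG_BASE
  if (h >= 3L) mant <- mant + limbs[h - 2L] / BIG_BASE^2
  log(mant) + (h - 1L) * log(BIG_BASE)
}

#' Kolmogorov-Smirnov distance between two mean Betti curves
#'
#' Maximum absolute difference over the shared threshold grid; ties are
#' broken by the smallest threshold.
#'
#' @param mean_a,mean_b Numeric curves on the same grid.
#' @param thresholds Grid thresholds (optional; indices used if absent).
#' @return List with `D` and `lambda_star` (first threshold attaining D).
#' @export
ks_distance <- function(mean_a, mean_b, thresholds = seq_along(mean_a)) {
  stopifnot(length(mean_a) == length(mean_b), length(mean_a) == length(thresholds))
  d <- abs(mean_a - mean_b)
  i <- which.max(d) # first maximum
  list(D = d[i], lambda_star = thresholds[i])
}

#' Exact p-value for a Betti-curve KS distance
#'
#' Probability that two exchangeable monotone walks from (0,0) to (q,q)
#' differ by at least `D` somewhere, computed by banded lattice-path
#' enumeration with exact integer arithmetic: with `b = ceil(D)`, the
#' number `A` of paths staying strictly within `|x - y| < b` is counted
#' by dynamic programming, and `p = 1 - A / C(2q, q)`.
#'
#' @param D Observed KS distance (Betti-count units, >= 0).
#' @param q Grid size: the node count for Betti-0 curves; the maximum
#'   independent-cycle count `E_max - V + 1` for Betti-1 curves.
#' @return p-value in \[0, 1\].
#' @export
exact_pvalue <- function(D, q) {
  stopifnot(q >= 1, D >= 0)
  b <- ceiling(D)
  if (b <= 0) return(1)
  if (b > q) return(0)
  A <- count_banded_paths(q, b)
  if (!is.finite(bigint_log(A))) return(1)
  C <- count_banded_paths(q, q + 1L)
  # p = (C - A) / C via exact integer subtraction, so no cancellation
  lD <- bigint_log(bigint_sub(unclass(C), unclass(A)))
  if (!is.finite(lD)) return(0)
  p <- exp(lD - bigint_log(C))
  min(max(p, 0), 1)
}

#' Permutation p-value for a Betti-curve group difference
#'
#' Permutes group labels, recomputes the KS distance between permuted
#' group-mean curves, and reports `(1 + #{D_perm >= D_obs}) / (1 + n_perm)`.
#' Deterministic given `seed`.
#'
#' @param curve_mat Participants x thresholds matrix of Betti numbers.
#' @param labels Group label per participant (row).
#' @param groups The two labels to compare.
#' @param n_perm Number of permutations.
#' @param seed Integer seed.
#' @return List with `p`, `D_obs`, `D_perm` (vector).
#' @export
permutation_pvalue <- function(curve_mat, labels, groups, n_perm = 999L, seed = 1L) {
  sel <- labels %in% groups
  cm <- curve_mat[sel, , drop = FALSE]
  lab <- labels[sel]
  na <- sum(lab == groups[1L])
  if (na < 2L || sum(lab == groups[2L]) < 2L) stop("need >= 2 participants per group")
  obs <- ks_distance(colMeans(cm[lab == groups[1L], , drop = FALSE]),
                     colMeans(cm[lab == groups[2L], , drop = FALSE]))$D
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  n <- nrow(cm)
  csum <- colSums(cm)
  d_perm <- vapply(seq_len(n_perm), function(i) {
    idx <- sample.int(n, na)
    ma <- colMeans(cm[idx, , drop = FALSE])
    mb <- (csum - ma * na) / (n - na)
    max(abs(ma - mb))
  }, numeric(1))
  list(p = (1 + sum(d_perm >= obs)) / (1 + n_perm), D_obs = obs, D_perm = d_perm)
}

#' Compare group mean Betti curves with exact inference
#'
#' Computes the two group mean curves, their KS distance and argmax
#' threshold, the walk grid size `q` (node count for Betti-0;
#' `max(0, E_max - V + 1)` for Betti-1, with `E_max` the edge count of
#' the densest participant graph), the exact combinatorial p-value, and
#' optionally a permutation p-value for validation.
#'
#' @param curves A `betti_curves` object.
#' @param records Participant metadata (for group labels).
#' @param groups Two group labels to compare.
#' @param curve `"betti0"` or `"betti1"`.
#' @param group_col Column of `records` holding the labels.
#' @param n_perm Permutations for the optional validation p-value (0 = skip).
#' @param seed Seed for the permutation test.
#' @return Object of class `exact_test_result`: list with `groups`,
#'   `curve`, `mean_curves`, `ks_distance`, `lambda_star`, `q`, `band`,
#'   `p_exact`, and optionally `p_permutation`.
#' @export
compare_betti_curves <- function(curves, records, groups = c("CN", "non-amnestic"),
                                 curve = c("betti0", "betti1"),
                                 group_col = "group", n_perm = 0L, seed = 1L) {
  curve <- match.arg(curve)
  cm <- curves[[curve]]
  labels <- as.character(records[[group_col]][match(curves$participants,
                                                    records$participant_id)])
  if (!all(groups %in% labels)) stop("requested groups not present in records")
  ma <- colMeans(cm[labels == groups[1L], , drop = FALSE])
  mb <- colMeans(cm[labels == groups[2L], , drop = FALSE])
  ks <- ks_distance(ma, mb, curves$grid$thresholds)
  q <- if (curve == "betti0") curves$n_nodes else {
    max(0L, max(curves$edge_count[, 1L]) - curves$n_nodes + 1L)
  }
  p <- if (q >= 1) exact_pvalue(ks$D, q) else NA_real_
  out <- list(groups = groups, curve = curve,
              mean_curves = list(a = ma, b = mb),
              ks_distance = ks$D, lambda_star = ks$lambda_star,
              q = q, band = ceiling(ks$D), p_exact = p)
  if (n_perm > 0L) {
    out$p_permutation <- permutation_pvalue(cm, labels, groups, n_perm, seed)$p
  }
  class(out) <- "exact_test_result"
  out
}

#' Betti numbers of each participant's subnetwork at a fixed threshold
#'
#' Evaluates Betti-0, Betti-1 and the Betti-1/Betti-0 ratio of every
#' participant's graph at the threshold `lambda_star` selected by a prior
#' group comparison. The ratio is well defined because Betti-0 >= 1.
#'
#' @param graphs A `tract_graphs` object.
#' @param lambda_star Filtration threshold (weight units).
#' @return Data frame `participant_id`, `betti0`, `betti1`, `ratio`.
#' @export
subnetwork_betti_at <- function(graphs, lambda_star) {
  n_nodes <- length(graphs$labels)
  rows <- lapply(seq_along(graphs$participants), function(i) {
    wi <- graphs$weights[i, ]
    b0 <- betti0(graphs$edges, wi, n_nodes, lambda_star)
    b1 <- b0 - n_nodes + sum(wi > lambda_star)
    data.frame(participant_id = graphs$participants[i],
               betti0 = b0, betti1 = b1, ratio = b1 / b0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
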