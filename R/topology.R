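# Persistent homology of weighted brain graphs over a descending-weight
# filtration: at threshold lambda the subgraph retains edges with weight
# strictly greater than lambda, so missing tracts (weight 0 after min/max
# normalization) never appear for any lambda >= 0. Betti-0 is the number
# of connected components (isolated nodes count); Betti-1 follows from
# the Euler characteristic: beta1 = beta0 - V + E.

#' Build per-participant graphs from a tract w-score (or GFA) table
#'
#' Edge weights are the table values; missing values are encoded as 0 so
#' that absent tracts never survive the strict filtration. All graphs
#' share the node set implied by the tract identifiers (or an explicit
#' label set).
#'
#' @param wtable `wscore_table` (typically min/max normalized) or any data
#'   frame with `participant_id`, `target_id`, `w`.
#' @param region_labels Optional full node label set.
#' @return Object of class `tract_graphs`: list with `labels`, `edges`
#'   (2-column integer matrix of node indices per tract), `weights`
#'   (participants x tracts matrix), `participants`.
#' @export
tract_graphs <- function(wtable, region_labels = NULL) {
  tr <- sort(unique(wtable$target_id))
  reg <- tract_regions(tr)
  labels <- if (is.null(region_labels)) sort(unique(c(reg$region_a, reg$region_b)))
            else sort(region_labels)
  miss <- setdiff(unique(c(reg$region_a, reg$region_b)), labels)
  if (length(miss)) stop("tract endpoints not in region_labels: ", paste(miss, collapse = ", "))
  edges <- cbind(match(reg$region_a, labels), match(reg$region_b, labels))
  parts <- sort(unique(wtable$participant_id))
  wmat <- matrix(0, nrow = length(parts), ncol = length(tr),
                 dimnames = list(parts, tr))
  wv <- wtable$w
  wv[!is.finite(wv)] <- 0
  wmat[cbind(match(wtable$participant_id, parts), match(wtable$target_id, tr))] <- wv
  structure(list(labels = labels, edges = edges, weights = wmat,
                 participants = parts),
            class = "tract_graphs")
}

# Minimal union-find with path halving; returns number of merges.
uf_components <- function(edges, n_nodes) {
  parent <- seq_len(n_nodes)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  merges <- 0L
  if (nrow(edges)) {
    for (k in seq_len(nrow(edges))) {
      ra <- find(edges[k, 1L]); rb <- find(edges[k, 2L])
      if (ra != rb) { parent[ra] <- rb; merges <- merges + 1L }
    }
  }
  n_nodes - merges
}

#' Betti-0 number of a thresholded graph
#'
#' Number of connected components (isolated nodes included) of the
#' subgraph retaining edges with weight strictly greater than `lambda`.
#'
#' @param edges 2-column integer matrix of node indices.
#' @param weights Edge weights (same length as rows of `edges`).
#' @param n_nodes Number of nodes in the fixed node set.
#' @param lambda Filtration threshold.
#' @return Integer component count in \[1, `n_nodes`\].
#' @export
betti0 <- function(edges, weights, n_nodes, lambda) {
  stopifnot(is.finite(lambda), nrow(edges) == length(weights))
  keep <- weights > lambda
  uf_components(edges[keep, , drop = FALSE], n_nodes)
}

#' Betti-1 number of a thresholded graph
#'
#' Computed from the Euler characteristic:
#' `beta1 = beta0 - n_nodes + n_edges(lambda)`, the number of
#' algebraically independent cycles; always >= 0.
#'
#' @inheritParams betti0
#' @return Integer cycle count (>= 0).
#' @export
betti1 <- function(edges, weights, n_nodes, lambda) {
  keep <- weights > lambda
  b0 <- uf_components(edges[keep, , drop = FALSE], n_nodes)
  b0 - n_nodes + sum(keep)
}

#' Filtration threshold grid
#'
#' `n_linear` linearly spaced thresholds spanning the pooled
#' \[min, max\] of all participants' edge weights. With
#' `augment_mst = TRUE` the union of every participant's spanning-tree
#' edge weights is merged in (deduplicated, sorted): under the
#' descending-weight filtration these are exactly the weights at which
#' component counts change, and the relevant tree is the maximum-weight
#' spanning tree of the similarity graph (`mst_direction = "max"`, the
#' default; `"min"` preserves the literal minimum spanning tree).
#'
#' @param graphs A `tract_graphs` object.
#' @param n_linear Number of linear grid points (default 100).
#' @param augment_mst Merge spanning-tree weights into the grid.
#' @param mst_direction `"max"` or `"min"` spanning tree.
#' @return Object of class `filtration_grid`: list with `thresholds`
#'   (strictly increasing) and `provenance`.
#' @export
build_grid <- function(graphs, n_linear = 100L, augment_mst = FALSE,
                       mst_direction = c("max", "min")) {
  mst_direction <- match.arg(mst_direction)
  w <- graphs$weights
  lo <- min(w); hi <- max(w)
  if (hi <= lo) stop("all edge weights identical; filtration grid degenerate")
  thresholds <- seq(lo, hi, length.out = n_linear)
  prov <- "linear-100"
  if (augment_mst) {
    mst_w <- unlist(lapply(seq_len(nrow(w)), function(i) {
      wi <- w[i, ]
      keep <- wi > 0
      if (!any(keep)) return(numeric(0))
      g <- igraph::graph_from_edgelist(graphs$edges[keep, , drop = FALSE],
                                       directed = FALSE)
      ww <- wi[keep]
      igraph::E(g)$w_orig <- ww
      igwt <- if (mst_direction == "max") -ww else ww
      tree <- igraph::mst(g, weights = igwt)
      igraph::E(tree)$w_orig
    }))
    thresholds <- sort(unique(c(thresholds, mst_w[is.finite(mst_w)])))
    prov <- "mst-augmented"
  }
  structure(list(thresholds = thresholds, provenance = prov),
            class = "filtration_grid")
}

#' Betti curves for every participant
#'
#' Evaluates Betti-0 and Betti-1 at every grid threshold for every
#' participant, by a single descending sweep per participant (edges are
#' added as the threshold decreases, merging components via union-find).
#'
#' @param graphs A `tract_graphs` object.
#' @param grid A `filtration_grid`.
#' @return Object of class `betti_curves`: list with `grid`, `n_nodes`,
#'   `participants`, and integer matrices `betti0`, `betti1`, `edge_count`
#'   (participants x thresholds).
#' @export
betti_curves <- function(graphs, grid) {
  th <- grid$thresholds
  n_th <- length(th)
  n_nodes <- length(graphs$labels)
  parts <- graphs$participants
  B0 <- E <- matrix(0L, nrow = length(parts), ncol = n_th,
                    dimnames = list(parts, NULL))
  edges <- graphs$edges
  for (i in seq_along(parts)) {
    wi <- graphs$weights[i, ]
    ord <- order(wi, decreasing = TRUE)
    parent <- seq_len(n_nodes)
    find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }
    merges <- 0L
    added <- 0L
    k <- 1L
    n_edges <- length(wi)
    # sweep thresholds from largest to smallest
    for (j in rev(seq_len(n_th))) {
      while (k <= n_edges && wi[ord[k]] > th[j]) {
        e <- ord[k]
        ra <- find(edges[e, 1L]); rb <- find(edges[e, 2L])
        if (ra != rb) { parent[ra] <- rb; merges <- merges + 1L }
        added <- added + 1L
        k <- k + 1L
      }
      B0[i, j] <- n_nodes - merges
      E[i, j] <- added
    }
  }
  B1 <- B0 - n_nodes + E
  structure(list(grid = grid, n_nodes = n_nodes, participants = parts,
                 betti0 = B0, betti1 = B1, edge_count = E),
            class = "betti_curves")
}
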