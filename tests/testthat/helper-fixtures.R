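# Shared fixtures, built in code. The default study-sized cohort and its
# pipeline run are memoized so several test files can reuse them.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

default_cohort <- function() {
  memo("default_cohort", generate_cohort(cohort_config(seed = 7)))
}

# Pipeline run through topology on the default cohort.
default_run <- function() {
  memo("default_run", run_pipeline(default_cohort(), out_dir = NULL,
                                   stages = c("qc", "wscore", "tracts",
                                              "gmwm", "micro", "topology")))
}

# Small symmetric connectivity matrix from an edge list (NA elsewhere).
edge_matrix <- function(labels, edges_df) {
  m <- matrix(NA_real_, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (k in seq_len(nrow(edges_df))) {
    i <- edges_df$a[k]; j <- edges_df$b[k]
    m[i, j] <- m[j, i] <- edges_df$w[k]
  }
  m
}

# Deterministic mini-cohort of connectivity matrices for QC tests:
# 8 participants, 4 regions; region "R_001" isolated in participants 1-2.
qc_fixture <- function() {
  labels <- c("L_001", "L_002", "L_003", "R_001")
  full <- data.frame(a = c("L_001", "L_001", "L_002", "L_003"),
                     b = c("L_002", "L_003", "L_003", "R_001"),
                     w = c(0.5, 0.6, 0.4, 0.7), stringsAsFactors = FALSE)
  iso <- full[full$b != "R_001", ]
  mats <- c(
    lapply(1:2, function(i) edge_matrix(labels, iso)),
    lapply(3:8, function(i) edge_matrix(labels, full))
  )
  names(mats) <- sprintf("sub-%03d", 1:8)
  records <- data.frame(
    participant_id = names(mats),
    phenotype = factor(rep(c("CN", "lvPPA"), each = 4), levels = tractopo:::PHENOTYPE_LEVELS),
    stringsAsFactors = FALSE
  )
  records$group <- phenotype_to_group(records$phenotype)
  list(matrices = mats, records = records, labels = labels)
}

# Records table for direct statistical tests (no generator involvement).
stat_records <- function(n_per_group = c(CN = 30L, amnestic = 30L, `non-amnestic` = 30L),
                         seed = 1L) {
  set.seed(seed)
  groups <- rep(names(n_per_group), times = n_per_group)
  n <- length(groups)
  data.frame(
    participant_id = sprintf("p-%03d", seq_len(n)),
    group = factor(groups, levels = tractopo:::GROUP_LEVELS),
    phenotype = factor(ifelse(groups == "CN", "CN",
                              ifelse(groups == "amnestic", "aAD", "PCA")),
                       levels = tractopo:::PHENOTYPE_LEVELS),
    age_at_mri = round(rnorm(n, 65, 7), 1),
    sex = factor(sample(c("F", "M"), n, TRUE), levels = c("F", "M")),
    mmse = pmin(pmax(round(rnorm(n, 25, 3)), 0), 30),
    stringsAsFactors = FALSE
  )
}

# Long w-score table from a participants x targets value matrix.
wtable_from_matrix <- function(vals, records) {
  structure(
    data.frame(
      participant_id = rep(records$participant_id, times = ncol(vals)),
      target_id = rep(colnames(vals), each = nrow(vals)),
      w = as.vector(vals), stringsAsFactors = FALSE
    ),
    class = c("wscore_table", "data.frame")
  )
}

# Random weighted graph on n nodes: edge list + weights (for topology
# oracle tests).
random_graph <- function(n, p = 0.3) {
  pairs <- t(utils::combn(n, 2L))
  keep <- runif(nrow(pairs)) < p
  edges <- pairs[keep, , drop = FALSE]
  list(edges = edges, weights = runif(nrow(edges)), n = n)
}

# Independent component-count oracle via igraph (BFS-based).
igraph_components <- function(edges, n_nodes) {
  g <- igraph::make_empty_graph(n = n_nodes, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  as.integer(igraph::components(g)$no)
}

# Exhaustive monotone-lattice-path enumeration: for grid size q, returns
# the vector of max |x - y| over all C(2q, q) paths.
enumerate_path_deviations <- function(q) {
  pos <- utils::combn(2L * q, q) # positions of the q "right" steps
  apply(pos, 2L, function(rs) {
    steps <- rep(-1L, 2L * q)
    steps[rs] <- 1L
    max(abs(cumsum(steps)))
  })
}
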