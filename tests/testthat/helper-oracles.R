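# Independent oracles and fixture builders shared across tests.

# Exhaustive-enumeration parsimony: minimum number of edges with differing
# endpoint states over ALL labelings of the internal nodes, plus the set of
# states each internal node takes in at least one optimal labeling.
# Deliberately brute force; only usable on tiny trees.
brute_force_parsimony <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  alphabet <- seq(min(tree$tip_cn), max(tree$tip_cn))
  internal <- setdiff(seq_len(nnode), seq_len(ntip))
  grid <- as.matrix(expand.grid(rep(list(alphabet), length(internal))))
  states <- matrix(0L, nrow = nrow(grid), ncol = nnode)
  states[, seq_len(ntip)] <- matrix(tree$tip_cn, nrow = nrow(grid),
                                    ncol = ntip, byrow = TRUE)
  states[, internal] <- grid
  cost <- rep(0L, nrow(grid))
  for (k in seq_len(nrow(tree$edge))) {
    cost <- cost + (states[, tree$edge[k, 1]] != states[, tree$edge[k, 2]])
  }
  best <- min(cost)
  opt <- lapply(seq_len(nnode), function(v) sort(unique(states[cost == best, v])))
  list(min_cost = best, optimal_sets = opt)
}

# random rooted tree (binary, sometimes with one polytomy) with random
# integer tip states from a small alphabet
random_state_tree <- function(n_tips, n_states, seed, polytomy = FALSE) {
  set.seed(seed)
  tree <- ape::rtree(n_tips)
  if (polytomy && n_tips >= 4) {
    internal_edges <- which(tree$edge[, 2] > n_tips)
    if (length(internal_edges) > 0) {
      tree$edge.length[sample(internal_edges, 1)] <- 0
      tree <- ape::di2multi(tree, tol = 1e-8)
    }
  }
  states <- sample(seq(5, 4 + n_states), n_tips, replace = TRUE)
  attach_tip_states(tree, stats::setNames(states, tree$tip.label))
}

# small region set on a toy chromosome: four gene regions, a reference
# interval, survey 1..100000, all aligned awkwardly against 5 kb windows
toy_regions <- function() {
  region_set(regions = list("1" = c(20001, 28000), "2" = c(35001, 41000),
                            "3" = c(52001, 56000), "4" = c(63001, 67000)),
             reference_interval = c(75001, 95000),
             survey_interval = c(1, 100000))
}

# interval depth table (0-based half-open) with constant depth over a span
depth_table <- function(start0, end, depth) {
  data.frame(chrom = "Y", start = start0, end = end, depth = depth)
}
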