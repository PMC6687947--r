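test_that("read_cn_tree and attach_tip_states parse, validate and round-trip", {
  tree <- read_cn_tree("((A:1,B:2):1,C:3);")
  expect_equal(sort(tree$tip.label), c("A", "B", "C"))
  tree <- attach_tip_states(tree, c(A = 8, B = 8, C = 6))
  expect_equal(tree$tip_cn, unname(c(A = 8, B = 8, C = 6)[tree$tip.label]))

  expect_error(attach_tip_states(tree, c(A = 8, Z = 5)), "Z")
  expect_error(attach_tip_states(read_cn_tree("((A:1,B:2):1,C:3);"),
                                 c(A = 8, B = 8)), "without")
  pruned <- attach_tip_states(read_cn_tree("((A:1,B:2):1,C:3);"),
                              c(A = 8, B = 7), prune_missing = TRUE)
  expect_equal(length(pruned$tip.label), 2)

  # serialization round trip preserves topology and branch lengths
  set.seed(5)
  t0 <- ape::rtree(12)
  path <- tempfile(fileext = ".nwk")
  on.exit(unlink(path))
  ape::write.tree(t0, path)
  t1 <- read_cn_tree(path)
  expect_equal(sort(t1$tip.label), sort(t0$tip.label))
  d0 <- ape::cophenetic.phylo(t0); d1 <- ape::cophenetic.phylo(t1)
  expect_equal(d1[rownames(d0), colnames(d0)], d0, tolerance = 1e-9)
})

test_that("min_event_labeling handles the canonical small cases", {
  # constant states -> zero events
  t1 <- attach_tip_states(read_cn_tree("((A:1,B:1):1,(C:1,D:1):1);"),
                          c(A = 8, B = 8, C = 8, D = 8))
  expect_equal(min_event_labeling(t1)$event_count, 0)

  # one divergent tip -> one event on its pendant edge
  t2 <- attach_tip_states(read_cn_tree("((A:1,B:1):1,(C:1,D:1):1);"),
                          c(A = 8, B = 8, C = 8, D = 6))
  asg <- min_event_labeling(t2)
  expect_equal(asg$event_count, 1)
  ev <- classify_events(asg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$edge_child_id, "D")
  expect_equal(ev$direction, "decrease")
  expect_equal(ev$magnitude, 2)
  expect_true(ev$confident)

  # sister pair 11 vs 8 under an 8-state outgroup: one confident increase of 3
  t3 <- attach_tip_states(read_cn_tree("((HG02020:1,HG02032:1):1,OUT:2);"),
                          c(HG02020 = 11, HG02032 = 8, OUT = 8))
  ev3 <- classify_events(min_event_labeling(t3))
  expect_equal(nrow(ev3), 1)
  expect_equal(ev3$edge_child_id, "HG02020")
  expect_equal(ev3$direction, "increase")
  expect_equal(ev3$magnitude, 3)

  expect_error(min_event_labeling(read_cn_tree("((A:1,B:1):1,C:1);")), "states")
})

test_that("parsimony equals exhaustive enumeration on random small trees", {
  # 60 random instances here; the full 200-instance sweep runs in the
  # acceptance suite
  for (i in 1:60) {
    tree <- random_state_tree(n_tips = sample(4:8, 1), n_states = sample(2:4, 1),
                              seed = 9000 + i, polytomy = i %% 3 == 0)
    got <- min_event_labeling(tree)
    oracle <- brute_force_parsimony(tree)
    expect_equal(got$event_count, oracle$min_cost,
                 info = sprintf("instance %d", i))
    # per-node optimal-state sets must match the enumeration
    for (v in seq_along(oracle$optimal_sets)) {
      expect_equal(sort(got$optimal_sets[[v]]), oracle$optimal_sets[[v]],
                   info = sprintf("instance %d node %d", i, v))
    }
    expect_identical(got$ambiguous,
                     vapply(oracle$optimal_sets, length, integer(1)) > 1)
  }
})

test_that("ambiguous endpoints yield ambiguous-direction, non-confident events", {
  # chain root -> x -> tip(10) with an 8-state sibling: x can be 8 or 10
  tree <- structure(list(edge = rbind(c(3L, 1L), c(3L, 4L), c(4L, 2L)),
                         tip.label = c("A", "B"), Nnode = 2L,
                         edge.length = c(1, 1, 1)),
                    class = "phylo", order = "cladewise")
  tree <- attach_tip_states(tree, c(A = 8, B = 10))
  asg <- min_event_labeling(tree)
  expect_equal(asg$event_count, 1)
  expect_true(asg$ambiguous[4])
  ev <- classify_events(asg)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "ambiguous")
  expect_false(ev$confident)
  tot <- attr(ev, "totals")
  expect_equal(unname(tot[c("increase", "decrease", "ambiguous", "total")]),
               c(0, 0, 1, 1))
})

test_that("clade_mode_labeling takes subtree modes with parent-ward ties", {
  # majority: tips (8, 8, 10) -> internal node 8
  t1 <- attach_tip_states(read_cn_tree("((A:1,B:1):1,C:1);"),
                          c(A = 8, B = 8, C = 10))
  a1 <- clade_mode_labeling(t1)
  expect_equal(a1$states[4], 8)   # root
  expect_equal(a1$states[5], 8)   # (A,B) clade

  # tie inside a cherry resolves toward the parent's state
  t2 <- attach_tip_states(read_cn_tree("(((A:1,B:1):1,C:1):1,(D:1,E:1):1);"),
                          c(A = 8, B = 10, C = 10, D = 10, E = 10))
  a2 <- clade_mode_labeling(t2)
  ix_root <- length(t2$tip.label) + 1
  expect_equal(a2$states[ix_root], 10)
  cherry_node <- t2$edge[t2$edge[, 2] == which(t2$tip.label == "A"), 1]
  expect_equal(a2$states[cherry_node], 10)  # tie {8, 10} -> parent's 10

  # clade-mode event count never beats the parsimony minimum
  for (i in 1:20) {
    tree <- random_state_tree(20, n_states = 3, seed = 500 + i)
    expect_gte(clade_mode_labeling(tree)$event_count,
               min_event_labeling(tree)$event_count)
  }
})

test_that("filter_events applies magnitude and range rules", {
  mk <- function(ps, cs) {
    n <- length(ps)
    structure(data.frame(edge_child_id = paste0("e", seq_len(n)),
                         parent_node = rep(1L, n), child_node = seq_len(n) + 1L,
                         parent_state = ps, child_state = cs,
                         magnitude = abs(cs - ps),
                         direction = ifelse(cs > ps, "increase", "decrease"),
                         confident = TRUE),
              totals = c(increase = sum(cs > ps), decrease = sum(cs < ps),
                         ambiguous = 0, total = n),
              class = c("cn_events", "data.frame"))
  }
  ev <- mk(c(8, 8, 13), c(6, 7, 8))
  f <- filter_events(ev, min_magnitude = 2, cn_range = c(5, 12))
  expect_equal(nrow(f), 1)                    # 8->6 kept
  expect_equal(f$parent_state, 8); expect_equal(f$child_state, 6)
  # 8->7 dropped (magnitude), 13->8 dropped (endpoint out of range)

  # cross-check against a plain filtering oracle on 20 random events
  set.seed(77)
  ps <- sample(3:15, 20, replace = TRUE)
  cs <- ps + sample(c(-4:-1, 1:4), 20, replace = TRUE)
  ev20 <- mk(ps, cs)
  f20 <- filter_events(ev20, min_magnitude = 2, cn_range = c(5, 12))
  keep <- abs(cs - ps) >= 2 & ps >= 5 & ps <= 12 & cs >= 5 & cs <= 12
  expect_equal(f20$edge_child_id, ev20$edge_child_id[keep])
  # filters never increase counts
  expect_lte(nrow(f20), nrow(ev20))
  expect_true(all(attr(f20, "totals") <= attr(ev20, "totals")))
})

test_that("direction totals always add up on random trees", {
  for (i in 1:15) {
    tree <- random_state_tree(15, n_states = 4, seed = 700 + i,
                              polytomy = i %% 2 == 0)
    ev <- classify_events(min_event_labeling(tree))
    tot <- attr(ev, "totals")
    expect_equal(unname(tot[["increase"]] + tot[["decrease"]] +
                          tot[["ambiguous"]]), unname(tot[["total"]]))
    expect_true(all(ev$magnitude >= 1))
    expect_true(all(!ev$confident | ev$direction != "ambiguous"))
  }
})

test_that("scale_confident_histogram uses largest-remainder rounding", {
  expect_equal(scale_confident_histogram(c("1" = 10, "2" = 5), 30),
               c("1" = 20L, "2" = 10L))

  s <- scale_confident_histogram(c("1" = 1, "2" = 1, "3" = 1), 10)
  expect_equal(sum(s), 10)
  expect_true(all(abs(s - 10 / 3) <= 1))

  # scaling 176 confident events up to 562 reproduces the genome-wide
  # size-class counts within +/-2 when the confident histogram is
  # proportional to those classes
  target <- c(dec1 = 227, dec2 = 54, dec3 = 16, dec4 = 13, dec5 = 3,
              inc1 = 185, inc2 = 42, inc3 = 19, inc4 = 4)
  raw <- target * 176 / sum(target)
  conf <- floor(raw)
  extra <- order(raw - conf, decreasing = TRUE)[seq_len(176 - sum(conf))]
  conf[extra] <- conf[extra] + 1
  expect_equal(sum(conf), 176)
  up <- scale_confident_histogram(conf, 562)
  expect_equal(sum(up), 562)
  expect_true(all(abs(up - target) <= 2))

  expect_error(scale_confident_histogram(numeric(0), 10), "empty")
  expect_error(scale_confident_histogram(c("1" = 10), 5), ">=")
})
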