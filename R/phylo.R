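#' Read a rooted tree and attach per-tip copy-number states
#'
#' Trees are consumed as Newick via ape; branch lengths are SNV counts.
#' Tip states are attached as an integer vector `tree$tip_cn` aligned with
#' `tree$tip.label`.
#'
#' @param newick path to a Newick file or a Newick string.
#' @return an ape `phylo` object (rooted).
#' @export
read_cn_tree <- function(newick) {
  tree <- if (file.exists(newick)) ape::read.tree(newick) else ape::read.tree(text = newick)
  if (is.null(tree)) stop("could not parse Newick input", call. = FALSE)
  if (anyDuplicated(tree$tip.label))
    stop(sprintf("duplicate tip label(s): %s",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")), call. = FALSE)
  # the Newick nesting fixes the root; basal polytomies are allowed (ape
  # would call such a tree "unrooted", but the node is unique)
  tree
}

#' @param tree an ape `phylo` object.
#' @param states data.frame with columns `sample_id` and `copy_number`, or a
#'   named integer vector.
#' @param prune_missing drop tips without a state instead of erroring.
#' @rdname read_cn_tree
#' @export
attach_tip_states <- function(tree, states, prune_missing = FALSE) {
  stopifnot(inherits(tree, "phylo"))
  if (is.data.frame(states)) {
    stopifnot(all(c("sample_id", "copy_number") %in% names(states)))
    cn <- stats::setNames(as.integer(states$copy_number), states$sample_id)
  } else {
    cn <- stats::setNames(as.integer(states), names(states))
  }
  unknown <- setdiff(names(cn), tree$tip.label)
  if (length(unknown) > 0)
    stop(sprintf("state table contains unknown tip id(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  if (any(cn < 0, na.rm = TRUE)) stop("copy numbers must be >= 0", call. = FALSE)
  missing <- setdiff(tree$tip.label, names(cn))
  if (length(missing) > 0) {
    if (!prune_missing)
      stop(sprintf("tip(s) without copy-number state: %s",
                   paste(utils::head(missing, 5), collapse = ", ")), call. = FALSE)
    tree <- ape::drop.tip(tree, missing)
  }
  tree$tip_cn <- unname(cn[tree$tip.label])
  tree
}

# children lists and a postorder over edges for a (possibly multifurcating)
# rooted phylo
tree_index <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  po <- ape::reorder.phylo(tree, "postorder")
  list(ntip = ntip, nnode = nnode, root = root,
       edge = po$edge, edge_length = po$edge.length)
}

#' Minimum-event (unit-cost parsimony) ancestral labeling
#'
#' Counts the minimum number of copy-number change events needed to explain
#' the tip states on the rooted tree, where any change on an edge costs one
#' event regardless of magnitude. The dynamic programme runs over the state
#' alphabet formed by all integers between the smallest and largest observed
#' tip state (allowing pass-through states) and handles multifurcations
#' natively. Besides one optimal labeling (ties broken toward the parent
#' state, then the smaller state) it computes, per node, the full set of
#' states attainable in at least one globally optimal labeling; nodes with
#' more than one such state carry an ambiguity flag.
#'
#' @param tree a `phylo` with `tip_cn` attached (see [attach_tip_states()]).
#' @return an object of class `cn_assignment`: list with `states` (integer
#'   vector over all nodes, tips first), `ambiguous` (logical), `optimal_sets`
#'   (list of integer vectors), `event_count`, `method = "min-event"`, `tree`.
#' @export
min_event_labeling <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip_cn)) stop("tree has no tip copy-number states", call. = FALSE)
  ix <- tree_index(tree)
  if (ix$ntip < 2) stop("tree must have at least 2 tips", call. = FALSE)
  alphabet <- seq(min(tree$tip_cn), max(tree$tip_cn))
  ns <- length(alphabet)

  # downpass: cost[v, s] = min events in subtree of v given v has state s
  cost <- matrix(Inf, nrow = ix$nnode, ncol = ns)
  for (i in seq_len(ix$ntip)) cost[i, match(tree$tip_cn[i], alphabet)] <- 0
  internal <- unique(ix$edge[, 1])
  cost[internal, ] <- 0
  for (k in seq_len(nrow(ix$edge))) {      # postorder: children before parents
    par <- ix$edge[k, 1]; chd <- ix$edge[k, 2]
    cc <- cost[chd, ]
    cost[par, ] <- cost[par, ] + pmin(cc, min(cc) + 1)
  }
  event_count <- min(cost[ix$root, ])

  # uppass 1: one optimal labeling, ties toward the parent state
  states <- integer(ix$nnode)
  states[seq_len(ix$ntip)] <- tree$tip_cn
  rs <- which(cost[ix$root, ] == event_count)
  states[ix$root] <- alphabet[rs[1]]
  pre <- rev(seq_len(nrow(ix$edge)))       # reverse postorder = preorder
  for (k in pre) {
    par <- ix$edge[k, 1]; chd <- ix$edge[k, 2]
    if (chd <= ix$ntip) next
    sp <- match(states[par], alphabet)
    tot <- cost[chd, ] + 1
    tot[sp] <- cost[chd, sp]
    best <- which(tot == min(tot))
    states[chd] <- if (sp %in% best) alphabet[sp] else alphabet[best[1]]
  }

  # uppass 2: per-node sets of states attainable in some optimal labeling
  opt <- vector("list", ix$nnode)
  for (i in seq_len(ix$ntip)) opt[[i]] <- tree$tip_cn[i]
  opt[[ix$root]] <- alphabet[rs]
  for (k in pre) {
    par <- ix$edge[k, 1]; chd <- ix$edge[k, 2]
    if (chd <= ix$ntip) next
    cc <- cost[chd, ]
    mc <- min(cc)
    sel <- rep(FALSE, ns)
    for (s in match(opt[[par]], alphabet)) {
      target <- min(cc[s], mc + 1)
      # child takes state t at cost cc[t] + (t != s); keep optimal t
      sel <- sel | (cc + 1 == target)
      if (cc[s] == target) sel[s] <- TRUE
    }
    opt[[chd]] <- alphabet[sel]
  }
  ambiguous <- vapply(opt, length, integer(1)) > 1

  structure(list(states = states, ambiguous = ambiguous, optimal_sets = opt,
                 event_count = event_count, method = "min-event", tree = tree),
            class = "cn_assignment")
}

#' Clade-modal ancestral labeling
#'
#' The heuristic that assigns each internal node the most common copy number
#' among the tips of its subtree. Ties are resolved toward the parent's
#' resolved state; a tie at the root resolves to the global modal tip state
#' if it is among the tied candidates, then to the smaller copy number.
#' Provided for comparison with [min_event_labeling()]; its implied event
#' count is never below the parsimony minimum.
#'
#' @param tree a `phylo` with `tip_cn` attached.
#' @return a `cn_assignment` with `method = "clade-mode"` (no ambiguity
#'   flags; `event_count` is the number of edges whose endpoint states
#'   differ).
#' @export
clade_mode_labeling <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$tip_cn)) stop("tree has no tip copy-number states", call. = FALSE)
  ix <- tree_index(tree)
  if (ix$ntip < 2) stop("tree must have at least 2 tips", call. = FALSE)
  alphabet <- sort(unique(tree$tip_cn))
  ns <- length(alphabet)

  # tip-state counts per subtree (postorder accumulation)
  counts <- matrix(0L, nrow = ix$nnode, ncol = ns)
  for (i in seq_len(ix$ntip)) counts[i, match(tree$tip_cn[i], alphabet)] <- 1L
  for (k in seq_len(nrow(ix$edge)))
    counts[ix$edge[k, 1], ] <- counts[ix$edge[k, 1], ] + counts[ix$edge[k, 2], ]

  candidates <- lapply(seq_len(ix$nnode), function(v) {
    alphabet[counts[v, ] == max(counts[v, ])]
  })
  states <- integer(ix$nnode)
  states[seq_len(ix$ntip)] <- tree$tip_cn
  root_cand <- candidates[[ix$root]]
  global_mode <- alphabet[which.max(counts[ix$root, ])]  # smallest on tie
  states[ix$root] <- if (global_mode %in% root_cand) global_mode else min(root_cand)
  for (k in rev(seq_len(nrow(ix$edge)))) {               # preorder
    par <- ix$edge[k, 1]; chd <- ix$edge[k, 2]
    if (chd <= ix$ntip) next
    cand <- candidates[[chd]]
    states[chd] <- if (states[par] %in% cand) states[par] else min(cand)
  }
  event_count <- sum(states[ix$edge[, 1]] != states[ix$edge[, 2]])
  structure(list(states = states, ambiguous = rep(FALSE, ix$nnode),
                 optimal_sets = as.list(states), event_count = event_count,
                 method = "clade-mode", tree = tree),
            class = "cn_assignment")
}

#' Classify copy-number change events from an ancestral labeling
#'
#' One event per edge whose endpoint states differ. Direction is the sign of
#' (child - parent); when either endpoint is ambiguous across optimal
#' labelings the direction is recorded as "ambiguous" and the event is not
#' confident. Confident events (both endpoints unambiguous) are the ones
#' whose magnitude histogram can be scaled to the total.
#'
#' @param assignment a `cn_assignment`.
#' @return an object of class `cn_events`: data.frame of events with
#'   attributes `totals` (counts per direction) and `magnitude_totals`.
#' @export
classify_events <- function(assignment) {
  stopifnot(inherits(assignment, "cn_assignment"))
  tree <- assignment$tree
  ix <- tree_index(tree)
  par <- ix$edge[, 1]; chd <- ix$edge[, 2]
  ps <- assignment$states[par]; cs <- assignment$states[chd]
  sel <- ps != cs
  amb <- assignment$ambiguous[par] | assignment$ambiguous[chd]
  dir <- ifelse(amb, "ambiguous", ifelse(cs > ps, "increase", "decrease"))
  child_id <- ifelse(chd <= ix$ntip, tree$tip.label[chd], paste0("node", chd))
  ev <- data.frame(edge_child_id = child_id[sel],
                   parent_node = par[sel], child_node = chd[sel],
                   parent_state = ps[sel], child_state = cs[sel],
                   magnitude = abs(cs - ps)[sel],
                   direction = dir[sel],
                   confident = !amb[sel],
                   stringsAsFactors = FALSE)
  totals <- c(increase = sum(ev$direction == "increase"),
              decrease = sum(ev$direction == "decrease"),
              ambiguous = sum(ev$direction == "ambiguous"),
              total = nrow(ev))
  structure(ev, totals = totals,
            magnitude_totals = table(factor(ev$magnitude)),
            class = c("cn_events", "data.frame"))
}

#' Filter events by magnitude and endpoint copy-number range
#'
#' The conservative filter: keep only events of magnitude at least
#' `min_magnitude` whose both endpoint states lie within `cn_range`
#' (the published analysis used magnitude >= 2 and range [5, 12]).
#'
#' @param events a `cn_events`.
#' @param min_magnitude minimum |change| to keep (default 1 = keep all).
#' @param cn_range inclusive `c(low, high)` bounds on both endpoint states.
#' @return filtered `cn_events`.
#' @export
filter_events <- function(events, min_magnitude = 1, cn_range = c(0, Inf)) {
  stopifnot(inherits(events, "cn_events"))
  if (cn_range[1] > cn_range[2]) stop("cn_range low must be <= high", call. = FALSE)
  keep <- events$magnitude >= min_magnitude &
    events$parent_state >= cn_range[1] & events$parent_state <= cn_range[2] &
    events$child_state >= cn_range[1] & events$child_state <= cn_range[2]
  ev <- events[keep, , drop = FALSE]
  totals <- c(increase = sum(ev$direction == "increase"),
              decrease = sum(ev$direction == "decrease"),
              ambiguous = sum(ev$direction == "ambiguous"),
              total = nrow(ev))
  structure(ev, totals = totals,
            magnitude_totals = table(factor(ev$magnitude)),
            class = c("cn_events", "data.frame"))
}

#' Scale a confident-event magnitude histogram to a total event count
#'
#' Events whose ancestral state is clear are a subset of all inferred events;
#' their magnitude histogram is scaled up so the classes sum to the total
#' event count, using largest-remainder rounding (so the scaled counts are
#' integers that sum exactly to `total_events`).
#'
#' @param confident named numeric vector, magnitude class -> count.
#' @param total_events target total (>= sum of `confident`).
#' @return named integer vector summing to `total_events`.
#' @export
scale_confident_histogram <- function(confident, total_events) {
  if (length(confident) == 0) stop("empty confident histogram", call. = FALSE)
  s <- sum(confident)
  if (s <= 0) stop("confident histogram must have positive total", call. = FALSE)
  if (total_events < s) stop("total_events must be >= sum(confident)", call. = FALSE)
  scaled <- confident * total_events / s
  base <- floor(scaled)
  short <- round(total_events - sum(base))
  if (short > 0) {
    extra <- order(scaled - base, decreasing = TRUE)[seq_len(short)]
    base[extra] <- base[extra] + 1
  }
  stats::setNames(as.integer(base), names(confident))
}

#' Write an event set to TSV
#'
#' @param events a `cn_events`.
#' @param path output path.
#' @export
write_events_tsv <- function(events, path) {
  stopifnot(inherits(events, "cn_events"))
  utils::write.table(events[, c("edge_child_id", "parent_state", "child_state",
                                "magnitude", "direction", "confident")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.cn_assignment <- function(x, ...) {
  cat(sprintf("Ancestral copy-number assignment (%s): %d nodes, %d events\n",
              x$method, length(x$states), x$event_count))
  if (any(x$ambiguous))
    cat(sprintf("  %d node(s) ambiguous across optimal labelings\n",
                sum(x$ambiguous)))
  invisible(x)
}
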