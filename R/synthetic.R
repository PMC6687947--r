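#' Default signed event-size distribution
#'
#' Weights proportional to the inferred genome-wide event-size histogram:
#' decreases of 1..5 copies (227/54/16/13/3) and increases of 1..4 copies
#' (185/42/19/4). Names are signed magnitudes, values are weights.
#'
#' @return named numeric vector of weights.
#' @export
default_size_distribution <- function() {
  cfg <- neutral_sim_config()
  stats::setNames(c(unname(cfg$decreases), unname(cfg$increases)),
                  c(paste0("-", names(cfg$decreases)), names(cfg$increases)))
}

#' Simulate a rooted binary tree with SNV-count branch lengths
#'
#' Generates a Yule (pure-birth) or Kingman coalescent topology, rescales
#' branch lengths (in generations) so the total tree length matches the
#' target, and draws per-branch SNV counts as Poisson with mean
#' generations / generations-per-SNV, mirroring the molecular-clock
#' calibration in which one SNV corresponds to about 4.26 generations.
#' The returned `phylo` carries SNV counts in `edge.length` and the
#' underlying generation lengths in `edge.generations`.
#'
#' @param n_tips number of tips (>= 2).
#' @param model "yule" or "kingman".
#' @param total_generations_target target total branch length in generations.
#' @param seed integer seed.
#' @param clock a `clock_constants` (sets generations per SNV).
#' @return a rooted `phylo`.
#' @export
simulate_tree <- function(n_tips, model = c("yule", "kingman"),
                          total_generations_target = 250000, seed = 1,
                          clock = clock_constants()) {
  if (n_tips < 2) stop("n_tips must be >= 2", call. = FALSE)
  model <- match.arg(model)
  set.seed(as.integer(seed))
  tree <- switch(model,
                 yule = ape::rphylo(n_tips, birth = 1, death = 0),
                 kingman = ape::rcoal(n_tips))
  tree$edge.generations <- tree$edge.length *
    total_generations_target / sum(tree$edge.length)
  gps <- snv_to_generations(1, clock)$generations_per_snv
  tree$edge.length <- stats::rpois(nrow(tree$edge), tree$edge.generations / gps)
  tree$tip.label <- sprintf("t%03d", seq_len(n_tips))
  tree
}

#' Evolve copy-number states along a tree under a known event process
#'
#' Each edge receives a Poisson(rate x edge generations) number of events
#' with signed sizes drawn from `size_distribution`. Tip copy number is the
#' root state plus the path sum of signed events, floored at zero (or, when
#' `bounds` is given, reflected into the bounded interval node by node —
#' used to emulate stabilizing selection). The full ground truth (event
#' placements, realized tip states, realized rate) is recorded.
#'
#' @param tree a `phylo` from [simulate_tree()] (needs `edge.generations`).
#' @param rate events per generation (father-to-son transmission).
#' @param size_distribution named weights over signed sizes
#'   (default [default_size_distribution()]).
#' @param root_cn ancestral copy number (default 8).
#' @param seed integer seed.
#' @param floor_at_zero floor tip states at 0 (default TRUE).
#' @param bounds optional `c(low, high)`; node states are reflected into
#'   the interval (overrides flooring).
#' @return an object of class `synthetic_truth`: list with `tree` (with
#'   `tip_cn` attached), `true_events` (data.frame edge/child/size),
#'   `true_tip_cn` (named), `true_event_count`, `true_rate`,
#'   `total_generations`, `root_cn`, `seed`.
#' @export
evolve_cn <- function(tree, rate, size_distribution = default_size_distribution(),
                      root_cn = 8, seed = 1, floor_at_zero = TRUE,
                      bounds = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (rate < 0) stop("rate must be >= 0", call. = FALSE)
  gens <- if (!is.null(tree$edge.generations)) tree$edge.generations else tree$edge.length
  ix <- tree_index(tree)
  # tree_index reorders edges; reorder generation lengths to match
  key_in <- paste(tree$edge[, 1], tree$edge[, 2])
  key_po <- paste(ix$edge[, 1], ix$edge[, 2])
  gens <- gens[match(key_po, key_in)]

  set.seed(as.integer(seed))
  sizes <- as.integer(names(size_distribution))
  nev_per_edge <- stats::rpois(nrow(ix$edge), rate * gens)
  total_events <- sum(nev_per_edge)
  ev_sizes <- if (total_events > 0)
    sample(sizes, total_events, replace = TRUE,
           prob = size_distribution / sum(size_distribution))
  else integer(0)
  ev_edge <- rep.int(seq_len(nrow(ix$edge)), nev_per_edge)

  delta <- numeric(nrow(ix$edge))
  if (total_events > 0) {
    agg <- rowsum(ev_sizes, ev_edge)
    delta[as.integer(rownames(agg))] <- agg[, 1]
  }
  node_cn <- numeric(ix$nnode)
  node_cn[ix$root] <- root_cn
  for (k in rev(seq_len(nrow(ix$edge)))) {    # preorder
    val <- node_cn[ix$edge[k, 1]] + delta[k]
    if (!is.null(bounds)) {
      while (val < bounds[1] || val > bounds[2]) {
        if (val > bounds[2]) val <- 2 * bounds[2] - val
        if (val < bounds[1]) val <- 2 * bounds[1] - val
      }
    }
    node_cn[ix$edge[k, 2]] <- val
  }
  tip_cn <- node_cn[seq_len(ix$ntip)]
  if (is.null(bounds) && floor_at_zero) tip_cn <- pmax(0, tip_cn)
  tip_cn <- as.integer(tip_cn)

  tree$tip_cn <- tip_cn
  total_generations <- sum(gens)
  structure(list(tree = tree,
                 true_events = data.frame(edge = ev_edge,
                                          child_node = ix$edge[ev_edge, 2],
                                          size = ev_sizes),
                 true_tip_cn = stats::setNames(tip_cn, tree$tip.label),
                 true_event_count = total_events,
                 true_rate = total_events / total_generations,
                 total_generations = total_generations,
                 root_cn = root_cn, seed = seed),
            class = "synthetic_truth")
}

#' Emulate a windowed depth profile under the read-pooling model
#'
#' Reads from every gene copy pool uniformly onto the fixed reference
#' footprint, so all windows overlapping the gene regions carry depth
#' base_depth x (gene copies + pseudogene equivalents) / reference
#' copy-equivalents, while the reference interval and the rest of the
#' survey stay at base_depth. Optional Poisson noise resamples each
#' window's read mass.
#'
#' @param cn_by_region named numeric map region -> gene copies (only the
#'   total matters under pooling).
#' @param base_depth single-copy mean depth in reads.
#' @param noise "none" or "poisson".
#' @param regions a `region_set`.
#' @param model a `copy_model`.
#' @param window_size window width in bp.
#' @param seed integer seed (used for Poisson noise).
#' @param sample_id sample label.
#' @return a `depth_profile`.
#' @export
emulate_depth <- function(cn_by_region, base_depth = 10,
                          noise = c("none", "poisson"),
                          regions = region_set(), model = copy_model(),
                          window_size = 5000, seed = 1, sample_id = "synth") {
  noise <- match.arg(noise)
  if (base_depth <= 0) stop("base_depth must be > 0", call. = FALSE)
  total_equiv <- sum(cn_by_region) + model$pseudogene_equivalents
  factor <- total_equiv / model$copy_equivalents_reference

  sv <- regions$survey_interval
  wstart <- seq(sv[1], sv[2], by = window_size)
  wend <- pmin(wstart + window_size - 1, sv[2])
  in_region <- rep(FALSE, length(wstart))
  for (iv in regions$regions)
    in_region <- in_region | interval_overlap(wstart, wend, iv[1], iv[2]) > 0
  depth <- ifelse(in_region, base_depth * factor, base_depth)
  if (noise == "poisson") {
    set.seed(as.integer(seed))
    width <- wend - wstart + 1
    depth <- stats::rpois(length(depth), depth * width) / width
  }
  structure(list(sample_id = sample_id, window_size = window_size,
                 windows = data.frame(start = wstart, end = wend,
                                      mean_depth = depth)),
            class = "depth_profile")
}

#' Emulate a two-channel droplet well for a known copy number
#'
#' Reference positives are Binomial(droplets, 1 - exp(-lambda_ref)) and
#' target positives Binomial(droplets, 1 - exp(-lambda_ref * true_cn)):
#' the target template is true_cn times as concentrated as the single-copy
#' reference.
#'
#' @param true_cn true copy number (real-valued allowed).
#' @param droplets droplet count (default 12000).
#' @param mean_ref_lambda reference channel occupancy (default 0.1; must be
#'   in (0, 5)).
#' @param seed integer seed.
#' @param assay assay label ("T" or "C").
#' @param sample_id sample label.
#' @return list with the well fields plus `true_cn` and `true_lambda_*`.
#' @export
emulate_droplets <- function(true_cn, droplets = 12000, mean_ref_lambda = 0.1,
                             seed = 1, assay = "T", sample_id = "synth") {
  if (droplets <= 0) stop("droplets must be > 0", call. = FALSE)
  if (mean_ref_lambda <= 0 || mean_ref_lambda >= 5)
    stop("mean_ref_lambda must be in (0, 5)", call. = FALSE)
  lam_t <- mean_ref_lambda * true_cn
  if (lam_t > 5)
    warning("saturation risk: target occupancy lambda exceeds 5", call. = FALSE)
  set.seed(as.integer(seed))
  ref_pos <- stats::rbinom(1, droplets, 1 - exp(-mean_ref_lambda))
  tgt_pos <- stats::rbinom(1, droplets, 1 - exp(-lam_t))
  list(sample_id = sample_id, assay = assay,
       target_positive = tgt_pos, target_total = droplets,
       reference_positive = ref_pos, reference_total = droplets,
       droplet_volume = 0.85,
       true_cn = true_cn, true_lambda_ref = mean_ref_lambda,
       true_lambda_target = lam_t, seed = seed)
}

#' Simulate father-son copy-number pairs
#'
#' Each son independently mutates with probability `rate` (one
#' transmission); mutated sons shift by a signed size drawn from
#' `size_distribution`, floored at zero.
#'
#' @param n_pairs number of pairs.
#' @param rate per-transmission mutation probability.
#' @param size_distribution named weights over signed sizes.
#' @param root_cn father copy number (default 8).
#' @param seed integer seed.
#' @return list with `pairs` (data.frame father_cn, son_cn, mutated) and
#'   `true_mutation_count`.
#' @export
make_father_son <- function(n_pairs, rate,
                            size_distribution = default_size_distribution(),
                            root_cn = 8, seed = 1) {
  if (n_pairs < 1) stop("n_pairs must be >= 1", call. = FALSE)
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]", call. = FALSE)
  set.seed(as.integer(seed))
  mutated <- stats::rbinom(n_pairs, 1, rate) == 1
  sizes <- as.integer(names(size_distribution))
  shift <- integer(n_pairs)
  if (any(mutated))
    shift[mutated] <- sample(sizes, sum(mutated), replace = TRUE,
                             prob = size_distribution / sum(size_distribution))
  pairs <- data.frame(pair_id = sprintf("p%03d", seq_len(n_pairs)),
                      father_cn = root_cn,
                      son_cn = pmax(0, root_cn + shift),
                      mutated = mutated)
  list(pairs = pairs, true_mutation_count = sum(mutated), rate = rate,
       seed = seed)
}

#' Emit a full synthetic input bundle
#'
#' Writes everything the pipeline consumes, with ground truth: `tree.nwk`
#' (SNV-count branch lengths), `cn.tsv` (tip copy numbers), `depth/` (one
#' windowed depth TSV per requested sample, Poisson noise),
#' `wells.csv` (two-channel droplet counts, two replicates per assay),
#' `trios.tsv` (father-son pairs) and `truth.json`.
#'
#' @param out_dir output directory (created if absent).
#' @param seed integer seed driving every generator.
#' @param n_tips tree size (default 100).
#' @param rate copy-number event rate per transmission (default 2.2e-3).
#' @param total_generations_target tree length in generations.
#' @param n_depth_samples how many tips also get a depth profile.
#' @param n_pairs father-son pairs (default 77).
#' @return invisibly, the truth list.
#' @export
simulate_all <- function(out_dir, seed = 1, n_tips = 100, rate = 2.2e-3,
                         total_generations_target = 250000,
                         n_depth_samples = 5, n_pairs = 77) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "depth"), showWarnings = FALSE)

  tree <- simulate_tree(n_tips, "kingman", total_generations_target,
                        seed = derive_seed(seed, 1))
  truth <- evolve_cn(tree, rate, seed = derive_seed(seed, 2))
  ape::write.tree(truth$tree, file.path(out_dir, "tree.nwk"))
  utils::write.table(data.frame(sample_id = names(truth$true_tip_cn),
                                copy_number = unname(truth$true_tip_cn)),
                     file.path(out_dir, "cn.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  depth_ids <- names(truth$true_tip_cn)[seq_len(min(n_depth_samples, n_tips))]
  for (i in seq_along(depth_ids)) {
    prof <- emulate_depth(c(pooled = unname(truth$true_tip_cn[depth_ids[i]])),
                          base_depth = 10, noise = "poisson",
                          seed = derive_seed(seed, 10 + i),
                          sample_id = depth_ids[i])
    w <- prof$windows
    utils::write.table(data.frame(chrom = "Y", start = w$start - 1,
                                  end = w$end, mean_depth = w$mean_depth),
                       file.path(out_dir, "depth", paste0(depth_ids[i], ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }

  wells <- do.call(rbind, lapply(seq_along(depth_ids), function(i) {
    cn <- unname(truth$true_tip_cn[depth_ids[i]])
    t_cn <- max(0, cn - 2); c_cn <- min(cn, 2)   # distal clusters hold ~2 copies
    do.call(rbind, lapply(1:2, function(rep_i) {
      wt <- emulate_droplets(t_cn, seed = derive_seed(seed, 100 + 4 * i + rep_i),
                             assay = "T", sample_id = depth_ids[i])
      wc <- emulate_droplets(c_cn, seed = derive_seed(seed, 300 + 4 * i + rep_i),
                             assay = "C", sample_id = depth_ids[i])
      data.frame(sample_id = depth_ids[i], assay = c("T", "C"),
                 replicate = rep_i,
                 target_positive = c(wt$target_positive, wc$target_positive),
                 target_total = c(wt$target_total, wc$target_total),
                 ref_positive = c(wt$reference_positive, wc$reference_positive),
                 ref_total = c(wt$reference_total, wc$reference_total))
    }))
  }))
  utils::write.csv(wells, file.path(out_dir, "wells.csv"), row.names = FALSE)

  trios <- make_father_son(n_pairs, rate = 0.013, seed = derive_seed(seed, 500))
  utils::write.table(trios$pairs, file.path(out_dir, "trios.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  truth_out <- list(seed = seed, n_tips = n_tips, rate = rate,
                    total_generations = truth$total_generations,
                    true_event_count = truth$true_event_count,
                    true_rate = truth$true_rate,
                    root_cn = truth$root_cn,
                    trio_mutations = trios$true_mutation_count,
                    depth_samples = depth_ids)
  jsonlite::write_json(truth_out, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(truth_out, list(truth = truth)))
}
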