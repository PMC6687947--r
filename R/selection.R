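#' Exact binomial test for direction bias among copy-number events
#'
#' Tests whether decrease events outnumber increase events (or vice versa)
#' beyond chance: two-sided exact binomial test of the decrease count against
#' p = 0.5 out of n = increases + decreases, with the standard convention
#' that the two-sided p sums all outcome probabilities not exceeding that of
#' the observed count. Also returns the decrease proportion and its exact
#' Clopper-Pearson interval.
#'
#' @param increases count of increase events.
#' @param decreases count of decrease events.
#' @param confidence confidence level for the proportion CI.
#' @return list with `p_value`, `proportion` (decreases / total), `ci`,
#'   `increases`, `decreases`.
#' @export
direction_bias_test <- function(increases, decreases, confidence = 0.95) {
  if (increases < 0 || decreases < 0 || increases + decreases < 1)
    stop("need non-negative counts with a positive total", call. = FALSE)
  n <- increases + decreases
  p <- stats::binom.test(decreases, n, p = 0.5)$p.value
  ci <- transmission_rate_ci(decreases, n, confidence)
  list(p_value = p, proportion = decreases / n,
       ci = c(ci$ci_low, ci$ci_high),
       increases = increases, decreases = decreases)
}

#' Configuration for the neutral copy-number simulator
#'
#' Defaults are the inferred genome-wide event-size histogram (confident
#' events scaled to the total): decreases of 1..5 copies with counts
#' 227/54/16/13/3 and increases of 1..4 copies with counts 185/42/19/4, an
#' ancestral (root) copy number of 8, 1000 replicates, and negative copy
#' numbers floored to zero.
#'
#' @param decreases named numeric vector, magnitude -> count.
#' @param increases named numeric vector, magnitude -> count.
#' @param root_cn ancestral copy number.
#' @param replicates number of neutral replicates.
#' @param floor_at_zero treat negative tip copy numbers as zero.
#' @param sample_variance use the n-1 (sample) variance instead of the
#'   population variance.
#' @return an object of class `neutral_sim_config`.
#' @export
neutral_sim_config <- function(decreases = c("1" = 227, "2" = 54, "3" = 16,
                                             "4" = 13, "5" = 3),
                               increases = c("1" = 185, "2" = 42, "3" = 19,
                                             "4" = 4),
                               root_cn = 8, replicates = 1000,
                               floor_at_zero = TRUE, sample_variance = FALSE) {
  if (any(c(decreases, increases) < 0))
    stop("event counts must be >= 0", call. = FALSE)
  if (root_cn < 0) stop("root_cn must be >= 0", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  structure(list(decreases = decreases, increases = increases,
                 root_cn = root_cn, replicates = replicates,
                 floor_at_zero = floor_at_zero,
                 sample_variance = sample_variance),
            class = "neutral_sim_config")
}

# expand the two histograms into one vector of signed event sizes
signed_event_sizes <- function(config) {
  dec <- rep(-as.integer(names(config$decreases)), times = config$decreases)
  inc <- rep(as.integer(names(config$increases)), times = config$increases)
  c(dec, inc)
}

pop_var <- function(x) mean((x - mean(x))^2)

#' Neutral Monte-Carlo simulation of copy-number evolution on a tree
#'
#' In each replicate the fixed set of signed events (from the configured
#' size histogram) is scattered independently over the edges of the tree
#' with probability proportional to edge length — the longer the branch, the
#' more likely it receives an event. Tip copy number is the root state plus
#' the sum of signed events on the root-to-tip path, floored at zero if
#' configured, and the across-tip variance is recorded per replicate.
#'
#' @param tree a rooted `phylo` with positive total branch length (units of
#'   the lengths are irrelevant; only proportions matter).
#' @param config a `neutral_sim_config`.
#' @param seed integer seed; the run is fully reproducible from it.
#' @return list with `variances` (length `replicates`), `tip_cn` (matrix,
#'   tips x replicates) and `config`.
#' @export
simulate_neutral <- function(tree, config = neutral_sim_config(), seed = 1) {
  stopifnot(inherits(tree, "phylo"), inherits(config, "neutral_sim_config"))
  ix <- tree_index(tree)
  len <- ix$edge_length
  if (is.null(len) || sum(len) <= 0)
    stop("tree must have positive total branch length", call. = FALSE)
  sizes <- signed_event_sizes(config)
  nev <- length(sizes)
  ne <- nrow(ix$edge)
  varfun <- if (config$sample_variance) stats::var else pop_var

  set.seed(as.integer(seed))
  tip_cn <- matrix(0, nrow = ix$ntip, ncol = config$replicates,
                   dimnames = list(tree$tip.label, NULL))
  variances <- numeric(config$replicates)
  pre <- rev(seq_len(ne))
  for (r in seq_len(config$replicates)) {
    delta <- numeric(ne)
    if (nev > 0) {
      idx <- sample.int(ne, nev, replace = TRUE, prob = len)
      agg <- rowsum(sizes, idx)
      delta[as.integer(rownames(agg))] <- agg[, 1]
    }
    node_cn <- numeric(ix$nnode)
    node_cn[ix$root] <- config$root_cn
    for (k in pre) {
      node_cn[ix$edge[k, 2]] <- node_cn[ix$edge[k, 1]] + delta[k]
    }
    tips <- node_cn[seq_len(ix$ntip)]
    if (config$floor_at_zero) tips <- pmax(0, tips)
    tip_cn[, r] <- tips
    variances[r] <- varfun(tips)
  }
  list(variances = variances, tip_cn = tip_cn, config = config, seed = seed)
}

#' Compare an empirical variance against a simulated neutral null
#'
#' Computes the percentile rank of the empirical across-tip variance within
#' the simulated variance distribution (midranks for ties) and the central
#' 95% interval of the null (2.5th / 97.5th percentiles, linear
#' interpolation). The verdict is `below_null` when the rank falls under the
#' threshold percentile (default 0.5), `above_null` when above
#' 100 - threshold, else `within_null`. An empirical variance below the
#' null indicates stabilizing selection on copy number.
#'
#' @param empirical_variance observed across-tip variance.
#' @param simulated numeric vector of null variances.
#' @param threshold_percentile tail threshold in percent (default 0.5).
#' @return an object of class `variance_test` with fields
#'   `empirical_variance`, `percentile_of_empirical`, `null_ci`, `verdict`.
#' @export
variance_percentile_test <- function(empirical_variance, simulated,
                                     threshold_percentile = 0.5) {
  if (length(simulated) == 0) stop("simulated list must be non-empty", call. = FALSE)
  n <- length(simulated)
  rank_pct <- 100 * (sum(simulated < empirical_variance) +
                       0.5 * sum(simulated == empirical_variance)) / n
  null_ci <- unname(stats::quantile(simulated, c(0.025, 0.975), type = 7))
  verdict <- if (rank_pct < threshold_percentile) "below_null"
  else if (rank_pct > 100 - threshold_percentile) "above_null"
  else "within_null"
  structure(list(empirical_variance = empirical_variance,
                 simulated_n = n,
                 percentile_of_empirical = rank_pct,
                 null_ci = null_ci,
                 threshold_percentile = threshold_percentile,
                 verdict = verdict),
            class = "variance_test")
}

#' @export
print.variance_test <- function(x, ...) {
  cat(sprintf("Empirical variance %.3f at percentile %.2f of %d neutral replicates\n",
              x$empirical_variance, x$percentile_of_empirical, x$simulated_n))
  cat(sprintf("  null 95%% interval: %.2f - %.2f; verdict: %s\n",
              x$null_ci[1], x$null_ci[2], x$verdict))
  invisible(x)
}
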