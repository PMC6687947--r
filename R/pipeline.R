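#' Pipeline run configuration
#'
#' Collects input paths, clock constants and every threshold with the
#' published defaults. Unknown keys are rejected so typos cannot silently
#' fall back to defaults.
#'
#' @param tree path to a Newick tree (SNV-count branch lengths).
#' @param cn_states path to a `sample_id  copy_number` TSV.
#' @param depth_dir directory of per-sample depth TSVs.
#' @param wells path to a droplet-well CSV.
#' @param trios path to a father-son pair TSV.
#' @param out_dir output directory for stage files and the run report.
#' @param stages character vector of stages to run, in dependency order.
#' @param clock a `clock_constants`.
#' @param regions a `region_set`.
#' @param window_size depth window width (bp).
#' @param flank_bp,max_rel_dev curation-flag parameters.
#' @param min_magnitude,cn_range event filter parameters (NULL = no filter).
#' @param replicate_threshold ddPCR replicate discrepancy threshold.
#' @param replicates neutral-simulation replicates.
#' @param seed global seed.
#' @return an object of class `run_config`.
#' @export
run_config <- function(tree = NULL, cn_states = NULL, depth_dir = NULL,
                       wells = NULL, trios = NULL, out_dir = "rbmycnv_run",
                       stages = c("depth", "events", "rate", "selection", "ddpcr"),
                       clock = clock_constants(), regions = region_set(),
                       window_size = 5000, flank_bp = 100000,
                       max_rel_dev = 0.25, min_magnitude = NULL,
                       cn_range = NULL, replicate_threshold = 0.8,
                       replicates = 1000, seed = 1) {
  known <- c("depth", "events", "rate", "selection", "ddpcr")
  bad <- setdiff(stages, known)
  if (length(bad) > 0)
    stop(sprintf("unknown stage(s): %s", paste(bad, collapse = ", ")), call. = FALSE)
  cfg <- structure(list(tree = tree, cn_states = cn_states,
                        depth_dir = depth_dir, wells = wells, trios = trios,
                        out_dir = out_dir, stages = stages, clock = clock,
                        regions = regions, window_size = window_size,
                        flank_bp = flank_bp, max_rel_dev = max_rel_dev,
                        min_magnitude = min_magnitude, cn_range = cn_range,
                        replicate_threshold = replicate_threshold,
                        replicates = replicates, seed = seed),
                   class = "run_config")
  needs <- list(depth = "depth_dir", events = c("tree", "cn_states"),
                rate = c("tree", "cn_states"),
                selection = c("tree", "cn_states"), ddpcr = "wells")
  for (st in stages) {
    for (field in needs[[st]]) {
      if (is.null(cfg[[field]]))
        stop(sprintf("stage '%s' requires config field '%s'", st, field),
             call. = FALSE)
      if (!file.exists(cfg[[field]]))
        stop(sprintf("input for '%s' does not exist: %s", field, cfg[[field]]),
             call. = FALSE)
    }
  }
  cfg
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on the configured
#' inputs: windowed depth to ratios and rough copy numbers with the curation
#' flag; parsimony event counting on the tree; SNV-clock mutation rate;
#' direction-bias and neutral-variance selection tests; and ddPCR
#' quantification. Writes per-stage TSVs and a JSON run report under
#' `out_dir` and returns the report.
#'
#' @param config a `run_config`.
#' @return the run report (list), invisibly written to
#'   `out_dir/report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(package_version = as.character(utils::packageVersion("rbmycnv")),
                 seed = config$seed, stages = config$stages)

  assignment <- NULL; events <- NULL

  if ("depth" %in% config$stages) {
    files <- list.files(config$depth_dir, pattern = "\\.tsv$", full.names = TRUE)
    rows <- list(); skipped <- character(0)
    for (f in files) {
      sid <- sub("\\.tsv$", "", basename(f))
      prof <- load_depth_windows(f, config$regions$survey_interval,
                                 config$window_size, sample_id = sid)
      ratio <- tryCatch(region_depth_ratio(prof, config$regions),
                        error = function(e) e)
      if (inherits(ratio, "error")) { skipped <- c(skipped, sid); next }
      flag <- flag_curated(prof, config$regions, config$flank_bp,
                           config$max_rel_dev)
      rr <- as.list(ratio$per_region_ratio)
      names(rr) <- paste0("ratio_r", names(ratio$per_region_ratio))
      rows[[sid]] <- data.frame(sample_id = sid, rr,
                                combined_ratio = ratio$combined_ratio,
                                rough_cn = rough_copy_number(ratio),
                                curated_flag = flag$pass,
                                check.names = FALSE)
    }
    depth_tab <- do.call(rbind, rows)
    utils::write.table(depth_tab, file.path(config$out_dir, "depth_cn.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$depth <- list(n_samples = nrow(depth_tab),
                         n_skipped_uninformative = length(skipped),
                         skipped = skipped,
                         n_curated = sum(depth_tab$curated_flag))
  }

  if (any(c("events", "rate", "selection") %in% config$stages)) {
    tree <- read_cn_tree(config$tree)
    states <- utils::read.table(config$cn_states, sep = "\t", header = TRUE,
                                stringsAsFactors = FALSE)
    tree <- attach_tip_states(tree, states)
    assignment <- min_event_labeling(tree)
    events <- classify_events(assignment)
    if (!is.null(config$min_magnitude) || !is.null(config$cn_range)) {
      events <- filter_events(events,
                              min_magnitude = if (is.null(config$min_magnitude)) 1
                              else config$min_magnitude,
                              cn_range = if (is.null(config$cn_range)) c(0, Inf)
                              else config$cn_range)
    }
    write_events_tsv(events, file.path(config$out_dir, "events.tsv"))
    report$events <- as.list(attr(events, "totals"))
    report$events$parsimony_minimum <- assignment$event_count
  }

  if ("rate" %in% config$stages) {
    snvs <- sum(assignment$tree$edge.length)
    est <- cn_mutation_rate(assignment$event_count, snvs, config$clock)
    report$rate <- list(events = est$events, snv_count = est$snv_count,
                        total_generations = est$total_generations,
                        rate = est$rate, rate_ci = est$rate_ci)
    if (!is.null(config$trios)) {
      pairs <- utils::read.table(config$trios, sep = "\t", header = TRUE,
                                 stringsAsFactors = FALSE)
      k <- sum(pairs$father_cn != pairs$son_cn)
      tr <- transmission_rate_ci(k, nrow(pairs))
      report$trio_rate <- tr
    }
  }

  if ("selection" %in% config$stages) {
    totals <- attr(events, "totals")
    report$selection <- list()
    if (totals[["increase"]] + totals[["decrease"]] >= 1) {
      db <- direction_bias_test(totals[["increase"]], totals[["decrease"]])
      report$selection$direction <- db
    }
    conf_ev <- events[events$confident, , drop = FALSE]
    dec <- table(factor(conf_ev$magnitude[conf_ev$direction == "decrease"]))
    inc <- table(factor(conf_ev$magnitude[conf_ev$direction == "increase"]))
    cfg_sim <- if (length(dec) + length(inc) > 0) {
      neutral_sim_config(decreases = if (length(dec)) stats::setNames(as.numeric(dec), names(dec)) else c("1" = 0),
                         increases = if (length(inc)) stats::setNames(as.numeric(inc), names(inc)) else c("1" = 0),
                         replicates = config$replicates)
    } else neutral_sim_config(replicates = config$replicates)
    sim <- simulate_neutral(assignment$tree, cfg_sim,
                            seed = derive_seed(config$seed, 7))
    emp_var <- pop_var(assignment$tree$tip_cn)
    vt <- variance_percentile_test(emp_var, sim$variances)
    report$selection$variance <- list(empirical = emp_var,
                                      percentile = vt$percentile_of_empirical,
                                      null_ci = vt$null_ci,
                                      verdict = vt$verdict)
  }

  if ("ddpcr" %in% config$stages) {
    wells <- read_droplet_wells(config$wells)
    quant <- ddpcr_quant(wells, config$replicate_threshold)
    utils::write.table(quant$totals, file.path(config$out_dir, "ddpcr_cn.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    report$ddpcr <- list(n_samples = nrow(quant$totals),
                         n_needs_third = sum(quant$assays$needs_third_replicate))
  }

  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}

# minimal --key value argument parser for the CLI
parse_cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      stop(sprintf("unexpected argument '%s'", args[i]), call. = FALSE)
    key <- sub("^--", "", args[i])
    if (i == length(args) || startsWith(args[i + 1], "--")) {
      out[[key]] <- TRUE; i <- i + 1
    } else {
      out[[key]] <- args[i + 1]; i <- i + 2
    }
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `depth`, `calibrate`, `events`, `rate`, `selection`,
#' `ddpcr`, `simulate`, `run`. Invoke from a shell as
#' `Rscript -e 'rbmycnv::rbmycnv_cli()' <subcommand> --key value ...`
#' Machine-readable JSON goes to stdout (or `--out`); diagnostics to stderr.
#'
#' @param args character vector of arguments (default: the command line).
#' @return invisibly, the result object of the subcommand.
#' @export
rbmycnv_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0)
    stop("usage: rbmycnv_cli <depth|calibrate|events|rate|selection|ddpcr|simulate|run> [--key value ...]",
         call. = FALSE)
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  emit <- function(x) {
    json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
    if (!is.null(opt$out)) writeLines(json, opt$out) else writeLines(json)
    invisible(x)
  }
  num <- function(x) if (is.null(x)) NULL else as.numeric(x)

  switch(cmd,
    depth = {
      prof <- load_depth_windows(opt$`in`, sample_id = if (is.null(opt$sample)) "sample" else opt$sample)
      regions <- if (is.null(opt$regions)) region_set() else read_regions_bed(opt$regions)
      ratio <- region_depth_ratio(prof, regions)
      emit(list(sample_id = ratio$sample_id,
                per_region_ratio = as.list(ratio$per_region_ratio),
                combined_ratio = ratio$combined_ratio,
                rough_cn = rough_copy_number(ratio),
                curated = flag_curated(prof, regions)$pass))
    },
    calibrate = {
      tab <- utils::read.table(opt$`in`, sep = "\t", header = TRUE)
      model <- fit_ols(tab[[opt$`x-col`]], tab[[opt$`y-col`]])
      if (!is.null(opt$model)) write_calibration_json(model, opt$model)
      emit(list(slope = model$slope, intercept = model$intercept,
                r2 = model$r_squared, n = model$n))
    },
    events = {
      tree <- attach_tip_states(read_cn_tree(opt$tree),
                                utils::read.table(opt$states, sep = "\t",
                                                  header = TRUE))
      asg <- if (!is.null(opt$method) && opt$method == "clade-mode")
        clade_mode_labeling(tree) else min_event_labeling(tree)
      ev <- classify_events(asg)
      if (!is.null(opt$`min-magnitude`) || !is.null(opt$`cn-range`)) {
        rng <- if (is.null(opt$`cn-range`)) c(0, Inf)
        else as.numeric(strsplit(opt$`cn-range`, ",")[[1]])
        ev <- filter_events(ev, min_magnitude = if (is.null(opt$`min-magnitude`)) 1
                            else as.numeric(opt$`min-magnitude`), cn_range = rng)
      }
      emit(c(as.list(attr(ev, "totals")),
             list(parsimony_minimum = asg$event_count, method = asg$method)))
    },
    rate = {
      if (!is.null(opt$events)) {
        est <- cn_mutation_rate(num(opt$events), num(opt$snvs))
        emit(list(events = est$events, snv_count = est$snv_count,
                  years_per_snv = est$years_per_snv,
                  generations_per_snv = est$generations_per_snv,
                  total_generations = est$total_generations,
                  rate = est$rate, rate_ci = est$rate_ci))
      } else {
        emit(transmission_rate_ci(num(opt$mutations), num(opt$transmissions)))
      }
    },
    selection = {
      if (!is.null(opt$inc)) {
        emit(direction_bias_test(num(opt$inc), num(opt$dec)))
      } else {
        sim_v <- as.numeric(readLines(opt$sim))
        vt <- variance_percentile_test(num(opt$empirical), sim_v)
        emit(list(percentile = vt$percentile_of_empirical,
                  null_ci = vt$null_ci, verdict = vt$verdict))
      }
    },
    ddpcr = {
      quant <- ddpcr_quant(read_droplet_wells(opt$`in`),
                           if (is.null(opt$threshold)) 0.8 else num(opt$threshold))
      if (!is.null(opt$out)) {
        utils::write.table(quant$totals, opt$out, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        invisible(quant)
      } else emit(quant$totals)
    },
    simulate = {
      res <- simulate_all(opt$out, seed = if (is.null(opt$seed)) 1 else as.integer(opt$seed))
      invisible(res)
    },
    run = {
      cfg_in <- jsonlite::read_json(opt$config, simplifyVector = TRUE)
      known <- names(formals(run_config))
      bad <- setdiff(names(cfg_in), known)
      if (length(bad) > 0)
        stop(sprintf("unknown config key(s): %s", paste(bad, collapse = ", ")),
             call. = FALSE)
      cfg <- do.call(run_config, cfg_in)
      emit(run_pipeline(cfg))
    },
    stop(sprintf("unknown subcommand '%s'", cmd), call. = FALSE)
  )
}
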