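#' Region definitions for multi-copy gene-family depth analysis
#'
#' A `region_set` holds the 1-based inclusive coordinates (GRCh37, chromosome
#' Y) of the four clusters containing the active RBMY1 gene copies, a nearby
#' single-copy reference interval used to normalize read depth, and the wider
#' survey interval over which windowed depth is computed. Defaults are the
#' published coordinates of the four RBMY1 regions, the unique normalizer
#' region downstream of the cluster, and the Y:22-29 Mb survey window.
#'
#' @param regions named list of numeric `c(start, end)` intervals (1-based
#'   inclusive), all on one chromosome. Default: RBMY1 regions "1".."4".
#' @param reference_interval single-copy normalizer interval.
#' @param survey_interval interval over which depth windows are laid out.
#' @param chrom chromosome name (used when reading/writing BED).
#' @return an object of class `region_set`.
#' @export
region_set <- function(regions = list(
                         "1" = c(23673224, 23711212),
                         "2" = c(24026223, 24064214),
                         "3" = c(24314689, 24329129),
                         "4" = c(24549583, 24564028)),
                       reference_interval = c(23255000, 23555000),
                       survey_interval = c(22000000, 29000000),
                       chrom = "Y") {
  if (length(regions) < 1 || is.null(names(regions)) || anyDuplicated(names(regions)))
    stop("'regions' must be a uniquely named list of intervals", call. = FALSE)
  for (nm in names(regions)) check_interval(regions[[nm]], paste0("region ", nm))
  check_interval(reference_interval, "reference_interval")
  check_interval(survey_interval, "survey_interval")

  ivs <- c(regions, list(REF = reference_interval))
  ord <- order(vapply(ivs, `[`, numeric(1), 1))
  sorted <- ivs[ord]
  for (i in seq_len(length(sorted) - 1)) {
    if (sorted[[i]][2] >= sorted[[i + 1]][1])
      stop(sprintf("intervals '%s' and '%s' overlap",
                   names(sorted)[i], names(sorted)[i + 1]), call. = FALSE)
  }
  for (nm in names(ivs)) {
    if (ivs[[nm]][1] < survey_interval[1] || ivs[[nm]][2] > survey_interval[2])
      stop(sprintf("interval '%s' lies outside the survey interval", nm),
           call. = FALSE)
  }
  structure(list(regions = regions, reference_interval = reference_interval,
                 survey_interval = survey_interval, chrom = chrom),
            class = "region_set")
}

#' Read a region set from a BED4 file
#'
#' BED uses 0-based half-open coordinates; they are converted to the 1-based
#' inclusive convention used internally (start + 1, end unchanged). The
#' reserved name `REF` in the name column marks the single-copy reference
#' interval; all other rows become gene regions.
#'
#' @param path BED4 file (chrom, start, end, name).
#' @param survey_interval survey interval (not representable in BED4).
#' @return a `region_set`.
#' @export
read_regions_bed <- function(path, survey_interval = c(22000000, 29000000)) {
  bed <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name"),
                           colClasses = c("character", "numeric", "numeric", "character"))
  if (nrow(bed) < 2) stop("BED must contain at least one region and a REF row", call. = FALSE)
  ref <- bed[bed$name == "REF", , drop = FALSE]
  if (nrow(ref) != 1) stop("BED must contain exactly one row named 'REF'", call. = FALSE)
  reg <- bed[bed$name != "REF", , drop = FALSE]
  regions <- lapply(seq_len(nrow(reg)), function(i) c(reg$start[i] + 1, reg$end[i]))
  names(regions) <- reg$name
  region_set(regions = regions,
             reference_interval = c(ref$start + 1, ref$end),
             survey_interval = survey_interval,
             chrom = bed$chrom[1])
}

#' Write a region set to a BED4 file
#'
#' Inverse of [read_regions_bed()]; conversion back to 0-based half-open is
#' bit-exact (start - 1, end unchanged).
#'
#' @param rs a `region_set`.
#' @param path output path.
#' @export
write_regions_bed <- function(rs, path) {
  stopifnot(inherits(rs, "region_set"))
  ivs <- c(rs$regions, list(REF = rs$reference_interval))
  bed <- data.frame(chrom = rs$chrom,
                    start = vapply(ivs, `[`, numeric(1), 1) - 1,
                    end = vapply(ivs, `[`, numeric(1), 2),
                    name = names(ivs))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Copy-equivalent model for the read-pooling depth ratio
#'
#' Reads from all gene copies mis-map interchangeably onto the fixed
#' reference footprint, so the depth ratio against a single-copy region
#' scales with total copy-equivalents. The reference footprint holds six
#' active genes plus pseudogenes worth about one extra copy, i.e. seven
#' copy-equivalents: a change of 1/7 (~0.14) in the ratio corresponds to a
#' change of one gene copy.
#'
#' @param copy_equivalents_reference copy-equivalents in the reference
#'   footprint (default 7).
#' @param pseudogene_equivalents pseudogene contribution included in the
#'   footprint but not counted as gene copies (default 1).
#' @return an object of class `copy_model`.
#' @export
copy_model <- function(copy_equivalents_reference = 7, pseudogene_equivalents = 1) {
  if (copy_equivalents_reference < 1) stop("copy_equivalents_reference must be >= 1", call. = FALSE)
  if (pseudogene_equivalents < 0) stop("pseudogene_equivalents must be >= 0", call. = FALSE)
  structure(list(copy_equivalents_reference = copy_equivalents_reference,
                 pseudogene_equivalents = pseudogene_equivalents),
            class = "copy_model")
}

#' Compute a windowed depth profile from a depth table
#'
#' Lays non-overlapping windows of `window_size` bp over the survey interval
#' (the last window may be shorter) and computes the arithmetic mean of
#' per-base depth in each window; bases absent from the source count as
#' depth 0.
#'
#' Accepted sources (path to a TSV, optionally gzipped, or a data.frame):
#' interval form `chrom start(0-based) end mean_depth` (BED-like half-open),
#' or per-base form `chrom pos(1-based) depth`.
#'
#' @param source file path or data.frame (3 or 4 columns as above).
#' @param survey 1-based inclusive survey interval.
#' @param window_size window width in bp (default 5000).
#' @param sample_id sample label attached to the profile.
#' @return an object of class `depth_profile` with fields `sample_id`,
#'   `window_size` and `windows` (data.frame `start`, `end`, `mean_depth`).
#' @export
load_depth_windows <- function(source, survey = c(22000000, 29000000),
                               window_size = 5000, sample_id = "sample") {
  check_interval(survey, "survey")
  if (window_size <= 0) stop("window_size must be > 0", call. = FALSE)

  if (is.character(source)) {
    tab <- utils::read.table(source, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)
  } else {
    tab <- as.data.frame(source)
  }
  if (nrow(tab) == 0) stop("empty depth source", call. = FALSE)

  if (ncol(tab) == 4) {          # interval rows, 0-based half-open
    s <- suppressWarnings(as.numeric(tab[[2]])) + 1
    e <- suppressWarnings(as.numeric(tab[[3]]))
    d <- suppressWarnings(as.numeric(tab[[4]]))
  } else if (ncol(tab) == 3) {   # per-base rows, 1-based
    s <- suppressWarnings(as.numeric(tab[[2]]))
    e <- s
    d <- suppressWarnings(as.numeric(tab[[3]]))
  } else {
    stop("depth source must have 3 (per-base) or 4 (interval) columns", call. = FALSE)
  }
  bad <- which(!is.finite(s) | !is.finite(e) | !is.finite(d) | s > e + 0.5 | d < 0)
  if (length(bad) > 0)
    stop(sprintf("malformed depth source row(s): line %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)

  wstart <- seq(survey[1], survey[2], by = window_size)
  wend <- pmin(wstart + window_size - 1, survey[2])
  nw <- length(wstart)

  # clip source rows to the survey, then spread each row across the windows
  # it spans; depth mass = depth * overlap length
  s <- pmax(s, survey[1]); e <- pmin(e, survey[2])
  keep <- s <= e
  s <- s[keep]; e <- e[keep]; d <- d[keep]
  mass <- numeric(nw)
  if (length(s) > 0) {
    i1 <- pmax(1L, as.integer(floor((s - survey[1]) / window_size)) + 1L)
    i2 <- pmin(nw, as.integer(floor((e - survey[1]) / window_size)) + 1L)
    widx <- unlist(mapply(seq.int, i1, i2, SIMPLIFY = FALSE), use.names = FALSE)
    ridx <- rep.int(seq_along(s), i2 - i1 + 1L)
    ov <- interval_overlap(s[ridx], e[ridx], wstart[widx], wend[widx])
    agg <- rowsum(ov * d[ridx], widx)
    mass[as.integer(rownames(agg))] <- agg[, 1]
  }
  windows <- data.frame(start = wstart, end = wend,
                        mean_depth = mass / (wend - wstart + 1))
  structure(list(sample_id = sample_id, window_size = window_size,
                 windows = windows),
            class = "depth_profile")
}

# overlap-length-weighted mean window depth over a 1-based inclusive interval
interval_mean_depth <- function(windows, iv) {
  ov <- interval_overlap(windows$start, windows$end, iv[1], iv[2])
  tot <- sum(ov)
  if (tot == 0) return(NA_real_)
  sum(windows$mean_depth * ov) / tot
}

#' Depth ratios of gene regions against the single-copy reference
#'
#' Computes, for one sample, the mean window depth over each gene region and
#' over all regions pooled, each divided by the mean depth of the single-copy
#' reference interval. Windows straddling an interval boundary contribute
#' with overlap-length weights, so the combined ratio is the length-weighted
#' pooled mean over the four regions divided by the reference mean.
#'
#' @param profile a `depth_profile`.
#' @param regions a `region_set`.
#' @return an object of class `depth_ratio_set` with fields `sample_id`,
#'   `per_region_ratio` (named), `combined_ratio`, `reference_mean_depth`.
#' @export
region_depth_ratio <- function(profile, regions) {
  stopifnot(inherits(profile, "depth_profile"), inherits(regions, "region_set"))
  w <- profile$windows

  for (nm in names(regions$regions)) {
    if (sum(interval_overlap(w$start, w$end,
                             regions$regions[[nm]][1], regions$regions[[nm]][2])) == 0)
      stop(sprintf("region '%s' lies outside the depth profile span", nm),
           call. = FALSE)
  }
  ref_mean <- interval_mean_depth(w, regions$reference_interval)
  if (is.na(ref_mean))
    stop("reference interval lies outside the depth profile span", call. = FALSE)
  if (ref_mean <= 0)
    stop("uninformative sample: reference mean depth is 0", call. = FALSE)

  per_region <- vapply(regions$regions, function(iv) {
    interval_mean_depth(w, iv) / ref_mean
  }, numeric(1))

  # pooled (length-weighted) mean across all regions
  num <- 0; den <- 0
  for (iv in regions$regions) {
    ov <- interval_overlap(w$start, w$end, iv[1], iv[2])
    num <- num + sum(w$mean_depth * ov)
    den <- den + sum(ov)
  }
  structure(list(sample_id = profile$sample_id,
                 per_region_ratio = per_region,
                 combined_ratio = (num / den) / ref_mean,
                 reference_mean_depth = ref_mean),
            class = "depth_ratio_set")
}

#' Rough copy number from a combined depth ratio
#'
#' Under the read-pooling model the combined ratio equals
#' (gene copies + pseudogene equivalents) / copy-equivalents of the
#' reference footprint, so the rough gene copy number is
#' `ratio * copy_equivalents_reference - pseudogene_equivalents`, rounded to
#' the nearest integer (ties away from zero) and floored at 0. With the
#' defaults, ratios 0.62 and 1.89 map to 3 and 12 copies.
#'
#' @param ratio a `depth_ratio_set` or a numeric combined ratio.
#' @param model a `copy_model`.
#' @return integer copy number (vectorized over numeric input).
#' @export
rough_copy_number <- function(ratio, model = copy_model()) {
  stopifnot(inherits(model, "copy_model"))
  x <- if (inherits(ratio, "depth_ratio_set")) ratio$combined_ratio else as.numeric(ratio)
  if (any(x < 0)) stop("combined ratio must be >= 0", call. = FALSE)
  pmax(0, round_half_away(x * model$copy_equivalents_reference -
                            model$pseudogene_equivalents))
}

#' Flag samples with constant flanking depth (curation proxy)
#'
#' Mirrors the manual curation step that kept only samples whose read depth
#' stayed constant in the regions flanking the gene cluster: a flank
#' duplication or deletion there would distort the reference normalization.
#' Flank windows are those overlapping `flank_bp` on either side of the
#' block spanned by the gene regions, excluding windows that touch the gene
#' regions themselves. The sample passes iff every flank window's depth lies
#' within `max_rel_dev` (relative) of the median flank depth.
#'
#' @param profile a `depth_profile`.
#' @param regions a `region_set`.
#' @param flank_bp flank width per side in bp (default 100000).
#' @param max_rel_dev maximum relative deviation from the median (default 0.25).
#' @return list with `pass` (logical), `median_flank_depth`, and `offending`
#'   (data.frame of windows violating the bound).
#' @export
flag_curated <- function(profile, regions, flank_bp = 100000, max_rel_dev = 0.25) {
  stopifnot(inherits(profile, "depth_profile"), inherits(regions, "region_set"))
  if (flank_bp <= 0) stop("flank_bp must be > 0", call. = FALSE)
  w <- profile$windows
  block <- range(unlist(regions$regions))
  flanks <- list(c(block[1] - flank_bp, block[1] - 1),
                 c(block[2] + 1, block[2] + flank_bp))
  in_flank <- rep(FALSE, nrow(w))
  for (fl in flanks)
    in_flank <- in_flank | interval_overlap(w$start, w$end, fl[1], fl[2]) > 0
  in_region <- rep(FALSE, nrow(w))
  for (iv in regions$regions)
    in_region <- in_region | interval_overlap(w$start, w$end, iv[1], iv[2]) > 0
  fw <- w[in_flank & !in_region, , drop = FALSE]
  if (nrow(fw) == 0)
    stop("no flank windows on either side of the gene-region block", call. = FALSE)
  med <- stats::median(fw$mean_depth)
  dev <- abs(fw$mean_depth - med)
  bad <- fw[dev > max_rel_dev * med, , drop = FALSE]
  list(pass = nrow(bad) == 0, median_flank_depth = med, offending = bad)
}

#' @export
print.depth_ratio_set <- function(x, ...) {
  cat("Depth ratio set for sample", x$sample_id, "\n")
  cat("  per-region ratios:",
      paste(sprintf("%s=%.3f", names(x$per_region_ratio), x$per_region_ratio),
            collapse = ", "), "\n")
  cat(sprintf("  combined ratio: %.4f (reference mean depth %.2f)\n",
              x$combined_ratio, x$reference_mean_depth))
  invisible(x)
}
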