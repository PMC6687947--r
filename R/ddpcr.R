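#' Droplet concentration by Poisson inversion
#'
#' Template molecules partition into droplets approximately Poisson, so the
#' mean occupancy is lambda = -ln(1 - positive/total) and the concentration
#' is lambda / droplet volume. Wells where every droplet is positive are
#' saturated and cannot be inverted.
#'
#' @param positive positive droplet count(s).
#' @param total total droplet count(s).
#' @param volume droplet volume in nL (default 0.85).
#' @return concentration in copies per nL (vectorized).
#' @export
droplet_concentration <- function(positive, total, volume = 0.85) {
  if (any(total <= 0)) stop("total droplet count must be > 0", call. = FALSE)
  if (any(positive < 0) || any(positive > total))
    stop("need 0 <= positive <= total", call. = FALSE)
  if (any(positive == total)) stop("saturated well: all droplets positive", call. = FALSE)
  if (volume <= 0) stop("droplet volume must be > 0", call. = FALSE)
  -log(1 - positive / total) / volume
}

#' Copy number of one assay well against the single-copy reference channel
#'
#' Copy number is the ratio of target to reference concentration, times the
#' copy count of the reference locus (a single-copy Y gene, so 1 by
#' default). The droplet volume cancels in the ratio.
#'
#' @param well list or one-row data.frame with `target_positive`,
#'   `target_total`, `reference_positive`, `reference_total` and optionally
#'   `droplet_volume`.
#' @param reference_copies copies of the reference locus (default 1).
#' @return real-valued copy number.
#' @export
assay_copy_number <- function(well, reference_copies = 1) {
  vol <- if (!is.null(well$droplet_volume)) well$droplet_volume else 0.85
  ct <- droplet_concentration(well$target_positive, well$target_total, vol)
  cr <- droplet_concentration(well$reference_positive, well$reference_total, vol)
  if (any(cr == 0)) stop("reference concentration is 0", call. = FALSE)
  ct / cr * reference_copies
}

#' Combine replicate copy-number estimates with the discrepancy rule
#'
#' With exactly two replicates differing by `discrepancy_threshold` or more,
#' no consensus is formed and a third replicate is requested; otherwise the
#' consensus is the arithmetic mean of the replicate values.
#'
#' @param values numeric replicate copy numbers (>= 1 value).
#' @param discrepancy_threshold copies (default 0.8).
#' @return list with `consensus` (NA when a third replicate is needed),
#'   `needs_third_replicate`, `replicate_values`.
#' @export
combine_replicates <- function(values, discrepancy_threshold = 0.8) {
  if (length(values) < 1) stop("need at least one replicate value", call. = FALSE)
  needs_third <- length(values) == 2 &&
    abs(values[1] - values[2]) >= discrepancy_threshold
  list(consensus = if (needs_third) NA_real_ else mean(values),
       needs_third_replicate = needs_third,
       replicate_values = values)
}

#' Total copy number from the two allele-specific assays
#'
#' The T-assay quantifies the gene copies in the two proximal clusters and
#' the C-assay the two distal clusters; the total is their sum.
#'
#' @param t_assay real copy number from the T-assay.
#' @param c_assay real copy number from the C-assay.
#' @return list with `real` (T + C) and `integer` (rounded half away from
#'   zero, floored at 0).
#' @export
total_copy_number <- function(t_assay, c_assay) {
  if (any(t_assay < 0) || any(c_assay < 0))
    stop("assay copy numbers must be >= 0", call. = FALSE)
  real <- t_assay + c_assay
  list(real = real, integer = pmax(0, round_half_away(real)))
}

#' Read a droplet well table
#'
#' @param path CSV with columns `sample_id, assay, replicate,
#'   target_positive, target_total, ref_positive, ref_total`.
#' @return data.frame.
#' @export
read_droplet_wells <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "assay", "replicate", "target_positive",
            "target_total", "ref_positive", "ref_total")
  missing <- setdiff(need, names(tab))
  if (length(missing) > 0)
    stop(sprintf("droplet table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  tab
}

#' Quantify copy numbers from a droplet well table
#'
#' Computes per-replicate copy numbers, applies the replicate-discrepancy
#' rule per sample and assay, and sums the T- and C-assay consensus values
#' into a total where both are available.
#'
#' @param wells data.frame as from [read_droplet_wells()].
#' @param discrepancy_threshold replicate discrepancy threshold in copies.
#' @param reference_copies copies of the reference locus.
#' @return list with `assays` (per sample/assay data.frame) and `totals`
#'   (per-sample data.frame with real and integer total copy number).
#' @export
ddpcr_quant <- function(wells, discrepancy_threshold = 0.8, reference_copies = 1) {
  cn <- vapply(seq_len(nrow(wells)), function(i) {
    assay_copy_number(list(target_positive = wells$target_positive[i],
                           target_total = wells$target_total[i],
                           reference_positive = wells$ref_positive[i],
                           reference_total = wells$ref_total[i]),
                      reference_copies)
  }, numeric(1))
  key <- interaction(wells$sample_id, wells$assay, drop = TRUE)
  per_assay <- do.call(rbind, lapply(split(seq_len(nrow(wells)), key), function(idx) {
    comb <- combine_replicates(cn[idx], discrepancy_threshold)
    data.frame(sample_id = wells$sample_id[idx[1]],
               assay = wells$assay[idx[1]],
               n_replicates = length(idx),
               copy_number = comb$consensus,
               needs_third_replicate = comb$needs_third_replicate,
               stringsAsFactors = FALSE)
  }))
  rownames(per_assay) <- NULL

  totals <- do.call(rbind, lapply(split(per_assay, per_assay$sample_id), function(g) {
    t_cn <- g$copy_number[g$assay == "T"]
    c_cn <- g$copy_number[g$assay == "C"]
    if (length(t_cn) == 1 && length(c_cn) == 1 &&
        !is.na(t_cn) && !is.na(c_cn)) {
      tot <- total_copy_number(t_cn, c_cn)
      data.frame(sample_id = g$sample_id[1], t_assay = t_cn, c_assay = c_cn,
                 total_cn = tot$real, total_cn_integer = tot$integer,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sample_id = g$sample_id[1],
                 t_assay = if (length(t_cn) == 1) t_cn else NA_real_,
                 c_assay = if (length(c_cn) == 1) c_cn else NA_real_,
                 total_cn = NA_real_, total_cn_integer = NA_real_,
                 stringsAsFactors = FALSE)
    }
  }))
  rownames(totals) <- NULL
  list(assays = per_assay, totals = totals)
}
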