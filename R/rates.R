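#' Molecular-clock constants for the Y chromosome
#'
#' Defaults: SNV mutation rate 0.76e-9 per bp per year (95% CI 0.67e-9 to
#' 0.86e-9), 10.3 Mb of callable sequence, 30-year generations. With these,
#' one SNV corresponds to 1 / (0.76e-9 * 10.3e6) = 127.7 years, i.e. 4.26
#' generations.
#'
#' @param snv_rate_per_bp_year point SNV rate.
#' @param snv_rate_ci length-2 CI for the SNV rate.
#' @param callable_bp callable sequence length in bp.
#' @param generation_years years per generation.
#' @return an object of class `clock_constants`.
#' @export
clock_constants <- function(snv_rate_per_bp_year = 0.76e-9,
                            snv_rate_ci = c(0.67e-9, 0.86e-9),
                            callable_bp = 10.3e6,
                            generation_years = 30) {
  if (snv_rate_per_bp_year <= 0 || callable_bp <= 0 || generation_years <= 0 ||
      any(snv_rate_ci <= 0))
    stop("clock constants must all be positive", call. = FALSE)
  if (snv_rate_ci[1] > snv_rate_per_bp_year || snv_rate_ci[2] < snv_rate_per_bp_year)
    stop("snv_rate_ci must bracket the point rate", call. = FALSE)
  structure(list(snv_rate_per_bp_year = snv_rate_per_bp_year,
                 snv_rate_ci = snv_rate_ci,
                 callable_bp = callable_bp,
                 generation_years = generation_years),
            class = "clock_constants")
}

#' Convert an SNV count to branch-length generations
#'
#' @param snv_count number of SNVs on the branches considered.
#' @param clock a `clock_constants`.
#' @return list with `years_per_snv`, `generations_per_snv`,
#'   `total_generations`.
#' @export
snv_to_generations <- function(snv_count, clock = clock_constants()) {
  stopifnot(inherits(clock, "clock_constants"))
  if (snv_count < 0) stop("snv_count must be >= 0", call. = FALSE)
  years_per_snv <- 1 / (clock$snv_rate_per_bp_year * clock$callable_bp)
  generations_per_snv <- years_per_snv / clock$generation_years
  list(years_per_snv = years_per_snv,
       generations_per_snv = generations_per_snv,
       total_generations = snv_count * generations_per_snv)
}

#' Copy-number mutation rate from tree-wide event and SNV counts
#'
#' rate = events / total branch-length generations, with the SNV count
#' converted to generations via the molecular clock. The confidence interval
#' propagates only the SNV-rate CI (the rate is linear in the SNV rate:
#' r = K * mu * L * g / S), matching how the published CIs were obtained;
#' Poisson uncertainty in the event count is deliberately not folded in.
#'
#' @param event_count number of copy-number change events (K).
#' @param snv_count number of SNVs defining the branch lengths (S).
#' @param clock a `clock_constants`.
#' @return an object of class `rate_estimate`.
#' @export
cn_mutation_rate <- function(event_count, snv_count, clock = clock_constants()) {
  stopifnot(inherits(clock, "clock_constants"))
  if (snv_count <= 0) stop("snv_count must be > 0", call. = FALSE)
  if (event_count < 0) stop("event_count must be >= 0", call. = FALSE)
  conv <- snv_to_generations(snv_count, clock)
  rate <- event_count / conv$total_generations
  rate_at <- function(mu) {
    event_count * mu * clock$callable_bp * clock$generation_years / snv_count
  }
  ci <- if (event_count == 0) c(0, 0) else
    c(rate_at(clock$snv_rate_ci[1]), rate_at(clock$snv_rate_ci[2]))
  structure(list(events = event_count, snv_count = snv_count,
                 years_per_snv = conv$years_per_snv,
                 generations_per_snv = conv$generations_per_snv,
                 total_generations = conv$total_generations,
                 rate = rate, rate_ci = ci, clock = clock),
            class = "rate_estimate")
}

#' Exact binomial (Clopper-Pearson) transmission rate
#'
#' Point estimate k/n for `mutations` observed in `transmissions`
#' father-to-son transmissions, with the exact Clopper-Pearson interval from
#' Beta quantiles; the lower bound is 0 when k = 0 and the upper bound 1
#' when k = n.
#'
#' @param mutations observed mutation count (k).
#' @param transmissions number of transmissions (n).
#' @param confidence confidence level (default 0.95).
#' @return list with `point`, `ci_low`, `ci_high`, `mutations`,
#'   `transmissions`.
#' @export
transmission_rate_ci <- function(mutations, transmissions, confidence = 0.95) {
  k <- mutations; n <- transmissions
  if (n <= 0 || k < 0 || k > n || k != round(k) || n != round(n))
    stop("need integer counts with 0 <= mutations <= transmissions, transmissions > 0",
         call. = FALSE)
  a <- (1 - confidence) / 2
  lo <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  hi <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  list(point = k / n, ci_low = lo, ci_high = hi,
       mutations = k, transmissions = n, confidence = confidence)
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("CN mutation rate: %d events / %.0f generations (%d SNVs)\n",
              x$events, x$total_generations, x$snv_count))
  cat(sprintf("  rate = %.3g per transmission (95%% CI %.3g - %.3g)\n",
              x$rate, x$rate_ci[1], x$rate_ci[2]))
  invisible(x)
}
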