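#' Round half away from zero
#'
#' Shared rounding convention for copy-number estimates: nearest integer,
#' ties away from zero (`round()` in base R rounds ties to even, which would
#' map 7.5 to 8 but 6.5 to 6).
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @keywords internal
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

# length of a 1-based inclusive interval
interval_length <- function(iv) iv[2] - iv[1] + 1

# overlap length of two 1-based inclusive intervals (0 when disjoint)
interval_overlap <- function(a_start, a_end, b_start, b_end) {
  pmax(0, pmin(a_end, b_end) - pmax(a_start, b_start) + 1)
}

check_interval <- function(iv, what) {
  if (!is.numeric(iv) || length(iv) != 2 || anyNA(iv) || iv[1] > iv[2]) {
    stop(sprintf("'%s' must be a numeric (start, end) with start <= end", what),
         call. = FALSE)
  }
  invisible(iv)
}

# derive a substream seed (kept below 2^31) from a user seed and a label
derive_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset) %% 1000L
}
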