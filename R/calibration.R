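#' Ordinary least squares calibration
#'
#' Fits `y = slope * x + intercept` by ordinary least squares. Used both to
#' calibrate depth-derived values against fibre-FISH gold-standard copy
#' numbers and for the ddPCR-vs-fibre-FISH concordance regression.
#'
#' @param x numeric predictor (e.g. depth ratio, or fibre-FISH copies for the
#'   concordance regression).
#' @param y numeric response (accurate copy numbers).
#' @return an object of class `calibration_model` with fields `slope`,
#'   `intercept`, `r_squared`, `n`, `residuals`.
#' @export
fit_ols <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (length(x) < 2) stop("need at least 2 points", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("x and y must not contain NA", call. = FALSE)
  if (stats::var(x) == 0) stop("zero variance predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  ss_res <- sum(res^2)
  ss_tot <- sum((y - mean(y))^2)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1,
                 n = length(x),
                 residuals = unname(res)),
            class = "calibration_model")
}

#' Predict copy number from a calibration model
#'
#' @param model a `calibration_model`.
#' @param x numeric vector of predictor values.
#' @return list with `real` (slope * x + intercept) and `integer` (rounded
#'   half away from zero, floored at 0).
#' @export
predict_cn <- function(model, x) {
  stopifnot(inherits(model, "calibration_model"))
  real <- model$slope * as.numeric(x) + model$intercept
  list(real = real, integer = pmax(0, round_half_away(real)))
}

#' Train/test split validation of the calibration
#'
#' Reproduces the validation design in which the calibration line is fitted
#' on a training subset of gold-standard samples and integer copy numbers are
#' predicted for the held-out test samples, tabulating exact matches,
#' off-by-one predictions and worse.
#'
#' @param table data.frame with columns `sample_id`, `x`, `y` (y = true
#'   integer copies).
#' @param train_ids,test_ids disjoint character vectors of sample ids.
#' @return list with `model`, `predictions` (data.frame) and `counts`
#'   (named vector `exact`, `off_by_one`, `worse`).
#' @export
split_validation <- function(table, train_ids, test_ids) {
  stopifnot(all(c("sample_id", "x", "y") %in% names(table)))
  if (length(intersect(train_ids, test_ids)) > 0)
    stop("train and test ids must be disjoint", call. = FALSE)
  missing <- setdiff(c(train_ids, test_ids), table$sample_id)
  if (length(missing) > 0)
    stop(sprintf("unknown sample id(s): %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  tr <- table[table$sample_id %in% train_ids, ]
  te <- table[table$sample_id %in% test_ids, ]
  model <- fit_ols(tr$x, tr$y)
  pred <- predict_cn(model, te$x)
  err <- abs(pred$integer - te$y)
  counts <- c(exact = sum(err == 0), off_by_one = sum(err == 1),
              worse = sum(err >= 2))
  list(model = model,
       predictions = data.frame(sample_id = te$sample_id, x = te$x,
                                truth = te$y, predicted_real = pred$real,
                                predicted = pred$integer, abs_error = err),
       counts = counts)
}

#' Packaged fibre-FISH gold-standard table
#'
#' The 14 fibre-FISH-validated samples with per-region copy counts, total
#' fibre-FISH copy number and the read-depth and ddPCR estimates. The one
#' sample with a partially duplicated region 1 ("4 + 2") is stored as 6.
#'
#' @return data.frame with columns `sample_id`, `haplogroup`, `region1`..
#'   `region4`, `total_fibre_fish`, `cn_read_depth`, `cn_ddpcr`.
#' @export
gold_standard_table <- function() {
  path <- system.file("extdata", "fibre_fish_gold_standard.tsv",
                      package = "rbmycnv", mustWork = TRUE)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(tab$region1 + tab$region2 + tab$region3 + tab$region4 ==
                  tab$total_fibre_fish))
  tab
}

#' Serialize / deserialize a calibration model as JSON
#'
#' @param model a `calibration_model`.
#' @param path file path.
#' @return `read_calibration_json` returns a `calibration_model`.
#' @export
write_calibration_json <- function(model, path) {
  stopifnot(inherits(model, "calibration_model"))
  jsonlite::write_json(list(slope = model$slope, intercept = model$intercept,
                            r2 = model$r_squared, n = model$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_json
#' @export
read_calibration_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(slope = obj$slope, intercept = obj$intercept,
                 r_squared = obj$r2, n = obj$n, residuals = NULL),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("OLS calibration: y = %.4f x + %.4f (R^2 = %.3f, n = %d)\n",
              x$slope, x$intercept, x$r_squared, x$n))
  invisible(x)
}
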