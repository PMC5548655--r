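#' Validate a table of classifier scores and truth states
#'
#' A score set is the universal input of the package: one row per subject,
#' a real-valued classifier `score` on an arbitrary scale and a binary
#' `truth` state (1 = diseased, 0 = non-diseased). `validate_scores()`
#' checks the contract and returns the data as a tibble with canonical
#' column names `score` and `truth`, preserving input order.
#'
#' @param data A data frame with at least the score and truth columns.
#' @param score,truth Column names (strings) holding the classifier score
#'   and the 0/1 truth state.
#' @param require_both_classes If `TRUE`, error unless both truth states are
#'   present (calibration is undefined with a single class).
#'
#' @return A tibble with columns `score` (double) and `truth` (integer 0/1).
#' @examples
#' validate_scores(data.frame(score = c(2, 12, 18), truth = c(0, 1, 0)))
#' @export
validate_scores <- function(data, score = "score", truth = "truth",
                            require_both_classes = FALSE) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  for (col in c(score, truth)) {
    if (!col %in% names(data)) {
      abort(sprintf("Column `%s` not found in `data`.", col))
    }
  }
  if (nrow(data) == 0L) abort("Score set is empty: no subjects to calibrate.")
  s <- data[[score]]
  d <- data[[truth]]
  if (!is.numeric(s)) abort(sprintf("Column `%s` must be numeric.", score))
  bad <- which(!is.finite(s))
  if (length(bad) > 0L) {
    abort(sprintf("Non-finite score at row %d (scores must be finite reals).",
                  bad[1L]))
  }
  d_num <- suppressWarnings(as.numeric(d))
  bad <- which(is.na(d_num) | !(d_num %in% c(0, 1)))
  if (length(bad) > 0L) {
    abort(sprintf("Truth value at row %d is not 0 or 1 (found `%s`).",
                  bad[1L], as.character(d[bad[1L]])))
  }
  out <- tibble::tibble(score = as.numeric(s), truth = as.integer(d_num))
  if (require_both_classes && length(unique(out$truth)) < 2L) {
    abort("Both truth states must be present: calibration is undefined with one class.")
  }
  out
}

# Class counts used throughout: N, N0 (truth = 0), N1 (truth = 1).
score_counts <- function(data) {
  n1 <- sum(data$truth == 1L)
  list(n = nrow(data), n0 = nrow(data) - n1, n1 = n1)
}

#' Read a score set from a CSV file
#'
#' Reads a comma-separated file with a header row and returns a validated
#' score set. The truth column must contain only 0/1 values; scores must be
#' finite reals. Input row order is preserved.
#'
#' @param path Path to a CSV file.
#' @param score,truth Names of the score and truth columns in the file.
#' @return A tibble with columns `score` and `truth`.
#' @seealso [validate_scores()], [write_curve()]
#' @export
read_scores <- function(path, score = "score", truth = "truth") {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  data <- tryCatch(
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE),
    error = function(e) abort(sprintf("Failed to parse CSV `%s`: %s", path,
                                      conditionMessage(e)))
  )
  if (nrow(data) == 0L) abort(sprintf("File `%s` contains no data rows.", path))
  validate_scores(data, score = score, truth = truth)
}

#' Write or read a calibration curve as CSV
#'
#' A calibration curve is the common output of all three calibrators: one
#' row per distinct training score with the probability-of-disease estimate
#' and its pointwise 95% confidence bounds.
#'
#' @param curve A data frame with columns `score`, `prob`, `lo95`, `hi95`.
#' @param path Output (input) CSV path.
#' @return `write_curve()` returns `curve` invisibly; `read_curve()` returns
#'   the curve tibble.
#' @export
write_curve <- function(curve, path) {
  curve <- check_curve(curve)
  readr::write_csv(curve, path)
  invisible(curve)
}

#' @rdname write_curve
#' @export
read_curve <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  check_curve(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

# Validate the CalibrationCurve contract: distinct ascending scores,
# probabilities and bounds in [0,1] with lo95 <= prob <= hi95.
check_curve <- function(curve) {
  if (!is.data.frame(curve) || nrow(curve) == 0L) {
    abort("Calibration curve must be a non-empty data frame.")
  }
  need <- c("score", "prob", "lo95", "hi95")
  miss <- setdiff(need, names(curve))
  if (length(miss) > 0L) {
    abort(sprintf("Curve is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (is.unsorted(curve$score, strictly = TRUE)) {
    abort("Curve scores must be strictly ascending (distinct training scores).")
  }
  tol <- 1e-9
  ok <- curve$lo95 >= -tol & curve$lo95 <= curve$prob + tol &
    curve$prob <= curve$hi95 + tol & curve$hi95 <= 1 + tol
  if (!all(ok, na.rm = TRUE)) {
    abort("Curve must satisfy 0 <= lo95 <= prob <= hi95 <= 1 elementwise.")
  }
  tibble::as_tibble(curve[need])
}

#' Rescale a probability of disease to a different prevalence
#'
#' A calibrated probability is specific to the prevalence of the dataset it
#' was trained on. Because the likelihood ratio of a score does not depend
#' on prevalence, a probability estimated at sample prevalence
#' \eqn{\eta_{sample}} converts to the population prevalence
#' \eqn{\eta_{pop}} by the odds-ratio factor
#' \deqn{\kappa = \frac{\eta_{pop}/(1-\eta_{pop})}{\eta_{sample}/(1-\eta_{sample})},\qquad
#'       P_{pop} = \frac{\kappa P}{(\kappa - 1) P + 1}.}
#' The map is monotone in `p`, fixes 0 and 1, and swapping the two
#' prevalences gives the exact inverse.
#'
#' @param p Probability (vector) estimated at prevalence `eta_sample`.
#' @param eta_sample,eta_pop Sample and target population prevalence, both
#'   strictly inside (0, 1).
#' @return Rescaled probabilities, same length as `p`.
#' @examples
#' rescale_prevalence(0.5, eta_sample = 0.5, eta_pop = 0.2)
#' @export
rescale_prevalence <- function(p, eta_sample, eta_pop) {
  for (e in c(eta_sample, eta_pop)) {
    if (!is.numeric(e) || length(e) != 1L || !is.finite(e) || e <= 0 || e >= 1) {
      abort("Prevalences must be single values strictly inside (0, 1).")
    }
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("`p` must contain probabilities in [0, 1].")
  }
  kappa <- (eta_pop / (1 - eta_pop)) / (eta_sample / (1 - eta_sample))
  kappa * p / ((kappa - 1) * p + 1)
}

#' Predict probabilities at new scores from a calibration curve
#'
#' The semi- and non-parametric calibrators define the probability of
#' disease on the distinct training scores only; a new score is mapped to a
#' probability by linear interpolation between the two bracketing training
#' scores. Queries outside the training range clamp to the first/last curve
#' value: extrapolating a probability beyond the observed scores is not
#' supported by any of the fitted models. Confidence bounds are
#' interpolated with the same rule.
#'
#' @param curve A calibration curve (columns `score`, `prob`, `lo95`,
#'   `hi95`), e.g. from [tidy()] on a fitted calibrator or [read_curve()].
#' @param new_scores Numeric vector of scores to calibrate.
#' @return A tibble with columns `score`, `prob`, `lo95`, `hi95`, one row
#'   per element of `new_scores`, in input order.
#' @export
apply_curve <- function(curve, new_scores) {
  curve <- check_curve(curve)
  if (!is.numeric(new_scores) || length(new_scores) == 0L) {
    abort("`new_scores` must be a non-empty numeric vector.")
  }
  interp <- function(col) {
    v <- curve[[col]]
    if (all(is.na(v))) return(rep(NA_real_, length(new_scores)))
    if (nrow(curve) == 1L) return(rep(v, length(new_scores)))
    approx(curve$score, v, xout = new_scores, rule = 2)$y
  }
  tibble::tibble(
    score = as.numeric(new_scores),
    prob = interp("prob"),
    lo95 = interp("lo95"),
    hi95 = interp("hi95")
  )
}
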