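#' Calibrate classifier scores to the probability of disease
#'
#' Front door to the three calibrators: dispatches to [cal_parametric()],
#' [cal_semiparametric()] or [cal_nonparametric()]. All three return a fit
#' carrying the common calibration curve — the probability-of-disease
#' estimate with pointwise 95% confidence bounds at every distinct training
#' score — retrievable with [tidy()] and usable on new scores with
#' [predict()].
#'
#' @param data A data frame with columns `score` (arbitrary-scale real
#'   classifier score) and `truth` (0/1 truth state).
#' @param method One of `"parametric"`, `"semiparametric"`,
#'   `"nonparametric"`.
#' @param ... Passed to the method-specific fitting function.
#' @return A `probcal_fit` object.
#' @examples
#' d <- sample_scores(normal_model(), 100, 100, seed = 7)
#' fit <- calibrate(d, "parametric")
#' predict(fit, c(-1, 0.6, 2))
#' @export
calibrate <- function(data,
                      method = c("parametric", "semiparametric", "nonparametric"),
                      ...) {
  method <- match.arg(method)
  switch(method,
         parametric = cal_parametric(data, ...),
         semiparametric = cal_semiparametric(data, ...),
         nonparametric = cal_nonparametric(data, ...))
}

#' @export
print.probcal_fit <- function(x, ...) {
  cnt <- score_counts(x$data)
  cat(sprintf("Probability-of-disease calibration (%s method)\n", x$method))
  cat(sprintf("  subjects: %d (N0 = %d, N1 = %d)\n", cnt$n, cnt$n0, cnt$n1))
  if (x$method == "parametric") {
    cat(sprintf("  sigmoid: P = 1/(1 + exp(A y + B)), A = %.4f, B = %.4f%s\n",
                x$A, x$B, if (x$converged) "" else " (NOT converged)"))
  } else if (x$method == "semiparametric") {
    cat(sprintf("  latent proper-binormal: m = %.4f, s = %.4f, %d bins, eta = %g\n",
                x$fit$m, x$fit$s, nrow(x$fit$binning$bins), x$eta))
  } else {
    cat(sprintf("  isotonic (PAVA): %d blocks, bootstrap B = %d\n",
                nrow(x$blocks), x$bootstrap$B))
  }
  cat(sprintf("  curve: %d distinct scores in [%g, %g]\n",
              nrow(x$curve), min(x$curve$score), max(x$curve$score)))
  invisible(x)
}

#' Predict probability of disease at new scores
#'
#' For the semi- and non-parametric calibrators the calibration function is
#' defined on the distinct training scores, so new scores are mapped by
#' linear interpolation with clamping outside the training range (the
#' shared [apply_curve()] rule). The parametric calibrator overrides this
#' with its fitted formula (see [predict.cal_parametric()]).
#'
#' @param object A `probcal_fit`.
#' @param new_scores Numeric vector; defaults to the distinct training
#'   scores.
#' @param ... Unused.
#' @return A tibble with `score`, `prob`, `lo95`, `hi95`.
#' @export
predict.probcal_fit <- function(object, new_scores = NULL, ...) {
  if (is.null(new_scores)) return(object$curve)
  apply_curve(object$curve, new_scores)
}

#' Tidy a calibration fit into its calibration curve
#'
#' Returns the per-score calibration curve — the quantity of interest of
#' all three methods — as a tibble, following the convention that `tidy()`
#' extracts the estimate-level table of a fit.
#'
#' @param x A `probcal_fit`.
#' @param ... Unused.
#' @return A tibble with `score`, `prob`, `lo95`, `hi95`, `method`.
#' @method tidy probcal_fit
#' @export
tidy.probcal_fit <- function(x, ...) {
  dplyr::mutate(x$curve, method = x$method)
}

#' One-row summary of a calibration fit
#'
#' @param x A `probcal_fit`.
#' @param ... Unused.
#' @return A one-row tibble: subject counts, convergence, the
#'   resubstitution Brier score, the mean 95% CI width over training
#'   subjects, and method-specific parameters (`A`, `B` or `m`, `s`).
#' @method glance probcal_fit
#' @export
glance.probcal_fit <- function(x, ...) {
  cnt <- score_counts(x$data)
  preds <- predict(x, x$data$score)
  out <- tibble::tibble(
    method = x$method,
    n = cnt$n, n0 = cnt$n0, n1 = cnt$n1,
    converged = if (!is.null(x$converged)) x$converged else TRUE,
    brier_resub = brier_score(preds$prob, x$data$truth),
    mean_ci_width = mean(preds$hi95 - preds$lo95)
  )
  if (x$method == "parametric") {
    out$A <- x$A
    out$B <- x$B
  } else if (x$method == "semiparametric") {
    out$m <- x$fit$m
    out$s <- x$fit$s
  }
  out
}

#' Plot a calibration curve with its confidence band
#'
#' Draws the fitted probability-of-disease curve over the training score
#' range with the pointwise 95% band, a rug of the training scores by truth
#' state and, optionally, the true posterior of a known score model.
#'
#' @param object A `probcal_fit`.
#' @param true_model Optional [normal_model()]/[beta_model()] whose
#'   [true_posterior()] is overlaid as a dashed reference.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot probcal_fit
#' @export
autoplot.probcal_fit <- function(object, true_model = NULL, ...) {
  curve <- object$curve
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo95, ymax = .data$hi95),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$prob), color = "steelblue") +
    ggplot2::geom_rug(
      data = object$data,
      ggplot2::aes(x = .data$score, color = factor(.data$truth)),
      sides = "b", alpha = 0.5, inherit.aes = FALSE) +
    ggplot2::scale_color_manual(values = c(`0` = "grey40", `1` = "firebrick"),
                                name = "truth") +
    ggplot2::labs(x = "classifier score", y = "probability of disease",
                  title = sprintf("%s calibration", object$method)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::theme_minimal()
  if (!is.null(true_model)) {
    grid <- seq(min(curve$score), max(curve$score), length.out = 200)
    truth_df <- tibble::tibble(score = grid,
                               prob = true_posterior(true_model, grid))
    p <- p + ggplot2::geom_line(data = truth_df,
                                ggplot2::aes(y = .data$prob),
                                linetype = "dashed", color = "black")
  }
  p
}
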