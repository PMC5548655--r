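#' Brier score
#'
#' Mean squared difference between predicted probabilities and binary truth
#' states, \eqn{BS = N^{-1}\sum_i (\hat P_i - D_i)^2}. It mixes calibration
#' and discrimination: 0.25 for a constant 0.5 prediction, 0 only for
#' perfect certainty that is always right.
#'
#' @param probs Predicted probabilities.
#' @param truths 0/1 truth states, same length.
#' @return A single number in \[0, 1\].
#' @export
brier_score <- function(probs, truths) {
  if (length(probs) != length(truths) || length(probs) == 0L) {
    abort("`probs` and `truths` must have equal positive length.")
  }
  if (any(!truths %in% c(0, 1))) abort("`truths` must be 0/1.")
  mean((probs - truths)^2)
}

#' Mean squared error against the true posterior
#'
#' In simulations the true probability of disease is known analytically, so
#' calibration accuracy can be measured directly:
#' \eqn{MSE = N^{-1}\sum_i (\hat P_i - P_i)^2}. Unlike the Brier score this
#' does not involve the truth states and carries no resubstitution bias.
#'
#' @param probs Predicted probabilities.
#' @param true_probs True posterior probabilities, same length.
#' @return A single non-negative number.
#' @export
mse_vs_truth <- function(probs, true_probs) {
  if (length(probs) != length(true_probs) || length(probs) == 0L) {
    abort("`probs` and `true_probs` must have equal positive length.")
  }
  mean((probs - true_probs)^2)
}

#' Brier score of the perfectly calibrated calibration function
#'
#' The infinitely trained (theoretical) calibration function is the true
#' posterior \eqn{P(y)} itself, and its expected Brier score is
#' \deqn{E[(P(y) - D)^2] = E_{pooled}[P(y)(1 - P(y))],}
#' the expectation taken over the pooled score density
#' \eqn{\eta f_1 + (1-\eta) f_0}. Computed by adaptive quadrature to
#' absolute accuracy below 1e-5; this is the reference line against which
#' resubstitution (optimistic) and independent (pessimistic) finite-sample
#' Brier estimates are compared.
#'
#' @param model A [normal_model()] or [beta_model()].
#' @return The theoretical Brier score.
#' @examples
#' theoretical_brier(normal_model())
#' @export
theoretical_brier <- function(model) {
  stopifnot(inherits(model, "score_model"))
  eta <- model$eta
  integrand <- function(y) {
    f0 <- model_density(model, y, 0)
    f1 <- model_density(model, y, 1)
    pooled <- eta * f1 + (1 - eta) * f0
    num <- eta * f1
    p <- ifelse(pooled > 0, num / pooled, 0.5)
    p * (1 - p) * pooled
  }
  lims <- if (model$family == "beta") c(0, 1) else c(-Inf, Inf)
  integrate(integrand, lims[1L], lims[2L],
            abs.tol = 1e-7, rel.tol = 1e-9)$value
}

# Deterministic seed fan-out (documented): within one evaluation replicate,
# the training draw uses `seed`, the bootstrap uses seed + 1e6 and the
# independent test draw uses seed + 3e6; run_experiment() hands replicate r
# the base seed + r, so every sub-draw is reproducible in isolation.
SEED_BOOT_OFFSET <- 1000000L
SEED_TEST_OFFSET <- 3000000L

#' One calibration-evaluation replicate
#'
#' Draws a training score set (`n_per_class` per class) from the model,
#' fits the requested calibrator with its confidence-interval machinery,
#' and reports: the mean 95% CI width over training subjects, and the Brier
#' score and MSE against the true posterior under both evaluation
#' scenarios — *resubstitution* (predictions on the training set itself)
#' and *independent* (predictions on a freshly drawn set of the same size).
#' The parametric method predicts new scores with its fitted formula; the
#' semi- and non-parametric methods use the shared interpolate-and-clamp
#' rule.
#'
#' @param model A score model; its `eta` is used for the true posterior.
#' @param method Calibrator name.
#' @param n_per_class Training subjects per class.
#' @param seed Integer seed; sub-draws are derived deterministically.
#' @param B Bootstrap replicates for the non-parametric band.
#' @return A one-row tibble (`EvalReport` row). If the calibrator fails the
#'   row is returned with metric columns `NA` and `converged = FALSE`.
#' @export
evaluate_once <- function(model,
                          method = c("parametric", "semiparametric", "nonparametric"),
                          n_per_class = 100L, seed = 1L, B = 500L) {
  stopifnot(inherits(model, "score_model"))
  method <- match.arg(method)
  train <- sample_scores(model, n_per_class, n_per_class, seed = seed)
  test <- sample_scores(model, n_per_class, n_per_class,
                        seed = seed + SEED_TEST_OFFSET)
  row <- tibble::tibble(
    method = method, n_per_class = as.integer(n_per_class),
    seed = as.integer(seed), converged = FALSE,
    mean_ci_width = NA_real_,
    brier_resub = NA_real_, brier_indep = NA_real_,
    mse_resub = NA_real_, mse_indep = NA_real_
  )
  fit <- tryCatch(
    switch(method,
           parametric = cal_parametric(train),
           semiparametric = cal_semiparametric(train, eta = model$eta),
           nonparametric = cal_nonparametric(train, B = B,
                                             seed = seed + SEED_BOOT_OFFSET)),
    error = function(e) NULL)
  if (is.null(fit)) return(row)
  pred_tr <- predict(fit, train$score)
  pred_te <- predict(fit, test$score)
  row$converged <- if (!is.null(fit$converged)) fit$converged else TRUE
  row$mean_ci_width <- mean(pred_tr$hi95 - pred_tr$lo95)
  row$brier_resub <- brier_score(pred_tr$prob, train$truth)
  row$brier_indep <- brier_score(pred_te$prob, test$truth)
  row$mse_resub <- mse_vs_truth(pred_tr$prob, true_posterior(model, train$score))
  row$mse_indep <- mse_vs_truth(pred_te$prob, true_posterior(model, test$score))
  row
}

#' Repeated-simulation comparison of the three calibrators
#'
#' Runs [evaluate_once()] over a grid of training sizes and replicates for
#' each requested method and averages the metrics, producing the table
#' behind the CI-width, MSE and Brier-score versus sample-size comparisons.
#' Replicate r uses data seed `seed + r` (bootstrap `seed + 1e6 + r`,
#' independent test draw `seed + 3e6 + r`), so partial reruns reproduce
#' individual replicates.
#'
#' @param model A score model.
#' @param methods Character vector of calibrators to compare.
#' @param n_grid Training subjects per class, one experiment per value.
#' @param reps Replicates per cell (at least 2).
#' @param seed Base integer seed.
#' @param B Bootstrap replicates inside each non-parametric fit.
#' @param summarize If `FALSE`, return the per-replicate rows instead of
#'   cell means.
#' @return A tibble of class `probcal_experiment`; one row per method and
#'   training size (or per replicate when `summarize = FALSE`), with
#'   `n_failed` counting replicates whose fit failed (excluded from means).
#' @examples
#' \donttest{
#' run_experiment(normal_model(), n_grid = c(30, 100), reps = 5, seed = 1)
#' }
#' @export
run_experiment <- function(model,
                           methods = c("parametric", "semiparametric", "nonparametric"),
                           n_grid = c(30L, 50L, 100L, 200L, 300L),
                           reps = 50L, seed = 1L, B = 500L,
                           summarize = TRUE) {
  stopifnot(inherits(model, "score_model"))
  if (reps < 2L) abort("`reps` must be at least 2.")
  methods <- match.arg(methods,
                       c("parametric", "semiparametric", "nonparametric"),
                       several.ok = TRUE)
  grid <- tidyr::expand_grid(method = methods, n_per_class = as.integer(n_grid),
                             rep = seq_len(reps))
  rows <- purrr::pmap(grid, function(method, n_per_class, rep) {
    evaluate_once(model, method = method, n_per_class = n_per_class,
                  seed = seed + rep, B = B)
  })
  out <- dplyr::bind_rows(rows)
  out$rep <- grid$rep
  if (!summarize) {
    return(structure(tibble::as_tibble(out),
                     class = c("probcal_experiment", class(out)),
                     model = model, reps = as.integer(reps)))
  }
  summ <- out |>
    dplyr::group_by(.data$method, .data$n_per_class) |>
    dplyr::summarise(
      reps = dplyr::n(),
      n_failed = sum(!.data$converged & is.na(.data$mean_ci_width)),
      dplyr::across(c("mean_ci_width", "brier_resub", "brier_indep",
                      "mse_resub", "mse_indep"),
                    ~ mean(.x, na.rm = TRUE)),
      .groups = "drop"
    )
  structure(summ, class = c("probcal_experiment", class(summ)),
            model = model, reps = as.integer(reps))
}

#' Plot an evaluation experiment
#'
#' Three panels versus training size per class: mean 95% CI width, MSE
#' against the true posterior, and Brier score (resubstitution and
#' independent, with the theoretical infinite-training Brier score as a
#' dot-dash reference line).
#'
#' @param object A summarized [run_experiment()] table.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot probcal_experiment
#' @export
autoplot.probcal_experiment <- function(object, ...) {
  model <- attr(object, "model")
  long <- object |>
    tidyr::pivot_longer(c("mean_ci_width", "mse_resub", "mse_indep",
                          "brier_resub", "brier_indep"),
                        names_to = "metric", values_to = "value") |>
    dplyr::mutate(panel = dplyr::case_when(
      .data$metric == "mean_ci_width" ~ "95% CI width",
      grepl("^mse", .data$metric) ~ "MSE vs true posterior",
      TRUE ~ "Brier score"
    ))
  p <- ggplot2::ggplot(long,
                       ggplot2::aes(x = .data$n_per_class, y = .data$value,
                                    color = .data$method,
                                    linetype = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~ .data$panel, scales = "free_y") +
    ggplot2::labs(x = "training subjects per class", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(model)) {
    ref <- tibble::tibble(panel = "Brier score", value = theoretical_brier(model))
    p <- p + ggplot2::geom_hline(data = ref,
                                 ggplot2::aes(yintercept = .data$value),
                                 linetype = "dotdash", color = "grey30")
  }
  p
}
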