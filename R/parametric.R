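#' Platt regularized targets
#'
#' Instead of the raw 0/1 truth states, the parametric calibrator fits the
#' sigmoid against shrunken targets that pull the fitted probabilities away
#' from the boundary and keep the optimum finite even for perfectly
#' separated data: non-diseased subjects get \eqn{1/(N_0+1)} and diseased
#' subjects \eqn{(N_1+1)/(N_1+2)}.
#'
#' @param data A score set (see [validate_scores()]); both classes must be
#'   present.
#' @return Numeric vector of targets in (0, 1), one per subject.
#' @export
platt_targets <- function(data) {
  data <- validate_scores(data, require_both_classes = TRUE)
  cnt <- score_counts(data)
  ifelse(data$truth == 1L,
         (cnt$n1 + 1) / (cnt$n1 + 2),
         1 / (cnt$n0 + 1))
}

# Overflow-safe pieces of the cross-entropy objective for
# p = 1 / (1 + exp(z)): log(1 + exp(z)) and the per-subject loss.
log1pexp <- function(z) pmax(z, 0) + log1p(exp(-abs(z)))

# Objective F(A,B) = -sum t*log(p) + (1-t)*log(1-p), p = 1/(1+exp(Ay+B)).
platt_objective <- function(ab, y, t) {
  z <- ab[1L] * y + ab[2L]
  sum(log1pexp(z) - (1 - t) * z)
}

#' Fit the parametric (sigmoid) calibration function
#'
#' Fits \eqn{P(D=1|y) = 1/(1+\exp(Ay+B))} by maximum likelihood with Platt
#' regularized targets ([platt_targets()]), i.e. univariate logistic
#' regression with shrunken responses. The optimizer is Newton's method
#' with a backtracking (step-halving) line search on the cross-entropy
#' objective; all sigmoid and log evaluations are overflow-safe. The
#' covariance of \eqn{(\hat A, \hat B)} is the inverse of the analytic
#' Hessian at the optimum and feeds the delta-method standard errors of
#' [predict.cal_parametric()].
#'
#' A fitted slope \eqn{\hat A > 0} means the calibrated probability
#' *decreases* with the score (anti-rational orientation); the fit is
#' returned but a warning is emitted.
#'
#' @param data A data frame with columns `score` and `truth`; both classes
#'   must be present and at least two scores must be distinct.
#' @param tol Convergence tolerance on the max-norm of the gradient.
#' @param max_iter Maximum Newton iterations.
#' @return An object of class `c("cal_parametric", "probcal_fit")` with
#'   elements `A`, `B`, `cov`, `converged`, `n_iter`, `objective`, the
#'   training `data`, and `curve` (the calibration curve over distinct
#'   training scores with 95% Wald intervals).
#' @examples
#' d <- sample_scores(normal_model(), 100, 100, seed = 1)
#' fit <- cal_parametric(d)
#' glance(fit)
#' @export
cal_parametric <- function(data, tol = 1e-10, max_iter = 100L) {
  data <- validate_scores(data, require_both_classes = TRUE)
  y <- data$score
  if (length(unique(y)) < 2L) {
    abort("At least two distinct scores are required to fit the sigmoid.")
  }
  t <- platt_targets(data)
  cnt <- score_counts(data)

  # Newton with backtracking line search; initialization as in penalized
  # logistic practice: flat slope, intercept at the target log-odds.
  ab <- c(A = 0, B = log((cnt$n0 + 1) / (cnt$n1 + 1)))
  f_old <- platt_objective(ab, y, t)
  converged <- FALSE
  iter <- 0L
  repeat {
    z <- ab[1L] * y + ab[2L]
    p <- plogis(-z)                       # P(D=1|y)
    g <- c(sum(y * (t - p)), sum(t - p))  # gradient of F
    if (max(abs(g)) < tol) {
      converged <- TRUE
      break
    }
    if (iter >= max_iter) break
    w <- p * (1 - p)
    H <- matrix(c(sum(y^2 * w), sum(y * w), sum(y * w), sum(w)), 2L, 2L)
    step <- tryCatch(-solve(H, g), error = function(e) NULL)
    if (is.null(step)) break
    # backtracking: halve until the objective decreases
    lambda <- 1
    improved <- FALSE
    for (k in 1:40) {
      f_new <- platt_objective(ab + lambda * step, y, t)
      if (is.finite(f_new) && f_new < f_old) {
        ab <- ab + lambda * step
        f_old <- f_new
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) {
      # objective at its numerical floor; take the full Newton step if it
      # still contracts the gradient (quadratic convergence regime)
      ab_try <- ab + step
      z <- ab_try[1L] * y + ab_try[2L]
      g_try <- c(sum(y * (t - plogis(-z))), sum(t - plogis(-z)))
      if (max(abs(g_try)) < max(abs(g))) {
        ab <- ab_try
        f_old <- platt_objective(ab, y, t)
        improved <- TRUE
      }
    }
    iter <- iter + 1L
    if (!improved) break
  }
  if (!converged) {
    # a stalled line search at machine precision still counts as converged
    # if the gradient is tiny relative to the objective's scale
    z <- ab[1L] * y + ab[2L]
    p <- plogis(-z)
    g <- c(sum(y * (t - p)), sum(t - p))
    if (max(abs(g)) < max(tol, 1e-10 * cnt$n)) converged <- TRUE
    if (!converged) {
      warn(sprintf(
        "Parametric fit did not reach gradient tolerance %.1e in %d iterations.",
        tol, max_iter))
    }
  }

  z <- ab[1L] * y + ab[2L]
  w <- plogis(-z) * plogis(z)
  H <- matrix(c(sum(y^2 * w), sum(y * w), sum(y * w), sum(w)), 2L, 2L)
  cov <- tryCatch(solve(H), error = function(e) NULL)
  if (is.null(cov)) {
    warn("Singular Hessian: parameter covariance unavailable, SEs reported as NA.")
  }
  if (ab[1L] > 0) {
    warn(sprintf(
      "Fitted slope A = %.3g > 0: calibrated probability decreases with the score (anti-rational orientation).",
      ab[1L]))
  }

  fit <- structure(
    list(method = "parametric", A = unname(ab[1L]), B = unname(ab[2L]),
         cov = cov, converged = converged, n_iter = iter,
         objective = f_old, data = data, curve = NULL),
    class = c("cal_parametric", "probcal_fit")
  )
  fit$curve <- predict(fit, sort(unique(y)))
  fit
}

# Delta-method SE of P(y) = 1/(1+exp(Ay+B)):
# dP/dA = -y P(1-P), dP/dB = -P(1-P).
se_parametric <- function(fit, y) {
  if (is.null(fit$cov)) return(rep(NA_real_, length(y)))
  p <- plogis(-(fit$A * y + fit$B))
  dA <- -y * p * (1 - p)
  dB <- -p * (1 - p)
  v <- dA^2 * fit$cov[1L, 1L] + dB^2 * fit$cov[2L, 2L] +
    2 * dA * dB * fit$cov[1L, 2L]
  sqrt(pmax(v, 0))
}

#' Predict from a fitted parametric calibrator
#'
#' Evaluates the fitted sigmoid at new scores and attaches delta-method 95%
#' Wald intervals (\eqn{\hat P \pm 1.96\,\sigma_{\hat P}}, clipped to
#' \[0, 1\]). Unlike the semi- and non-parametric methods, the parametric
#' calibration function is a formula, so new scores are evaluated exactly
#' rather than by interpolation.
#'
#' @param object A `cal_parametric` fit.
#' @param new_scores Numeric vector of scores (defaults to the sorted
#'   distinct training scores).
#' @param ... Unused.
#' @return A tibble with columns `score`, `prob`, `lo95`, `hi95`.
#' @export
predict.cal_parametric <- function(object, new_scores = NULL, ...) {
  if (is.null(new_scores)) return(object$curve)
  if (!is.numeric(new_scores)) abort("`new_scores` must be numeric.")
  p <- plogis(-(object$A * new_scores + object$B))
  se <- se_parametric(object, new_scores)
  tibble::tibble(
    score = as.numeric(new_scores),
    prob = p,
    lo95 = clip01(p - 1.96 * se),
    hi95 = clip01(p + 1.96 * se)
  )
}

#' @export
coef.cal_parametric <- function(object, ...) c(A = object$A, B = object$B)

#' @export
vcov.cal_parametric <- function(object, ...) object$cov
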