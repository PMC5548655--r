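#' Score-generating models for simulation
#'
#' Two class-conditional score models drive the simulation studies.
#' `normal_model()` is the equal-variance binormal model
#' \eqn{y|D=0 \sim N(\mu_0, \sigma^2)}, \eqn{y|D=1 \sim N(\mu_1, \sigma^2)};
#' the defaults \eqn{\mu_0 = 0, \mu_1 = 1.2, \sigma = 1} give AUC
#' \eqn{\Phi(1.2/\sqrt 2) \approx 0.80}. `beta_model()` is the rational
#' beta pair on \[0, 1\]
#' \deqn{f(y|D=0) = \beta (1-y)^{\beta-1},\quad f(y|D=1) = \alpha y^{\alpha-1},
#'       \quad \alpha \ge 1, \beta \ge 1,}
#' whose likelihood ratio is monotone so the score is rational (proper ROC);
#' the defaults \eqn{\alpha = 1.1, \beta = 3.5} also give AUC close to 0.80.
#' `eta` is the prevalence of disease used when computing posteriors.
#'
#' An unequal-variance binormal model (set `sigma1` different from `sigma`)
#' is available as a deliberately non-rational score model for diagnostics;
#' its likelihood ratio is non-monotone.
#'
#' @param mu0,mu1 Class-conditional means of the binormal model.
#' @param sigma Common standard deviation (class 0; also class 1 unless
#'   `sigma1` is given).
#' @param sigma1 Optional class-1 standard deviation; defaults to `sigma`.
#' @param alpha,beta Shape parameters of the beta pair, both at least 1.
#' @param eta Prevalence of disease, strictly inside (0, 1).
#' @return An object of class `score_model`.
#' @examples
#' m <- normal_model()
#' model_auc(m)
#' true_posterior(m, 0.6)
#' @export
normal_model <- function(mu0 = 0, mu1 = 1.2, sigma = 1, eta = 0.5,
                         sigma1 = NULL) {
  if (!is.finite(sigma) || sigma <= 0) abort("`sigma` must be > 0.")
  if (is.null(sigma1)) sigma1 <- sigma
  if (!is.finite(sigma1) || sigma1 <= 0) abort("`sigma1` must be > 0.")
  check_eta(eta)
  structure(
    list(family = "normal", mu0 = mu0, mu1 = mu1, sigma0 = sigma,
         sigma1 = sigma1, eta = eta),
    class = "score_model"
  )
}

#' @rdname normal_model
#' @export
beta_model <- function(alpha = 1.1, beta = 3.5, eta = 0.5) {
  if (!is.finite(alpha) || alpha < 1) abort("`alpha` must be >= 1.")
  if (!is.finite(beta) || beta < 1) abort("`beta` must be >= 1.")
  check_eta(eta)
  structure(
    list(family = "beta", alpha = alpha, beta = beta, eta = eta),
    class = "score_model"
  )
}

check_eta <- function(eta) {
  if (!is.numeric(eta) || length(eta) != 1L || !is.finite(eta) ||
      eta <= 0 || eta >= 1) {
    abort("`eta` must be a prevalence strictly inside (0, 1).")
  }
  invisible(eta)
}

#' @export
print.score_model <- function(x, ...) {
  if (x$family == "normal") {
    cat(sprintf(
      "Score model: binormal, y|0 ~ N(%g, %g^2), y|1 ~ N(%g, %g^2), eta = %g\n",
      x$mu0, x$sigma0, x$mu1, x$sigma1, x$eta))
  } else {
    cat(sprintf(
      "Score model: beta pair, f(y|0) = %g(1-y)^%g, f(y|1) = %g y^%g, eta = %g\n",
      x$beta, x$beta - 1, x$alpha, x$alpha - 1, x$eta))
  }
  invisible(x)
}

# Class-conditional density f(y | D = class) of a score model.
model_density <- function(model, y, class) {
  stopifnot(inherits(model, "score_model"), class %in% c(0, 1))
  if (model$family == "normal") {
    if (class == 0) dnorm(y, model$mu0, model$sigma0)
    else dnorm(y, model$mu1, model$sigma1)
  } else {
    # f(y|0) = Beta(1, beta), f(y|1) = Beta(alpha, 1) on [0, 1]
    if (class == 0) dbeta(y, 1, model$beta) else dbeta(y, model$alpha, 1)
  }
}

#' Sample labeled scores from a score model
#'
#' Draws `n0` scores from the non-diseased distribution and `n1` from the
#' diseased distribution, returning a labeled score set. The draw is fully
#' determined by `seed` and does not disturb the caller's RNG state.
#'
#' @param model A [normal_model()] or [beta_model()].
#' @param n0,n1 Number of non-diseased and diseased subjects to draw.
#' @param seed Integer seed; required.
#' @return A tibble with columns `score` and `truth` (`n0` zeros followed by
#'   `n1` ones).
#' @export
sample_scores <- function(model, n0, n1, seed) {
  stopifnot(inherits(model, "score_model"))
  if (n0 < 0 || n1 < 0 || n0 + n1 == 0) {
    abort("`n0` and `n1` must be non-negative with at least one draw.")
  }
  with_seed(seed, {
    if (model$family == "normal") {
      y0 <- rnorm(n0, model$mu0, model$sigma0)
      y1 <- rnorm(n1, model$mu1, model$sigma1)
    } else {
      y0 <- rbeta(n0, 1, model$beta)
      y1 <- rbeta(n1, model$alpha, 1)
    }
    tibble::tibble(score = c(y0, y1),
                   truth = rep(c(0L, 1L), c(n0, n1)))
  })
}

#' True posterior probability of disease under a score model
#'
#' Bayes' rule at the model's prevalence:
#' \deqn{P(D=1|y) = \frac{\eta f(y|1)}{\eta f(y|1) + (1-\eta) f(y|0)}.}
#' For the beta pair the support is \[0, 1\] and queries outside it are an
#' error.
#'
#' @inheritParams sample_scores
#' @param y Numeric vector of scores.
#' @param eta Optional prevalence overriding the model's `eta`.
#' @return Vector of posterior probabilities.
#' @export
true_posterior <- function(model, y, eta = NULL) {
  stopifnot(inherits(model, "score_model"))
  eta <- if (is.null(eta)) model$eta else check_eta(eta)
  if (model$family == "beta" && (any(y < 0) || any(y > 1))) {
    abort("Beta-pair scores live on [0, 1]; query outside the support.")
  }
  f1 <- eta * model_density(model, y, 1)
  f0 <- (1 - eta) * model_density(model, y, 0)
  out <- f1 / (f1 + f0)
  # 0/0 can only occur in far normal tails; resolve by the likelihood-ratio
  # limit (equal-variance: sign of mu1 - mu0 decides the tail limit)
  if (any(!is.finite(out))) {
    bad <- !is.finite(out)
    if (model$family == "normal" && model$sigma0 == model$sigma1) {
      up <- model$mu1 > model$mu0
      out[bad] <- ifelse((y[bad] > (model$mu0 + model$mu1) / 2) == up, 1, 0)
    } else {
      abort("Posterior undefined (0/0) at a query point.")
    }
  }
  out
}

#' Area under the ROC curve of a score model
#'
#' Closed form \eqn{\Phi((\mu_1-\mu_0)/\sqrt{\sigma_0^2+\sigma_1^2})} for the
#' binormal model; \eqn{1 - \alpha B(\alpha, \beta + 1)} for the beta pair
#' (the concordance probability \eqn{P(Y_1 > Y_0)} integrates in closed
#' form).
#'
#' @inheritParams sample_scores
#' @return AUC in \[0.5, 1\] for rational parameterizations.
#' @export
model_auc <- function(model) {
  stopifnot(inherits(model, "score_model"))
  if (model$family == "normal") {
    pnorm((model$mu1 - model$mu0) / sqrt(model$sigma0^2 + model$sigma1^2))
  } else {
    1 - model$alpha * beta(model$alpha, model$beta + 1)
  }
}

#' Theory of the linear Gaussian classifier
#'
#' `gaussian_world()` describes a p-dimensional biomarker vector with
#' class-conditional normals \eqn{X|D \sim N(\mu_D, V)} (common covariance)
#' and a linear classifier score \eqn{y = w^T X}.
#' `linear_classifier_auc()` is the induced AUC
#' \deqn{AUC = \Phi\!\left(\frac{w^T(\mu_1 - \mu_0)}{\sqrt{2\, w^T V w}}\right),}
#' and `perfect_calibration_params()` returns the unique sigmoid parameters
#' \eqn{(A, B)} for which \eqn{P = 1/(1+\exp(Ay+B))} is the perfectly
#' calibrated probability of disease at prevalence \eqn{\eta}:
#' \deqn{A = -\frac{w^T(\mu_1-\mu_0)}{w^T V w},\qquad
#'       B = \frac{w^T(\mu_1\mu_1^T - \mu_0\mu_0^T)w}{2\, w^T V w}
#'           - \log\frac{\eta}{1-\eta}.}
#' Any monotone calibration leaves AUC untouched, so discrimination and
#' calibration are not in conflict for such classifiers.
#'
#' @param mu0,mu1 Class-conditional mean vectors (length p).
#' @param V p-by-p symmetric positive-definite covariance matrix.
#' @param w Length-p classifier coefficient vector (nonzero).
#' @param eta Prevalence of disease.
#' @param world A `gaussian_world` object.
#' @return `linear_classifier_auc()`: a probability.
#'   `perfect_calibration_params()`: a named list with `A` and `B`.
#' @examples
#' w <- gaussian_world(mu0 = 0, mu1 = 1.2, V = 1, w = 1)
#' linear_classifier_auc(w)
#' perfect_calibration_params(w)
#' @export
gaussian_world <- function(mu0, mu1, V, w, eta = 0.5) {
  mu0 <- as.numeric(mu0); mu1 <- as.numeric(mu1); w <- as.numeric(w)
  V <- as.matrix(V)
  p <- length(w)
  if (length(mu0) != p || length(mu1) != p || any(dim(V) != p)) {
    abort("`mu0`, `mu1`, `w` and `V` must have matching dimension p.")
  }
  if (max(abs(V - t(V))) > 1e-10 * max(1, max(abs(V)))) {
    abort("`V` must be symmetric.")
  }
  if (any(eigen(V, symmetric = TRUE, only.values = TRUE)$values <= 0)) {
    abort("`V` must be positive definite.")
  }
  check_eta(eta)
  structure(list(p = p, mu0 = mu0, mu1 = mu1, V = V, w = w, eta = eta),
            class = "gaussian_world")
}

#' @rdname gaussian_world
#' @export
linear_classifier_auc <- function(world) {
  stopifnot(inherits(world, "gaussian_world"))
  w <- world$w
  if (all(w == 0)) abort("Classifier coefficients `w` must be nonzero.")
  num <- sum(w * (world$mu1 - world$mu0))
  pnorm(num / sqrt(2 * drop(t(w) %*% world$V %*% w)))
}

#' @rdname gaussian_world
#' @export
perfect_calibration_params <- function(world) {
  stopifnot(inherits(world, "gaussian_world"))
  w <- world$w
  if (all(w == 0)) abort("Classifier coefficients `w` must be nonzero.")
  wVw <- drop(t(w) %*% world$V %*% w)
  A <- -sum(w * (world$mu1 - world$mu0)) / wVw
  quad <- drop(t(w) %*% (tcrossprod(world$mu1) - tcrossprod(world$mu0)) %*% w)
  B <- quad / (2 * wVw) - log(world$eta / (1 - world$eta))
  list(A = A, B = B)
}

#' Check rationality of a score model on a grid
#'
#' A score is rational when it is a monotonically increasing function of its
#' own likelihood ratio \eqn{LR(y) = f(y|1)/f(y|0)}; equivalently the
#' posterior probability of disease increases with the score and the ROC
#' curve is proper (convex). The check evaluates \eqn{LR} on an ascending
#' grid and reports the first strict decrease beyond tolerance, if any.
#'
#' @inheritParams sample_scores
#' @param grid Ascending numeric grid inside the score support.
#' @param tol Violations smaller than this are ignored.
#' @return A list with `pass` (logical) and, on failure, `violation`: the
#'   first grid pair `(y1, y2)` with `LR(y1) > LR(y2)`.
#' @export
rationality_check <- function(model, grid, tol = 1e-12) {
  stopifnot(inherits(model, "score_model"))
  if (is.unsorted(grid)) abort("`grid` must be sorted ascending.")
  if (model$family == "beta" && (any(grid < 0) || any(grid > 1))) {
    abort("Grid outside the beta-pair support [0, 1].")
  }
  lr <- model_density(model, grid, 1) / model_density(model, grid, 0)
  dec <- which(diff(lr) < -tol)
  if (length(dec) == 0L) {
    list(pass = TRUE, violation = NULL)
  } else {
    i <- dec[1L]
    list(pass = FALSE,
         violation = tibble::tibble(y1 = grid[i], y2 = grid[i + 1L],
                                    lr1 = lr[i], lr2 = lr[i + 1L]))
  }
}

#' AUC of a perfectly calibrated score uniform over the population
#'
#' Under the assumption that calibrated probability scores are uniformly
#' distributed in the whole population with prevalence 1/2, the
#' class-conditional densities are \eqn{f_1(p) = 2p} and
#' \eqn{f_0(p) = 2(1-p)}, and the AUC has the closed form
#' \eqn{\int_0^1 F_0(p) f_1(p)\,dp = 5/6 \approx 0.83}. This ceiling is an
#' artifact of the uniformity assumption, not a property of calibrated
#' scores in general: any AUC in (0.5, 1) is compatible with perfect
#' calibration.
#'
#' @return The exact value 5/6.
#' @export
diamond_uniform_auc <- function() {
  # F0(p) = 1 - (1-p)^2; integral of (1 - (1-p)^2) * 2p dp on [0,1] = 5/6
  5 / 6
}
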