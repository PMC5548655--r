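#' Truth-state-run binning of a score set
#'
#' Sorts the subjects by score and forms bins from maximal runs of
#' consecutive subjects sharing one truth state. A distinct score value
#' shared by subjects of both truth states (a mixed tie) forms its own bin
#' and terminates the adjacent runs. This data-driven binning (rather than
#' ad-hoc categories) is what the semi-parametric latent model is fitted
#' to: the bin counts per class are a sufficient multinomial summary under
#' the monotone-latent-transformation assumption.
#'
#' @param data A data frame with columns `score` and `truth`; both classes
#'   must be present.
#' @return An object of class `run_binning`: a list with `bins` (tibble:
#'   `bin`, `count0`, `count1`, `score_lo`, `score_hi`), `distinct`
#'   (tibble: distinct ascending `score`, per-score class counts `c0`,
#'   `c1`, and its `bin`), and class totals `n0`, `n1`.
#' @examples
#' d <- data.frame(score = 1:10, truth = c(0, 1, 0, 0, 1, 1, 0, 1, 1, 1))
#' run_binning(d)$bins
#' @export
run_binning <- function(data) {
  data <- validate_scores(data, require_both_classes = TRUE)
  ord <- order(data$score)
  s <- data$score[ord]
  d <- data$truth[ord]
  grp <- cumsum(c(TRUE, diff(s) > 0))
  c0 <- as.vector(rowsum(as.numeric(d == 0L), grp))
  c1 <- as.vector(rowsum(as.numeric(d == 1L), grp))
  sc <- s[!duplicated(grp)]

  m <- length(sc)
  bin_of <- integer(m)    # bin index per distinct score
  cur <- 0L
  state <- NA_integer_  # truth state of the open run; NA = no open run
  for (j in seq_len(m)) {
    mixed <- c0[j] > 0 && c1[j] > 0
    if (mixed) {
      cur <- cur + 1L
      bin_of[j] <- cur
      state <- NA_integer_
    } else {
      cls <- if (c1[j] > 0) 1L else 0L
      if (is.na(state) || cls != state) {
        cur <- cur + 1L
        state <- cls
      }
      bin_of[j] <- cur
    }
  }
  bins <- tibble::tibble(
    bin = seq_len(cur),
    count0 = as.vector(rowsum(c0, bin_of)),
    count1 = as.vector(rowsum(c1, bin_of)),
    score_lo = sc[!duplicated(bin_of)],
    score_hi = sc[rev(!duplicated(rev(bin_of)))]
  )
  structure(
    list(bins = bins,
         distinct = tibble::tibble(score = sc, c0 = c0, c1 = c1, bin = bin_of),
         n0 = sum(c0), n1 = sum(c1)),
    class = "run_binning"
  )
}

#' @export
print.run_binning <- function(x, ...) {
  cat(sprintf("Truth-state-run binning: %d bins, N0 = %d, N1 = %d\n",
              nrow(x$bins), x$n0, x$n1))
  print(x$bins, ...)
  invisible(x)
}

# ---- latent likelihood-ratio geometry -------------------------------------
#
# The latent raw axis z has class-0 density N(0,1) and class-1 density
# N(m, s^2). The decision axis is u(z) = log LR(z), a quadratic in z:
#   u(z) = z^2/2 - (z - m)^2 / (2 s^2) - log s = a z^2 + b z + c
#   a = (1 - 1/s^2)/2,  b = m/s^2,  c = -m^2/(2 s^2) - log s.
# For s > 1 the sublevel set {u <= t} is the interval between the two real
# roots (empty below the minimum of u); for s < 1 it is the complement of
# an interval; near s = 1, u is linear in z. All probabilities are
# differences of normal CDFs at the roots.

u_coefs <- function(m, s) {
  list(a = 0.5 * (1 - 1 / s^2), b = m / s^2, c = -m^2 / (2 * s^2) - log(s))
}

EQUAL_VAR_EPS <- 1e-8

# P_class( u(z) <= t ), vectorized over t; t may be +-Inf.
p_u_le <- function(t, m, s, class) {
  if (!is.finite(s) || s <= 0) abort("Latent scale `s` must be > 0.")
  cdf <- if (class == 0) {
    function(z) pnorm(z)
  } else {
    function(z) pnorm((z - m) / s)
  }
  out <- numeric(length(t))
  out[t == Inf] <- 1
  fin <- is.finite(t)
  if (!any(fin)) return(out)
  tt <- t[fin]
  co <- u_coefs(m, s)
  if (abs(s - 1) < EQUAL_VAR_EPS) {
    if (abs(co$b) < 1e-12) {
      val <- as.numeric(tt >= co$c)      # LR constant: u is a point mass at c
    } else if (co$b > 0) {
      val <- cdf((tt - co$c) / co$b)
    } else {
      val <- 1 - cdf((tt - co$c) / co$b)
    }
  } else {
    disc <- co$b^2 - 4 * co$a * (co$c - tt)
    pos <- disc > 0
    r <- sqrt(pmax(disc, 0))
    if (co$a > 0) {
      val <- numeric(length(tt))          # below the minimum of u: empty set
      z1 <- (-co$b - r[pos]) / (2 * co$a)
      z2 <- (-co$b + r[pos]) / (2 * co$a)
      val[pos] <- cdf(z2) - cdf(z1)
    } else {
      val <- rep(1, length(tt))           # above the maximum of u: full mass
      za <- (-co$b - r[pos]) / (2 * co$a)
      zb <- (-co$b + r[pos]) / (2 * co$a)
      z1 <- pmin(za, zb)
      z2 <- pmax(za, zb)
      val[pos] <- cdf(z1) + 1 - cdf(z2)
    }
  }
  out[fin] <- val
  out
}

# Density of u under the given class at finite t (change of variables over
# the quadratic's roots).
u_density <- function(t, m, s, class) {
  dens <- if (class == 0) {
    function(z) dnorm(z)
  } else {
    function(z) dnorm((z - m) / s) / s
  }
  co <- u_coefs(m, s)
  out <- numeric(length(t))
  fin <- is.finite(t)
  if (!any(fin)) return(out)
  tt <- t[fin]
  if (abs(s - 1) < EQUAL_VAR_EPS) {
    if (abs(co$b) < 1e-12) {
      val <- rep(0, length(tt))
    } else {
      z <- (tt - co$c) / co$b
      val <- dens(z) / abs(co$b)
    }
  } else {
    disc <- co$b^2 - 4 * co$a * (co$c - tt)
    pos <- disc > 0
    r <- sqrt(pmax(disc, 0))
    z1 <- (-co$b - r[pos]) / (2 * co$a)
    z2 <- (-co$b + r[pos]) / (2 * co$a)
    val <- numeric(length(tt))
    val[pos] <- dens(z1) / abs(2 * co$a * z1 + co$b) +
      dens(z2) / abs(2 * co$a * z2 + co$b)
  }
  out[fin] <- val
  out
}

#' Latent-model bin probability
#'
#' Probability, under the latent proper-binormal model (class 0 latent
#' \eqn{N(0,1)}, class 1 latent \eqn{N(m, s^2)}, decision axis
#' \eqn{u = \log LR}), that a subject of the given class falls in the
#' log-likelihood-ratio interval \eqn{(t_{lo}, t_{hi}]}. Computed
#' analytically from the roots of the quadratic \eqn{u(z) = t}.
#'
#' @param m,s Latent class-1 mean and standard deviation (`s > 0`).
#' @param t_lo,t_hi Interval endpoints on the log-LR axis; infinite values
#'   allowed.
#' @param class Truth state, 0 or 1.
#' @return A probability.
#' @export
latent_bin_probs <- function(m, s, t_lo, t_hi, class) {
  if (!is.finite(s) || s <= 0) abort("`s` must be > 0.")
  if (!(class %in% c(0, 1))) abort("`class` must be 0 or 1.")
  if (t_lo >= t_hi) abort("`t_lo` must be strictly below `t_hi`.")
  p_u_le(t_hi, m, s, class) - p_u_le(t_lo, m, s, class)
}

# ---- multinomial likelihood over run bins ---------------------------------
#
# Parameters are optimized in the unconstrained space
# theta = (m, log s, t1, log-gaps d2..d_{I-1}); boundaries are
# t_j = t1 + sum_{k<=j} exp(d_k), which enforces strict ordering.

theta_to_boundaries <- function(theta) {
  nI <- length(theta) - 2L          # = I - 1 boundaries
  if (nI == 1L) return(theta[3L])
  theta[3L] + cumsum(c(0, exp(theta[-(1:3)])))
}

bin_prob_matrix <- function(m, s, bounds) {
  edges <- c(-Inf, bounds, Inf)
  p0 <- diff(p_u_le(edges, m, s, 0))
  p1 <- diff(p_u_le(edges, m, s, 1))
  list(p0 = pmax(p0, 1e-300), p1 = pmax(p1, 1e-300))
}

negloglik_runbins <- function(theta, n0, n1) {
  m <- theta[1L]
  s <- exp(theta[2L])
  pr <- bin_prob_matrix(m, s, theta_to_boundaries(theta))
  -(sum(n0 * log(pr$p0)) + sum(n1 * log(pr$p1)))
}

# Gradient of the negative log-likelihood: analytic in the boundary
# parameters (each boundary touches only its two flanking bins), central
# finite differences in (m, log s).
negloglik_grad <- function(theta, n0, n1) {
  m <- theta[1L]
  s <- exp(theta[2L])
  bounds <- theta_to_boundaries(theta)
  pr <- bin_prob_matrix(m, s, bounds)
  I <- length(n0)
  j <- seq_len(I - 1L)
  g_t <- u_density(bounds, m, s, 0) *
    (n0[j] / pr$p0[j] - n0[j + 1L] / pr$p0[j + 1L]) +
    u_density(bounds, m, s, 1) *
    (n1[j] / pr$p1[j] - n1[j + 1L] / pr$p1[j + 1L])
  # chain rule through t_j = t1 + cumsum(exp(d))
  g_bound <- c(sum(g_t),
               if (I > 2L) exp(theta[-(1:3)]) * rev(cumsum(rev(g_t)))[-1L])
  g_ms <- numeric(2L)
  for (k in 1:2) {
    h <- 1e-5 * max(1, abs(theta[k]))
    up <- theta; up[k] <- up[k] + h
    dn <- theta; dn[k] <- dn[k] - h
    g_ms[k] <- (negloglik_runbins(up, n0, n1) -
                  negloglik_runbins(dn, n0, n1)) / (2 * h)
  }
  c(g_ms, -g_bound)
}

# Rank-based deterministic initialization: class separation from the
# normal-deviate transform of within-class mean pooled ranks; boundaries
# from empirical pooled quantiles pushed through the initial (linear) u.
init_theta <- function(binning) {
  bins <- binning$bins
  n_bin <- bins$count0 + bins$count1
  ntot <- sum(n_bin)
  cum <- cumsum(n_bin)
  midrank <- cum - (n_bin - 1) / 2
  mr0 <- sum(bins$count0 * midrank) / binning$n0
  mr1 <- sum(bins$count1 * midrank) / binning$n1
  m0 <- qnorm(mr1 / (ntot + 1)) - qnorm(mr0 / (ntot + 1))
  m0 <- min(max(m0, 0.1), 5)
  q <- cum[-length(cum)] / ntot
  t0 <- m0 * qnorm(q) - m0^2 / 2
  c(m0, 0, t0[1L], if (length(t0) > 1L) log(diff(t0)))
}

#' Fit the latent proper-binormal model to run bins
#'
#' Maximizes the multinomial likelihood of the per-class bin counts over
#' the latent parameters: class-1 mean `m` and standard deviation `s`
#' (class 0 fixed at standard normal) and the `I - 1` ascending bin
#' boundaries on the log-likelihood-ratio axis. Optimization is
#' quasi-Newton (L-BFGS) in an unconstrained parameterization
#' (`m`, `log s`, first boundary, log-gaps) with an analytic boundary
#' gradient, from a deterministic rank-based initialization; refitting
#' identical inputs reproduces the fit exactly. The parameter covariance is
#' the inverse observed information (finite-difference Hessian of the
#' gradient), mapped to the natural parameters by the delta method.
#'
#' @param binning A [run_binning()] object (at least 2 bins).
#' @param tol Relative convergence tolerance passed to the optimizer.
#' @param se Compute the parameter covariance (needed for LLR standard
#'   errors). `NULL` (default) computes it unless the parameter count
#'   `I + 1` exceeds `se_limit`.
#' @param se_limit Parameter-count cutoff for the automatic `se` choice.
#' @param max_iter Maximum optimizer iterations.
#' @param engine `"joint"` maximizes over all `I + 1` parameters;
#'   `"profile"` anchors each boundary at the pooled-mixture u-quantile of
#'   its empirical cumulative fraction (re-anchored at every objective
#'   evaluation) and maximizes over `(m, log s)` alone — the two agree
#'   asymptotically, and the profile engine keeps run binning of large
#'   continuous samples (one parameter per boundary, most bins a single
#'   subject) tractable. `"auto"` picks joint up to `joint_limit` bins.
#' @param joint_limit Bin-count cutoff for the automatic engine choice.
#' @return An object of class `proper_binormal_fit`: latent `m`, `s`,
#'   `boundaries` (log-LR axis), `cov` (natural parameters `m`, `s`,
#'   boundaries; `NULL` when not computed), `loglik`, `converged`,
#'   `n_iter`, and the `binning`.
#' @export
fit_proper_binormal <- function(binning, tol = 1e-9, se = NULL,
                                se_limit = 1500L, max_iter = 1000L,
                                engine = c("auto", "joint", "profile"),
                                joint_limit = 2000L) {
  stopifnot(inherits(binning, "run_binning"))
  engine <- match.arg(engine)
  n0 <- binning$bins$count0
  n1 <- binning$bins$count1
  I <- length(n0)
  if (I < 2L) {
    abort("At least 2 truth-state-run bins are required (scores carry no ordering signal).")
  }
  if (engine == "auto") engine <- if (I <= joint_limit) "joint" else "profile"
  if (engine == "profile") {
    return(fit_proper_binormal_profile(binning, tol = tol, se = se,
                                       max_iter = max_iter))
  }
  theta0 <- init_theta(binning)
  opt <- optim(theta0, fn = negloglik_runbins, gr = negloglik_grad,
               n0 = n0, n1 = n1, method = "L-BFGS-B",
               control = list(maxit = max_iter, factr = tol / .Machine$double.eps))
  theta <- opt$par
  m <- theta[1L]
  s <- exp(theta[2L])
  if (abs(m) < 1e-5) {
    abort("No discrimination signal: latent separation collapsed (likelihood ratio constant).")
  }
  bounds <- theta_to_boundaries(theta)
  if (is.null(se)) se <- (I + 1L) <= se_limit
  cov_u <- NULL
  cov_nat <- NULL
  if (se) {
    p <- length(theta)
    H <- matrix(0, p, p)
    for (k in seq_len(p)) {
      h <- 1e-4 * max(1, abs(theta[k]))
      up <- theta; up[k] <- up[k] + h
      dn <- theta; dn[k] <- dn[k] - h
      H[, k] <- (negloglik_grad(up, n0, n1) - negloglik_grad(dn, n0, n1)) / (2 * h)
    }
    H <- (H + t(H)) / 2
    ev <- eigen(H, symmetric = TRUE)
    vals <- pmax(ev$values, 1e-10)          # SPD repair by eigenvalue flooring
    cov_theta <- ev$vectors %*% (t(ev$vectors) / vals)
    # map (m, log s, t1, d..) -> (m, log s, T1..T_{I-1})
    J <- diag(p)
    if (I > 2L) {
      for (jj in 2:(I - 1L)) {
        J[2L + jj, 3L + seq_len(jj - 1L)] <- exp(theta[3L + seq_len(jj - 1L)])
      }
    }
    cov_u <- J %*% cov_theta %*% t(J)
    # natural scale: s = exp(log s)
    Js <- diag(p)
    Js[2L, 2L] <- s
    cov_nat <- Js %*% cov_u %*% t(Js)
  }
  structure(
    list(m = m, s = s, boundaries = bounds,
         cov = cov_nat, cov_u = cov_u,
         loglik = -opt$value, converged = opt$convergence == 0L,
         n_iter = opt$counts[["function"]], binning = binning,
         theta = theta, engine = "joint"),
    class = "proper_binormal_fit"
  )
}

# Profile engine: boundaries are anchored, inside every objective
# evaluation, at the pooled-mixture u-quantiles of the empirical cumulative
# bin fractions, and the multinomial likelihood is maximized over
# (m, log s) alone. Re-anchoring inside the objective is essential: with
# boundaries held fixed at quantiles of a wrong (m, s), that (m, s) is a
# self-consistent stationary point.
fit_proper_binormal_profile <- function(binning, tol = 1e-9, se = NULL,
                                        max_iter = 1000L) {
  n0 <- binning$bins$count0
  n1 <- binning$bins$count1
  ntot <- binning$n0 + binning$n1
  w1 <- binning$n1 / ntot
  q <- cumsum(n0 + n1)[-length(n0)] / ntot
  anchored <- function(m, s) pooled_quantile(q, m, s, w1)
  nll <- function(par) {
    m <- par[1L]
    s <- exp(par[2L])
    pr <- bin_prob_matrix(m, s, anchored(m, s))
    -(sum(n0 * log(pr$p0)) + sum(n1 * log(pr$p1)))
  }
  theta0 <- init_theta(binning)[1:2]
  opt <- optim(theta0, nll, method = "Nelder-Mead",
               control = list(maxit = max_iter, reltol = tol))
  m <- opt$par[1L]
  s <- exp(opt$par[2L])
  if (abs(m) < 1e-5) {
    abort("No discrimination signal: latent separation collapsed (likelihood ratio constant).")
  }
  if (is.null(se)) se <- FALSE
  cov_u <- NULL
  cov_nat <- NULL
  if (se) {
    # observed profile information in (m, log s)
    H <- matrix(0, 2L, 2L)
    h <- 1e-4 * pmax(1, abs(opt$par))
    for (k in 1:2) {
      for (l in 1:k) {
        ek <- el <- c(0, 0); ek[k] <- h[k]; el[l] <- h[l]
        H[k, l] <- H[l, k] <-
          (nll(opt$par + ek + el) - nll(opt$par + ek - el) -
             nll(opt$par - ek + el) + nll(opt$par - ek - el)) /
          (4 * h[k] * h[l])
      }
    }
    ev <- eigen(H, symmetric = TRUE)
    vals <- pmax(ev$values, 1e-10)
    cov_u <- ev$vectors %*% (t(ev$vectors) / vals)
    cov_nat <- diag(c(1, s)) %*% cov_u %*% diag(c(1, s))
  }
  structure(
    list(m = m, s = s, boundaries = anchored(m, s),
         cov = cov_nat, cov_u = cov_u,
         loglik = -opt$value, converged = opt$convergence == 0L,
         n_iter = opt$counts[["function"]], binning = binning,
         theta = opt$par, engine = "profile"),
    class = "proper_binormal_fit"
  )
}

#' @export
print.proper_binormal_fit <- function(x, ...) {
  cat(sprintf(
    "Proper-binormal latent fit: m = %.4f, s = %.4f, %d bins, logLik = %.3f%s\n",
    x$m, x$s, nrow(x$binning$bins), x$loglik,
    if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

# ---- mapping distinct scores to the latent log-LR axis --------------------

# Pooled-mixture CDF of u with sample class weights.
pooled_cdf <- function(t, m, s, w1) {
  (1 - w1) * p_u_le(t, m, s, 0) + w1 * p_u_le(t, m, s, 1)
}

# Vectorized quantile inversion of the pooled CDF by bisection.
pooled_quantile <- function(targets, m, s, w1) {
  co <- u_coefs(m, s)
  zs <- c(-1, 1) * (12 + abs(m) + 12 * s)
  uz <- co$a * zs^2 + co$b * zs + co$c
  cand <- uz
  if (abs(co$a) > 0) cand <- c(cand, co$c - co$b^2 / (4 * co$a))
  lo <- rep(min(cand) - 1, length(targets))
  hi <- rep(max(cand) + 1, length(targets))
  for (it in 1:60) {
    mid <- (lo + hi) / 2
    below <- pooled_cdf(mid, m, s, w1) < targets
    lo[below] <- mid[below]
    hi[!below] <- mid[!below]
  }
  (lo + hi) / 2
}

# Complementary latent values for a set of distinct scores, vectorized
# across bins. Sub-boundaries split each bin's latent interval so the
# pooled-model mass of every sub-interval matches its empirical share of
# the bin's subjects; each distinct score is then represented by the median
# of the pooled mixture restricted to its sub-interval ("mixture" rule) or
# by the arithmetic midpoint of its sub-interval ("midpoint" rule; outer
# sub-intervals with an infinite latent edge fall back to the mixture
# median). `counts` and `bin_id` are per distinct score; `C_edges` is the
# pooled CDF at the I + 1 latent bin edges.
utilde_vec <- function(counts, bin_id, C_edges, m, s, w1, rule,
                       edges_t = NULL) {
  K <- ave(counts, bin_id, FUN = sum)
  cumk <- ave(counts, bin_id, FUN = cumsum)
  C_lo_bin <- C_edges[bin_id]
  span <- C_edges[bin_id + 1L] - C_lo_bin
  edge_C <- C_lo_bin + (cumk / K) * span          # upper sub-edge, in CDF units
  prev_C <- C_lo_bin + ((cumk - counts) / K) * span
  u_med <- pooled_quantile((prev_C + edge_C) / 2, m, s, w1)
  want_edges <- !is.null(edges_t) || rule == "midpoint"
  if (want_edges) {
    lo_u <- pooled_quantile(prev_C, m, s, w1)
    hi_u <- pooled_quantile(edge_C, m, s, w1)
    if (!is.null(edges_t)) {
      # sub-edges coinciding with bin boundaries are exact (possibly infinite)
      at_lo <- cumk - counts == 0
      at_hi <- cumk == K
      lo_u[at_lo] <- edges_t[bin_id[at_lo]]
      hi_u[at_hi] <- edges_t[bin_id[at_hi] + 1L]
    }
  }
  if (rule == "midpoint") {
    mid <- (lo_u + hi_u) / 2
    usable <- prev_C > 0 & edge_C < 1 & is.finite(mid)
    u_med[usable] <- mid[usable]
  }
  if (is.null(edges_t)) u_med else list(u = u_med, lo = lo_u, hi = hi_u)
}

#' Map distinct scores to latent log-likelihood-ratio values
#'
#' Places each distinct training score on the latent log-LR axis of a
#' fitted proper-binormal model. Within the latent interval of each run
#' bin, sub-boundaries are positioned so that the pooled-mixture mass
#' (classes weighted by their sample proportions) of every sub-interval
#' equals that sub-interval's empirical share of the bin's subjects; the
#' complementary value \eqn{\tilde u} of a distinct score is the median of
#' the pooled mixture restricted to its sub-interval. Because the latent
#' axis is itself the log likelihood ratio, \eqn{LLR(y) = \tilde u}, and
#' the posterior at prevalence \eqn{\eta} follows from Bayes' theorem:
#' \deqn{P(D=1|y) = \frac{\eta e^{LLR}}{\eta e^{LLR} + 1 - \eta}.}
#' The standard error of \eqn{\tilde u} combines two delta-method terms:
#' the MLE covariance of the latent distribution parameters `(m, log s)`
#' propagated by finite-difference gradients of the map, and the binomial
#' uncertainty of the score's empirical pooled cumulative fraction
#' propagated through the inverse pooled CDF (slope one over the pooled
#' latent density). Run bins of continuous scores mostly hold a single
#' subject, so the Wald variances of individual boundary parameters are
#' too unstable to contract directly; the quantile term plays their role.
#'
#' @param fit A [fit_proper_binormal()] object.
#' @param eta Assumed prevalence of disease in (0, 1).
#' @param rule Complementary-value rule: `"mixture"` (pooled-mixture
#'   median, default) or `"midpoint"` (interval midpoint).
#' @param se Compute LLR standard errors (requires the fit covariance).
#' @return A tibble with one row per distinct score: `score`, latent
#'   interval `u_lo`/`u_hi`, complementary value `u_tilde`, `llr`,
#'   `llr_se`, and posterior `prob`.
#' @export
map_scores_to_latent <- function(fit, eta = 0.5, rule = c("mixture", "midpoint"),
                                 se = TRUE) {
  stopifnot(inherits(fit, "proper_binormal_fit"))
  rule <- match.arg(rule)
  check_eta(eta)
  binning <- fit$binning
  dst <- binning$distinct
  w1 <- binning$n1 / (binning$n0 + binning$n1)
  edges <- c(-Inf, fit$boundaries, Inf)
  counts <- dst$c0 + dst$c1

  utilde_all <- function(m, s, edges_t, rows = seq_len(nrow(dst))) {
    C_edges <- pooled_cdf(edges_t, m, s, w1)
    utilde_vec(counts[rows], dst$bin[rows], C_edges, m, s, w1, rule)
  }
  full <- utilde_vec(counts, dst$bin, pooled_cdf(edges, fit$m, fit$s, w1),
                     fit$m, fit$s, w1, rule, edges_t = edges)
  u_tilde <- full$u

  llr_se <- rep(NA_real_, nrow(dst))
  if (se && !is.null(fit$cov_u)) {
    # Delta-method variance of u_tilde, in two parts.
    # (1) Distribution parameters: u_tilde = Cw^{-1}(q; m, s) at fixed
    #     pooled cumulative fraction q, so perturb (m, log s) with the
    #     boundaries re-anchored to their quantile positions and contract
    #     with the (m, log s) block of the MLE covariance.
    # (2) Quantile anchoring: q is the score's empirical pooled cumulative
    #     fraction, a binomial proportion with variance q(1-q)/N, entering
    #     u_tilde through the inverse pooled CDF with slope 1/f_pooled(u).
    # The Wald variances of individual boundary parameters are not used:
    # for run binning of continuous scores most bins hold a single subject,
    # their quadratic approximation is poor, and contracting them directly
    # overstates the CI severalfold (checked against Monte Carlo).
    grads <- matrix(0, nrow(dst), 2L)
    h_m <- 1e-4 * max(1, abs(fit$m))
    grads[, 1L] <- (utilde_all(fit$m + h_m, fit$s, edges) -
                      utilde_all(fit$m - h_m, fit$s, edges)) / (2 * h_m)
    h_s <- 1e-4 * max(1, abs(log(fit$s)))
    grads[, 2L] <- (utilde_all(fit$m, exp(log(fit$s) + h_s), edges) -
                      utilde_all(fit$m, exp(log(fit$s) - h_s), edges)) / (2 * h_s)
    Sms <- fit$cov_u[1:2, 1:2]
    v_par <- rowSums((grads %*% Sms) * grads)
    ntot <- binning$n0 + binning$n1
    C_edges <- pooled_cdf(edges, fit$m, fit$s, w1)
    K <- ave(counts, dst$bin, FUN = sum)
    cumk <- ave(counts, dst$bin, FUN = cumsum)
    span <- C_edges[dst$bin + 1L] - C_edges[dst$bin]
    q <- C_edges[dst$bin] + ((cumk - counts / 2) / K) * span
    f_pool <- (1 - w1) * u_density(u_tilde, fit$m, fit$s, 0) +
      w1 * u_density(u_tilde, fit$m, fit$s, 1)
    v_q <- q * (1 - q) / ntot / pmax(f_pool, 1e-12)^2
    llr_se <- sqrt(pmax(v_par + v_q, 0))
  }

  tibble::tibble(
    score = dst$score,
    u_lo = full$lo,
    u_hi = full$hi,
    u_tilde = u_tilde,
    llr = u_tilde,
    llr_se = llr_se,
    prob = plogis(u_tilde + qlogis(eta))
  )
}

#' Fit the semi-parametric (latent proper-binormal) calibration function
#'
#' Chains [run_binning()], [fit_proper_binormal()] and
#' [map_scores_to_latent()] into the common calibrator interface: scores
#' are reduced to truth-state-run bins, the latent log-likelihood-ratio
#' model is fitted by multinomial maximum likelihood, each distinct
#' training score receives a latent LLR value with a delta-method standard
#' error, and Bayes' theorem converts LLR to the probability of disease at
#' the assumed prevalence. The 95% interval is Wald on the LLR scale
#' (\eqn{\tilde u \pm 1.96\,se}) transformed through the posterior formula,
#' which keeps it inside (0, 1) without clipping.
#'
#' @param data A data frame with columns `score` and `truth`; both classes
#'   must be present.
#' @param eta Assumed prevalence of disease; defaults to the sample
#'   prevalence `N1/N`.
#' @param rule Complementary-value rule passed to
#'   [map_scores_to_latent()].
#' @param se,se_limit,tol,max_iter,engine,joint_limit Passed to
#'   [fit_proper_binormal()].
#' @return An object of class `c("cal_semiparametric", "probcal_fit")` with
#'   the latent `fit`, the per-score `latent` map, `eta`, the training
#'   `data`, and the calibration `curve`.
#' @examples
#' d <- sample_scores(normal_model(), 100, 100, seed = 1)
#' fit <- cal_semiparametric(d)
#' glance(fit)
#' @export
cal_semiparametric <- function(data, eta = NULL,
                               rule = c("mixture", "midpoint"),
                               se = NULL, se_limit = 1500L,
                               tol = 1e-9, max_iter = 1000L,
                               engine = c("auto", "joint", "profile"),
                               joint_limit = 2000L) {
  data <- validate_scores(data, require_both_classes = TRUE)
  rule <- match.arg(rule)
  cnt <- score_counts(data)
  if (is.null(eta)) eta <- cnt$n1 / cnt$n
  check_eta(eta)
  binning <- run_binning(data)
  fit <- fit_proper_binormal(binning, tol = tol, se = se,
                             se_limit = se_limit, max_iter = max_iter,
                             engine = engine, joint_limit = joint_limit)
  want_se <- !is.null(fit$cov_u)
  latent <- map_scores_to_latent(fit, eta = eta, rule = rule, se = want_se)
  lo_llr <- latent$llr - 1.96 * latent$llr_se
  hi_llr <- latent$llr + 1.96 * latent$llr_se
  curve <- tibble::tibble(
    score = latent$score,
    prob = latent$prob,
    lo95 = plogis(lo_llr + qlogis(eta)),
    hi95 = plogis(hi_llr + qlogis(eta))
  )
  structure(
    list(method = "semiparametric", fit = fit, latent = latent,
         eta = eta, data = data, curve = curve,
         converged = fit$converged),
    class = c("cal_semiparametric", "probcal_fit")
  )
}
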