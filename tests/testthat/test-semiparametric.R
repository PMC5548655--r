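test_that("truth-state runs form the documented bins", {
  d <- tibble::tibble(score = 1:10, truth = c(0L,1L,0L,0L,1L,1L,0L,1L,1L,1L))
  bn <- run_binning(d)
  expect_equal(nrow(bn$bins), 6L)
  expect_equal(bn$bins$count0, c(1, 0, 2, 0, 1, 0))
  expect_equal(bn$bins$count1, c(0, 1, 0, 2, 0, 3))
  expect_equal(sum(bn$bins$count0), bn$n0)
  expect_equal(sum(bn$bins$count1), bn$n1)

  # alternating truths: singleton bins
  da <- tibble::tibble(score = 1:4, truth = c(0L, 1L, 0L, 1L))
  expect_equal(nrow(run_binning(da)$bins), 4L)

  # a mixed tie forms its own bin and terminates runs
  dt <- tibble::tibble(score = c(1, 2, 2, 3), truth = c(0L, 0L, 1L, 0L))
  bt <- run_binning(dt)
  expect_equal(nrow(bt$bins), 3L)
  expect_equal(bt$bins$count0, c(1, 1, 1))
  expect_equal(bt$bins$count1, c(0, 1, 0))

  expect_error(run_binning(tibble::tibble(score = 1:3, truth = c(0L, 0L, 0L))),
               "one class")
})

test_that("latent bin probabilities match closed forms and a sampling oracle", {
  # equal variance: u = 1.2 z - 0.72 is linear, P0(u <= 0) = Phi(0.6)
  expect_equal(latent_bin_probs(1.2, 1, -Inf, 0, 0), pnorm(0.6))
  # total mass for assorted shapes
  for (par in list(c(1.2, 1), c(0.8, 1.7), c(1.5, 0.6))) {
    expect_equal(latent_bin_probs(par[1], par[2], -Inf, Inf, 0), 1)
    expect_equal(latent_bin_probs(par[1], par[2], -Inf, Inf, 1), 1)
  }
  # s > 1: a level below the minimum of u carries no mass
  expect_equal(latent_bin_probs(1, 2, -Inf, -2, 0), 0)
  # Monte-Carlo oracle: simulate the latent variable and bin its log-LR
  m <- 1.2; s <- 1.5
  u_of <- function(z) z^2 / 2 - (z - m)^2 / (2 * s^2) - log(s)
  mc <- withr::with_seed(77, {
    u0 <- u_of(rnorm(1e6))
    u1 <- u_of(rnorm(1e6, m, s))
    c(mean(u0 > -0.5 & u0 <= 0.7), mean(u1 > -0.5 & u1 <= 0.7))
  })
  expect_lt(abs(latent_bin_probs(m, s, -0.5, 0.7, 0) - mc[1]), 0.002)
  expect_lt(abs(latent_bin_probs(m, s, -0.5, 0.7, 1) - mc[2]), 0.002)
  # the equal-variance branch joins the quadratic branch continuously
  expect_equal(latent_bin_probs(1.2, 1 + 1e-9, -Inf, 0.3, 1),
               latent_bin_probs(1.2, 1 + 1e-6, -Inf, 0.3, 1), tolerance = 1e-4)
  expect_error(latent_bin_probs(1, -1, 0, 1, 0), "s")
  expect_error(latent_bin_probs(1, 1, 1, 0, 0), "t_lo")
})

test_that("log-LR densities satisfy the LR-of-LR identity and a proper ROC", {
  m <- 1.2; s <- 1.3
  # grid above the minimum of u (about -1.31 here), where densities exist
  tt <- seq(-1.2, 2, length.out = 40)
  lr <- probcal:::u_density(tt, m, s, 1) / probcal:::u_density(tt, m, s, 0)
  expect_equal(lr, exp(tt), tolerance = 1e-8)
  # implied ROC is convex: TPF as a function of FPF has non-increasing slope
  thr <- seq(-3, 5, length.out = 1000)
  fpf <- 1 - probcal:::p_u_le(thr, m, s, 0)
  tpf <- 1 - probcal:::p_u_le(thr, m, s, 1)
  ord <- order(fpf)
  slopes <- diff(tpf[ord]) / diff(fpf[ord])
  keep <- is.finite(slopes)
  expect_true(all(diff(slopes[keep]) <= 1e-6))
})

test_that("the smallest well-posed fit matches a brute-force grid search", {
  d <- tibble::tibble(score = 1:6, truth = c(0L, 0L, 0L, 1L, 1L, 1L))
  bn <- run_binning(d)
  expect_equal(nrow(bn$bins), 2L)
  fit <- fit_proper_binormal(bn)
  expect_length(fit$boundaries, 1L)
  # brute force over (m, log s, t1)
  best <- -Inf
  t1_grid <- seq(-3, 3, by = 0.05)
  for (m in seq(0.1, 3, by = 0.05)) {
    for (ls in seq(-0.7, 0.7, by = 0.05)) {
      s <- exp(ls)
      p0 <- probcal:::p_u_le(t1_grid, m, s, 0)
      p1 <- probcal:::p_u_le(t1_grid, m, s, 1)
      ll <- 3 * log(pmax(p0, 1e-300)) + 3 * log(pmax(1 - p1, 1e-300))
      best <- max(best, max(ll))
    }
  }
  expect_gte(fit$loglik, best - 1e-6)

  # refitting identical inputs reproduces the fit exactly
  fit2 <- fit_proper_binormal(bn)
  expect_identical(fit$m, fit2$m)
  expect_identical(fit$boundaries, fit2$boundaries)

  expect_error(
    fit_proper_binormal(run_binning(
      tibble::tibble(score = c(1, 1), truth = c(0L, 1L)))),
    "2 truth-state-run bins")
})

test_that("the latent map is monotone, mass-conserving, and Bayes-consistent", {
  d <- sample_scores(normal_model(), 80, 80, seed = 2)
  f <- cal_semiparametric(d, eta = 0.5)
  lat <- f$latent
  expect_false(is.unsorted(lat$u_tilde))
  expect_true(all(lat$u_lo <= lat$u_tilde + 1e-9))
  expect_true(all(lat$u_tilde <= lat$u_hi + 1e-9))
  expect_equal(lat$llr, lat$u_tilde)
  # posterior via Bayes at eta = 0.5
  expect_equal(lat$prob, plogis(lat$llr), tolerance = 1e-12)
  # sub-interval pooled mass equals the empirical share of the bin
  bn <- f$fit$binning
  pm <- probcal:::pooled_cdf(lat$u_hi, f$fit$m, f$fit$s, 0.5) -
    probcal:::pooled_cdf(lat$u_lo, f$fit$m, f$fit$s, 0.5)
  cnt <- bn$distinct$c0 + bn$distinct$c1
  binmass <- tapply(pm, bn$distinct$bin, sum)[bn$distinct$bin]
  bintot <- tapply(cnt, bn$distinct$bin, sum)[bn$distinct$bin]
  expect_equal(pm / binmass, cnt / bintot, tolerance = 1e-9)
  # a bin with one distinct score has the bin interval as its sub-interval
  one <- which(bintot == cnt)
  edges <- c(-Inf, f$fit$boundaries, Inf)
  expect_equal(lat$u_lo[one], edges[bn$distinct$bin[one]])
  expect_equal(lat$u_hi[one], edges[bn$distinct$bin[one] + 1L])
})

test_that("posterior transform respects prevalence", {
  d <- sample_scores(normal_model(), 60, 60, seed = 8)
  f5 <- cal_semiparametric(d, eta = 0.5)
  # LLR = 0 maps to prob = eta for any eta; monotone in eta at fixed LLR
  etas <- c(0.1, 0.3, 0.5, 0.8)
  at06 <- vapply(etas, function(e) {
    predict(cal_semiparametric(d, eta = e), 0.6)$prob
  }, numeric(1))
  expect_false(is.unsorted(at06))
  expect_true(all(at06 > 0 & at06 < 1))
  # curve contract
  cv <- tidy(f5)
  expect_true(all(cv$lo95 <= cv$prob & cv$prob <= cv$hi95))
  expect_false(is.unsorted(cv$prob))
  expect_true(all(cv$lo95 > 0 & cv$hi95 < 1))  # LLR-scale Wald stays inside
})

test_that("midpoint rule is a documented alternative to the mixture median", {
  d <- sample_scores(normal_model(), 50, 50, seed = 12)
  fm <- cal_semiparametric(d, rule = "mixture")
  fp <- cal_semiparametric(d, rule = "midpoint")
  expect_false(is.unsorted(fp$latent$u_tilde))
  # interior scores differ between the two rules in general
  interior <- which(is.finite(fp$latent$u_lo) & is.finite(fp$latent$u_hi))
  expect_gt(max(abs(fp$latent$u_tilde[interior] - fm$latent$u_tilde[interior])), 0)
})

test_that("profile and joint engines agree on moderate data", {
  d <- sample_scores(normal_model(), 300, 300, seed = 2)
  bn <- run_binning(d)
  fj <- fit_proper_binormal(bn, engine = "joint")
  fp <- fit_proper_binormal(bn, engine = "profile")
  expect_lt(abs(fj$m - fp$m), 0.1)
  expect_lt(abs(fj$s - fp$s), 0.1)
})

test_that("moderate-sample fit recovers the generating latent parameters", {
  d <- sample_scores(normal_model(), 500, 500, seed = 31)
  f <- cal_semiparametric(d, eta = 0.5)
  expect_true(f$fit$converged)
  expect_lt(abs(f$fit$m - 1.2), 0.2)
  expect_lt(abs(f$fit$s - 1), 0.2)
  expect_lt(abs(predict(f, 0.6)$prob - 0.5), 0.1)
})
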