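test_that("sample_scores is seeded, labeled, and matches its model", {
  m <- normal_model()
  d1 <- sample_scores(m, 300, 300, seed = 42)
  d2 <- sample_scores(m, 300, 300, seed = 42)
  expect_identical(d1, d2)
  expect_identical(table(d1$truth), table(factor(rep(0:1, each = 300))))

  d <- sample_scores(m, 0, 5, seed = 1)
  expect_identical(d$truth, rep(1L, 5))

  # empirical class moments at large n (3 SE tolerance)
  big <- sample_scores(m, 1e5, 1e5, seed = 7)
  y1 <- big$score[big$truth == 1]
  y0 <- big$score[big$truth == 0]
  expect_lt(abs(mean(y0) - 0), 3 / sqrt(1e5))
  expect_lt(abs(mean(y1) - 1.2), 3 / sqrt(1e5))
  expect_lt(abs(stats::sd(y1) - 1), 3 / sqrt(2e5))

  bb <- sample_scores(beta_model(), 5e4, 5e4, seed = 8)
  expect_true(all(bb$score >= 0 & bb$score <= 1))
  # E[y|0] = 1/(1+beta) = 2/9; E[y|1] = alpha/(alpha+1) = 11/21
  expect_lt(abs(mean(bb$score[bb$truth == 0]) - 2 / 9), 0.005)
  expect_lt(abs(mean(bb$score[bb$truth == 1]) - 11 / 21), 0.005)

  # sample AUC of the binormal model is near its closed form
  d <- sample_scores(m, 300, 300, seed = 5)
  auc_hat <- mean(outer(d$score[d$truth == 1], d$score[d$truth == 0], ">"))
  expect_lt(abs(auc_hat - model_auc(m)), 3 * 0.025)
})

test_that("true_posterior implements Bayes' rule on both models", {
  m <- normal_model()
  expect_equal(true_posterior(m, 0.6), 0.5)      # LLR = 1.2*0.6 - 0.72 = 0
  expect_equal(true_posterior(m, 0.6, eta = 0.2), 0.2)
  b <- beta_model()
  expect_equal(true_posterior(b, 1), 1)          # f(1|0) = 0
  expect_equal(true_posterior(b, 0), 0)          # f(0|1) = 0
  expect_error(true_posterior(b, 1.5), "support")
  # monotone (rationality) on a grid, both models
  gy <- seq(-4, 6, length.out = 200)
  expect_false(is.unsorted(true_posterior(m, gy)))
  gb <- seq(0, 1, length.out = 200)
  expect_false(is.unsorted(true_posterior(b, gb)))
})

test_that("model_auc matches closed forms and a concordance oracle", {
  expect_equal(model_auc(normal_model()), pnorm(1.2 / sqrt(2)))
  expect_equal(round(model_auc(normal_model()), 2), 0.80)
  expect_equal(model_auc(normal_model(mu1 = 0)), 0.5)
  expect_equal(round(model_auc(beta_model()), 2), 0.80)
  # Monte-Carlo concordance oracle for the beta pair
  auc_mc <- withr::with_seed(31, {
    y1 <- rbeta(4e5, 1.1, 1)
    y0 <- rbeta(4e5, 1, 3.5)
    mean(y1 > y0)
  })
  expect_lt(abs(model_auc(beta_model()) - auc_mc), 0.003)
})

test_that("linear Gaussian world reduces to the binormal score model", {
  w1 <- gaussian_world(mu0 = 0, mu1 = 1.2, V = 1, w = 1)
  expect_equal(linear_classifier_auc(w1), model_auc(normal_model()))
  expect_equal(linear_classifier_auc(gaussian_world(0, 0, 1, 1)), 0.5)
  # w orthogonal to the mean difference under V = I
  w2 <- gaussian_world(mu0 = c(0, 0), mu1 = c(1, 0), V = diag(2), w = c(0, 1))
  expect_equal(linear_classifier_auc(w2), 0.5)
  expect_error(linear_classifier_auc(gaussian_world(0, 1, 1, 1e-300) |>
                                       (\(x) {x$w <- 0; x})()), "nonzero")
  expect_error(gaussian_world(0, 1, -1, 1), "positive definite")
})

test_that("perfect calibration parameters reproduce the true posterior", {
  w1 <- gaussian_world(mu0 = 0, mu1 = 1.2, V = 1, w = 1, eta = 0.5)
  ab <- perfect_calibration_params(w1)
  expect_equal(ab$A, -1.2)
  expect_equal(ab$B, 0.72)
  # symmetric means at eta = 0.5 give B = 0
  ws <- gaussian_world(mu0 = -0.7, mu1 = 0.7, V = 1, w = 1, eta = 0.5)
  expect_equal(perfect_calibration_params(ws)$B, 0)
  # sigmoid with (A, B) equals Bayes posterior of the induced score model
  wm <- gaussian_world(mu0 = c(-1, 0.5), mu1 = c(0.3, 1), V = diag(c(2, 1)),
                       w = c(0.8, -0.4), eta = 0.35)
  ab <- perfect_calibration_params(wm)
  mu0y <- sum(wm$w * wm$mu0)
  mu1y <- sum(wm$w * wm$mu1)
  sdy <- sqrt(drop(t(wm$w) %*% wm$V %*% wm$w))
  induced <- normal_model(mu0 = mu0y, mu1 = mu1y, sigma = sdy, eta = 0.35)
  ys <- withr::with_seed(9, rnorm(100, mean(c(mu0y, mu1y)), 2 * sdy))
  expect_equal(plogis(-(ab$A * ys + ab$B)), true_posterior(induced, ys),
               tolerance = 1e-10)
})

test_that("rationality holds for the study models and fails when variances differ", {
  gy <- seq(-5, 7, length.out = 500)
  expect_true(rationality_check(normal_model(), gy)$pass)
  expect_true(rationality_check(beta_model(), seq(0.001, 0.999, length.out = 500))$pass)
  bad <- rationality_check(normal_model(sigma = 1, sigma1 = 2), gy)
  expect_false(bad$pass)
  expect_true(bad$violation$lr1 > bad$violation$lr2)
})

test_that("uniformly distributed calibrated scores cap the AUC at 5/6", {
  expect_identical(diamond_uniform_auc(), 5 / 6)
  expect_equal(round(diamond_uniform_auc(), 2), 0.83)
  # concordance oracle: f1(p) = 2p, f0(p) = 2(1-p) via inverse-CDF sampling
  auc_mc <- withr::with_seed(13, {
    p1 <- sqrt(runif(1e6))
    p0 <- 1 - sqrt(runif(1e6))
    mean(p1 > p0) + 0.5 * mean(p1 == p0)
  })
  expect_lt(abs(auc_mc - 5 / 6), 0.002)
})

test_that("score model constructors validate their parameters", {
  expect_error(normal_model(sigma = 0), "sigma")
  expect_error(beta_model(alpha = 0.5), "alpha")
  expect_error(normal_model(eta = 1), "prevalence")
  expect_error(sample_scores(normal_model(), 0, 0, seed = 1), "at least one")
  expect_error(sample_scores(normal_model(), 5, 5, seed = NULL), "seed")
})
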