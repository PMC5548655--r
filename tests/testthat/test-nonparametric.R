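test_that("PAVA reproduces the worked ten-subject example exactly", {
  fit <- fit_pava(table1_scores())
  expect_equal(fit$data$fitted, table1_solution, tolerance = 1e-12)
  expect_equal(fit$curve$prob, table1_solution, tolerance = 1e-12)
  expect_equal(fit$blocks$value, c(0, 1/3, 2/3, 1), tolerance = 1e-12)
  # block values strictly increasing, block means equal truth means
  expect_true(all(diff(fit$blocks$value) > 0))
  d <- fit$data
  for (i in seq_len(nrow(fit$blocks))) {
    idx <- fit$blocks$start[i]:fit$blocks$end[i]
    expect_equal(fit$blocks$value[i], mean(d$truth[idx]))
  }
})

test_that("PAVA handles degenerate and already-isotonic inputs", {
  iso <- tibble::tibble(score = 1:4, truth = c(0L, 0L, 1L, 1L))
  expect_equal(fit_pava(iso)$data$fitted, c(0, 0, 1, 1))
  ones <- tibble::tibble(score = 1:5, truth = rep(1L, 5))
  expect_equal(fit_pava(ones)$data$fitted, rep(1, 5))
  single <- tibble::tibble(score = 3, truth = 0L)
  expect_equal(fit_pava(single)$data$fitted, 0)
  # mixed tie pre-averaged into one weighted point
  tie <- tibble::tibble(score = c(1, 2, 2, 3), truth = c(0L, 0L, 1L, 1L))
  f <- fit_pava(tie)
  expect_equal(f$curve$prob, c(0, 0.5, 1))
  expect_equal(f$data$fitted, c(0, 0.5, 0.5, 1))
})

test_that("fit_pava equals the brute-force oracle and isoreg on random sets", {
  for (seed in 1:25) {
    n <- withr::with_seed(seed, sample(2:10, 1))
    d <- random_scoreset(n, seed + 500)
    a <- fit_pava(d)
    b <- pava_oracle(d)
    expect_equal(a$data$fitted, b$data$fitted, tolerance = 1e-12)
    # independent cross-check on tie-free data: stats::isoreg
    if (!anyDuplicated(d$score)) {
      ord <- order(d$score)
      expect_equal(a$data$fitted, stats::isoreg(d$score[ord], d$truth[ord])$yf,
                   tolerance = 1e-12)
    }
  }
  expect_error(pava_oracle(random_scoreset(13, 1)), "N <= 12")
})

test_that("PAVA preserves the disease fraction and has monotone block odds", {
  for (seed in c(2, 9, 40)) {
    d <- sample_scores(normal_model(), 40, 60, seed = seed)
    fit <- fit_pava(d)
    expect_equal(mean(fit$data$fitted), 60 / 100, tolerance = 1e-12)
    # ROC convex hull: block likelihood ratios (odds of the block values)
    # must increase strictly across blocks
    v <- fit$blocks$value
    odds <- v / (1 - v)
    expect_true(all(diff(odds) > 0))
  }
})

test_that("balanced bootstrap is balanced, seeded, and yields a sane band", {
  d <- sample_scores(normal_model(), 25, 25, seed = 4)
  bb <- bootstrap_band(d, B = 40, seed = 11)
  expect_identical(dim(bb$replicates), c(40L, length(unique(d$score))))
  # balance: reconstruct the permutation and count each subject
  idx <- withr::with_seed(11, sample(rep.int(seq_len(50), 40)))
  expect_true(all(tabulate(idx, 50) == 40))
  expect_true(all(bb$band$lo95 <= bb$band$hi95))
  expect_true(all(bb$band$lo95 >= 0 & bb$band$hi95 <= 1))
  # determinism
  bb2 <- bootstrap_band(d, B = 40, seed = 11)
  expect_identical(bb$band, bb2$band)
  expect_error(bootstrap_band(d, B = 40), "seed")
  expect_error(bootstrap_band(d, B = 1, seed = 1), "at least 2")
})

test_that("degenerate single-class data gives a degenerate band", {
  d <- tibble::tibble(score = 1:6, truth = rep(0L, 6))
  fit <- fit_pava(d)
  expect_equal(fit$data$fitted, rep(0, 6))
  # bootstrap requires both classes by contract
  expect_error(bootstrap_band(d, B = 10, seed = 1), "one class")
})

test_that("the nonparametric calibrator exposes the common interface", {
  d <- sample_scores(normal_model(), 40, 40, seed = 6)
  fit <- cal_nonparametric(d, B = 200, seed = 9)
  curve <- tidy(fit)
  expect_true(all(curve$lo95 <= curve$prob & curve$prob <= curve$hi95))
  expect_false(is.unsorted(curve$prob))
  g <- glance(fit)
  expect_equal(g$method, "nonparametric")
  expect_equal(g$brier_resub, fit$objective / nrow(d), tolerance = 1e-12)
  # percentile band from the raw bootstrap contains the point estimate
  # for nearly all scores
  bb <- bootstrap_band(d, B = 200, seed = 9)
  base <- fit_pava(d)$curve$prob
  covered <- mean(bb$band$lo95 <= base & base <= bb$band$hi95)
  expect_gte(covered, 0.9)
})
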