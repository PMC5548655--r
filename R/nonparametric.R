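# Weighted pool-adjacent-violators on points already sorted by score.
# v: point values (here: truth-state means within tied scores), w: weights.
# Returns the isotonic least-squares fit per point. Blocks are merged while
# the previous block's value is >= the current one, so final block values
# are strictly increasing and each equals the weighted mean of its members.
pava_weighted <- function(v, w) {
  n <- length(v)
  val <- numeric(n)
  wt <- numeric(n)
  sz <- integer(n)
  nb <- 0L
  for (i in seq_len(n)) {
    nb <- nb + 1L
    val[nb] <- v[i]; wt[nb] <- w[i]; sz[nb] <- 1L
    while (nb > 1L && val[nb - 1L] >= val[nb]) {
      val[nb - 1L] <- (wt[nb - 1L] * val[nb - 1L] + wt[nb] * val[nb]) /
        (wt[nb - 1L] + wt[nb])
      wt[nb - 1L] <- wt[nb - 1L] + wt[nb]
      sz[nb - 1L] <- sz[nb - 1L] + sz[nb]
      nb <- nb - 1L
    }
  }
  list(fitted = rep(val[seq_len(nb)], sz[seq_len(nb)]),
       block_value = val[seq_len(nb)],
       block_size = sz[seq_len(nb)])
}

# Collapse tied scores to weighted points: the isotonic function cannot
# separate equal scores, so ties are pre-averaged (value = truth mean,
# weight = tie count) before pooling.
distinct_points <- function(data) {
  ord <- order(data$score)
  s <- data$score[ord]
  d <- data$truth[ord]
  grp <- cumsum(c(TRUE, diff(s) > 0))
  tibble::tibble(
    score = s[!duplicated(grp)],
    value = as.vector(rowsum(as.numeric(d), grp)) / tabulate(grp),
    weight = tabulate(grp)
  )
}

#' Isotonic regression of truth states on scores (PAVA)
#'
#' Computes the least-squares isotonic fit
#' \eqn{g = \arg\min_z \sum_i (D_i - z(y_i))^2} subject to \eqn{z}
#' non-decreasing in the score, by the pool-adjacent-violators algorithm:
#' subjects are sorted by score, each starts in its own group at its truth
#' state, and adjacent groups whose values violate the ordering are pooled
#' (replaced by their mean) until none do. The solution is unique, and each
#' block value equals the fraction of diseased subjects in the block, so the
#' fitted values are direct non-parametric probability-of-disease estimates.
#' Tied scores are pre-merged into a single weighted point.
#'
#' @param data A data frame with columns `score` and `truth`. A single
#'   class is legal (the fit is constant).
#' @return A list with `data` (subjects sorted by score, with `fitted`),
#'   `blocks` (tibble: `start`, `end` subject indices in sort order,
#'   `value`), and `curve` (tibble: distinct `score`, fitted `prob`).
#' @examples
#' d <- data.frame(score = c(2, 12, 18, 20, 27, 30, 42, 50, 55, 78),
#'                 truth = c(0, 1, 0, 0, 1, 1, 0, 1, 1, 1))
#' fit_pava(d)$curve
#' @export
fit_pava <- function(data) {
  data <- validate_scores(data)
  pts <- distinct_points(data)
  res <- pava_weighted(pts$value, pts$weight)
  ord <- order(data$score)
  sorted <- data[ord, ]
  # fitted value per distinct point, expanded to subjects
  sorted$fitted <- rep(res$fitted, pts$weight)
  # block extents in subject (sorted) indexing
  pts_per_block <- res$block_size
  subj_per_block <- as.vector(
    rowsum(pts$weight, rep(seq_along(pts_per_block), pts_per_block)))
  ends <- cumsum(subj_per_block)
  list(
    data = tibble::as_tibble(sorted),
    blocks = tibble::tibble(start = c(1L, head(ends, -1L) + 1L),
                            end = ends,
                            value = res$block_value),
    curve = tibble::tibble(score = pts$score, prob = res$fitted)
  )
}

#' Brute-force oracle for isotonic regression
#'
#' Enumerates every ordered partition of the distinct score points into
#' contiguous blocks, assigns each block its weighted truth mean, keeps only
#' partitions whose block means are non-decreasing, and returns the feasible
#' partition with minimal squared error. Exponential in the number of
#' points, hence restricted to small inputs; used to cross-check
#' [fit_pava()] in tests.
#'
#' @inheritParams fit_pava
#' @return Same shape as [fit_pava()] (without `blocks` detail beyond the
#'   optimum).
#' @export
pava_oracle <- function(data) {
  data <- validate_scores(data)
  if (nrow(data) > 12L) abort("pava_oracle is restricted to N <= 12.")
  pts <- distinct_points(data)
  m <- nrow(pts)
  best_sse <- Inf
  best_fit <- NULL
  for (mask in 0:(2^(max(m - 1L, 0L)) - 1L)) {
    # bit k set => cut between point k and k+1
    cuts <- which(bitwAnd(mask, bitwShiftL(1L, 0:(m - 2L))) != 0L)
    bounds <- c(0L, cuts, m)
    means <- numeric(length(bounds) - 1L)
    sse <- 0
    for (b in seq_along(means)) {
      i <- (bounds[b] + 1L):bounds[b + 1L]
      means[b] <- sum(pts$value[i] * pts$weight[i]) / sum(pts$weight[i])
      sse <- sse + sum(pts$weight[i] * (pts$value[i] - means[b])^2)
    }
    if (is.unsorted(means)) next
    if (sse < best_sse - 1e-12) {
      best_sse <- sse
      best_fit <- rep(means, diff(bounds))
    }
  }
  ord <- order(data$score)
  sorted <- data[ord, ]
  sorted$fitted <- rep(best_fit, pts$weight)
  list(data = tibble::as_tibble(sorted),
       curve = tibble::tibble(score = pts$score, prob = best_fit),
       sse = best_sse)
}

#' Balanced-bootstrap percentile band for the isotonic fit
#'
#' Builds `B` resamples of size N by concatenating `B` copies of the
#' subject indices, applying one seeded uniform permutation, and slicing
#' into `B` consecutive blocks, so that every subject appears exactly `B`
#' times across all resamples (a balanced bootstrap). Each resample is
#' refitted with [fit_pava()] and its step function is evaluated at every
#' original distinct score by the shared interpolate-and-clamp rule; the
#' pointwise 2.5th and 97.5th percentiles of the `B` replicate values form
#' the 95% band.
#'
#' @inheritParams fit_pava
#' @param B Number of bootstrap replicates (at least 2).
#' @param seed Integer seed for the single balancing permutation; required.
#' @return A list with `band` (tibble: `score`, `lo95`, `hi95` over distinct
#'   original scores), `B`, `seed`, and the `replicates` matrix
#'   (B rows x distinct scores) for diagnostics.
#' @export
bootstrap_band <- function(data, B = 2000L, seed = NULL) {
  data <- validate_scores(data, require_both_classes = TRUE)
  if (!is.numeric(B) || B < 2) abort("`B` must be at least 2.")
  if (is.null(seed)) abort("`seed` is required for the bootstrap (reproducibility).")
  B <- as.integer(B)
  n <- nrow(data)
  sgrid <- sort(unique(data$score))
  idx <- with_seed(seed, sample(rep.int(seq_len(n), B)))
  dim(idx) <- c(n, B)
  reps <- matrix(NA_real_, nrow = B, ncol = length(sgrid))
  for (b in seq_len(B)) {
    i <- idx[, b]
    fit <- fit_pava(tibble::tibble(score = data$score[i], truth = data$truth[i]))
    cv <- fit$curve
    if (nrow(cv) == 1L) {
      reps[b, ] <- cv$prob
    } else {
      reps[b, ] <- approx(cv$score, cv$prob, xout = sgrid, rule = 2)$y
    }
  }
  qs <- apply(reps, 2L, quantile, probs = c(0.025, 0.975), names = FALSE)
  list(
    band = tibble::tibble(score = sgrid, lo95 = qs[1L, ], hi95 = qs[2L, ]),
    B = B, seed = seed, replicates = reps
  )
}

#' Fit the non-parametric (isotonic) calibration function
#'
#' Combines [fit_pava()] with the balanced-bootstrap percentile band of
#' [bootstrap_band()] into the common calibrator interface. The fitted step
#' function is defined on the distinct training scores; prediction at new
#' scores interpolates linearly between them and clamps outside the
#' training range (see [apply_curve()]).
#'
#' @inheritParams bootstrap_band
#' @param B Bootstrap replicates for the 95% band; `B = 0` skips the
#'   bootstrap (bounds collapse to the point estimate).
#' @return An object of class `c("cal_nonparametric", "probcal_fit")` with
#'   the training `data`, pooled `blocks`, and `curve` (distinct scores with
#'   `prob`, `lo95`, `hi95`).
#' @examples
#' d <- sample_scores(normal_model(), 50, 50, seed = 1)
#' fit <- cal_nonparametric(d, B = 100, seed = 2)
#' head(tidy(fit))
#' @export
cal_nonparametric <- function(data, B = 2000L, seed = NULL) {
  data <- validate_scores(data, require_both_classes = TRUE)
  base <- fit_pava(data)
  curve <- base$curve
  if (B > 0) {
    bb <- bootstrap_band(data, B = B, seed = seed)
    curve$lo95 <- pmin(bb$band$lo95, curve$prob)
    curve$hi95 <- pmax(bb$band$hi95, curve$prob)
    band_meta <- list(B = bb$B, seed = bb$seed)
  } else {
    curve$lo95 <- curve$prob
    curve$hi95 <- curve$prob
    band_meta <- list(B = 0L, seed = NULL)
  }
  structure(
    list(method = "nonparametric",
         data = base$data, blocks = base$blocks,
         curve = curve[, c("score", "prob", "lo95", "hi95")],
         bootstrap = band_meta,
         objective = sum((base$data$fitted - base$data$truth)^2)),
    class = c("cal_nonparametric", "probcal_fit")
  )
}
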