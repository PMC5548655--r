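# Worked PAVA example: ten subjects sorted by score, with the known
# isotonic solution (0, 1/3, 1/3, 1/3, 2/3, 2/3, 2/3, 1, 1, 1).
table1_scores <- function() {
  tibble::tibble(
    score = c(2, 12, 18, 20, 27, 30, 42, 50, 55, 78),
    truth = c(0L, 1L, 0L, 0L, 1L, 1L, 0L, 1L, 1L, 1L)
  )
}

table1_solution <- c(0, 1/3, 1/3, 1/3, 2/3, 2/3, 2/3, 1, 1, 1)

# Random small score set with occasional ties, for property-based tests.
random_scoreset <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(
      score = sample(1:(2 * n), n, replace = TRUE) + 0,
      truth = sample(0:1, n, replace = TRUE)
    )
  })
}
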