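test_that("passage sampling is seed-deterministic", {
  lm <- demo_toy_lm()
  c1 <- sample_passages(lm, 3, 25, seed = 11)
  c2 <- sample_passages(lm, 3, 25, seed = 11)
  expect_identical(c1$word, c2$word)
  expect_identical(c1$word_id, c2$word_id)
  c3 <- sample_passages(lm, 3, 25, seed = 12)
  expect_false(identical(c1$word, c3$word))
})

test_that("a degenerate model generates a deterministic cycle", {
  dlm <- degenerate_lm()
  corpus <- sample_passages(dlm, 1, 12, seed = 4)
  w <- corpus$word
  # after the first word the continuation is fully determined
  expect_true(all(w[-1] == ifelse(w[-length(w)] == "the", "end", "the")))
})

test_that("sentence numbering resets at sentence boundaries", {
  lm <- demo_toy_lm()
  corpus <- sample_passages(lm, 2, 30, seed = 8)
  wns <- corpus$word_number_in_sentence
  # every passage starts a sentence; each step either increments or resets
  for (tid in unique(corpus$text_id)) {
    x <- wns[corpus$text_id == tid]
    expect_equal(x[1], 1L)
    expect_true(all(diff(x) == 1L | x[-1] == 1L))
  }
})

test_that("with all coefficients zero and no variance, skipping is a fair coin", {
  lm <- demo_toy_lm()
  corpus <- sample_passages(lm, 2, 40, seed = 31)
  metrics <- corpus_metrics(lm, corpus)
  zero <- lapply(default_gaze_beta_names <- c("skip", "first_fixation",
                                              "gaze", "total_time",
                                              "regression"),
                 function(nm) c(intercept = 0, entropy = 0, surprisal = 0,
                                entropy_surprisal = 0, frequency = 0,
                                length = 0, word_number = 0, similarity = 0))
  names(zero) <- default_gaze_beta_names
  zero[c("first_fixation", "gaze", "total_time")] <-
    lapply(zero[c("first_fixation", "gaze", "total_time")], function(b) {
      b["intercept"] <- 5.5; b
    })
  cfg <- gaze_sim_config(n_participants = 200, beta = zero,
                         sd_participant = 0, sd_item = 0, sd_text = 0,
                         sd_resid = 0.2, seed = 5)
  g <- simulate_gaze(corpus, metrics, cfg)
  expect_equal(nrow(g), 200 * nrow(metrics))
  expect_equal(mean(g$skipped), 0.5, tolerance = 0.02)
  expect_equal(mean(g$regression_in), 0.5, tolerance = 0.02)
})

test_that("a positive entropy coefficient raises skipping across entropy tertiles", {
  lm <- demo_toy_lm()
  corpus <- sample_passages(lm, 2, 40, seed = 31)
  metrics <- corpus_metrics(lm, corpus)
  cfg <- gaze_sim_config(n_participants = 200,
                         beta = list(skip = c(intercept = 0, entropy = 1,
                                              surprisal = 0,
                                              entropy_surprisal = 0,
                                              frequency = 0, length = 0,
                                              word_number = 0)),
                         sd_participant = 0, sd_item = 0, sd_text = 0,
                         seed = 6)
  g <- simulate_gaze(corpus, metrics, cfg)
  d <- merge(g, metrics[c("word_id", "entropy")], by = "word_id")
  tert <- equal_frequency_bins(d$entropy, 3)$bin
  rates <- tapply(d$skipped, tert, mean)
  expect_true(all(diff(rates) > 0))
})

test_that("an OLS oracle recovers the surprisal effect on log first fixations", {
  lm <- demo_toy_lm()
  corpus <- sample_passages(lm, 2, 60, seed = 41)
  metrics <- corpus_metrics(lm, corpus)
  cfg <- gaze_sim_config(n_participants = 150,
                         beta = list(first_fixation = c(surprisal = 0.05)),
                         sd_participant = 0, sd_item = 0, sd_text = 0,
                         seed = 42)
  g <- simulate_gaze(corpus, metrics, cfg)
  obs <- merge_observations(corpus, g, metrics,
                            frequency = synthetic_frequency_table(corpus))
  ols <- lm(log(first_fixation_ms) ~ entropy * surprisal + log_frequency +
              length_letters + word_number_in_sentence,
            data = obs[!obs$skipped, ])
  est <- coef(summary(ols))["surprisal", ]
  # 3 s.e. keeps this single-draw deterministic check off the coverage
  # boundary; the replicated 2 s.e. recovery study lives elsewhere
  expect_lt(abs(est["Estimate"] - 0.05), 3 * est["Std. Error"])
})

test_that("gaze records respect the structural invariants", {
  s <- small_synth()
  g <- s$gaze
  expect_equal(nrow(g), s$config$n_participants * nrow(s$metrics))
  expect_true(all(is.na(g$first_fixation_ms[g$skipped])))
  expect_true(all(is.na(g$gaze_ms[g$skipped])))
  expect_true(all(is.na(g$total_ms[g$skipped])))
  fx <- g[!g$skipped, ]
  expect_true(all(fx$first_fixation_ms > 0))
  expect_true(all(fx$gaze_ms >= fx$first_fixation_ms))
  expect_true(all(fx$total_ms >= fx$gaze_ms))
  # the intercept spacing alone orders the three measures: nothing clamped
  expect_equal(attr(g, "n_clamped"), 0)
  # determinism
  g2 <- simulate_gaze(s$corpus, s$metrics, s$config)
  expect_identical(g$skipped, g2$skipped)
  expect_identical(g$gaze_ms, g2$gaze_ms)
})

test_that("missing metrics for a non-initial word stop the generator", {
  s <- small_synth(n_participants = 3)
  broken <- s$metrics[-5, ]
  expect_error(simulate_gaze(s$corpus, broken, s$config), "metrics missing")
})

test_that("cloze norms converge to the true conditional probabilities", {
  lm <- uniform_lm()
  corpus <- sample_passages(lm, 2, 60, seed = 13)
  norms <- simulate_cloze(lm, corpus, n_respondents = 10000, seed = 14)
  expect_true(all(abs(norms$cloze_probability - 0.25) < 0.02))
  # degenerate model: every predictable word has cloze exactly 1
  dlm <- degenerate_lm()
  dc <- sample_passages(dlm, 1, 15, seed = 15)
  dn <- simulate_cloze(dlm, dc, n_respondents = 25, seed = 16)
  expect_true(all(dn$cloze_probability == 1))
  # determinism
  n2 <- simulate_cloze(lm, corpus, n_respondents = 10000, seed = 14)
  expect_identical(norms$cloze_probability, n2$cloze_probability)
})

test_that("few respondents floor low-probability words at zero cloze", {
  lm <- toy_lm(c("x", "y", "z"), 1L, list(
    x = c(x = 0.96, y = 0.02, z = 0.02),
    y = c(x = 0.9, y = 0.05, z = 0.05),
    z = c(x = 0.9, y = 0.05, z = 0.05)))
  corpus <- manual_corpus(rep(c("x", "y"), 26))
  norms <- simulate_cloze(lm, corpus, n_respondents = 20, seed = 17)
  rare <- norms[norms$true_probability == 0.02, ]   # the x -> y transitions
  expect_gt(nrow(rare), 20)
  # P(estimate == 0) = 0.98^20 ~ 0.67 per word: the cloze floor effect
  expect_gt(mean(rare$cloze_probability == 0), 0.3)
  expect_true(all(rare$true_probability > 0))
})
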