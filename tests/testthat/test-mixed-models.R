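test_that("the Box-Cox profile points to the right duration transform", {
  set.seed(31)
  lognormal <- rlnorm(5000, meanlog = 5.5, sdlog = 0.3)
  tr <- choose_transform(lognormal)
  expect_lt(abs(tr$lambda), 0.1)
  expect_equal(tr$transform, "log")

  normal <- rnorm(5000, mean = 300, sd = 20)
  tr2 <- choose_transform(normal)
  expect_lt(abs(tr2$lambda - 1), 0.2)
  expect_equal(tr2$transform, "identity")

  expect_error(choose_transform(rep(250, 10)), "constant")
  expect_error(choose_transform(c(100, -5)), "positive")
})

test_that("model specifications validate interactions and choose families", {
  expect_equal(model_spec("skip")$family, "binomial")
  expect_equal(model_spec("gaze")$family, "gaussian_log")
  expect_error(model_spec("skip", fixed = c("entropy", "entropy:cloze")),
               "undeclared")
})

test_that("binary fits satisfy the odds-ratio and chi-square identities", {
  s <- small_synth(n_participants = 25, n_passages = 2, len = 50)
  fit <- suppressWarnings(fit_mixed(model_spec("skip"), s$obs))
  expect_true(fit$converged)
  expect_equal(fit$n, sum(!is.na(s$obs$skipped)))
  # OR = exp(beta) on every term
  expect_equal(fit$coefficients$odds_ratio,
               exp(fit$coefficients$estimate), tolerance = 1e-9)
  # single-df type-III chi-square = squared Wald statistic
  an <- type3_wald(fit)
  ix <- match(fit$coefficients$term, an$term)
  expect_equal(an$chisq[ix], unname(fit$coefficients$statistic^2),
               tolerance = 1e-6)
  expect_true(all(fit$varcomp$variance >= 0))

  # gaussian fit: same chi-square identity, no odds ratios
  fitg <- suppressWarnings(fit_mixed(model_spec("gaze"), s$obs))
  ang <- type3_wald(fitg)
  ixg <- match(fitg$coefficients$term, ang$term)
  expect_equal(ang$chisq[ixg], unname(fitg$coefficients$statistic^2),
               tolerance = 1e-6)
  expect_true(all(is.na(fitg$coefficients$odds_ratio)))
  # duration models use fixated rows only
  expect_equal(fitg$n, sum(!s$obs$skipped))
})

test_that("rank-deficient designs fail with the aliased terms named", {
  s <- small_synth(n_participants = 5, n_passages = 1, len = 20)
  s$obs$entropy_copy <- s$obs$entropy
  expect_error(
    fit_mixed(model_spec("skip", fixed = c("entropy", "entropy_copy")),
              s$obs),
    "aliased")
})

test_that("variance inflation factors match the definition and car::vif", {
  # orthogonal predictors: all VIF exactly 1
  orth <- data.frame(x1 = c(1, 1, -1, -1), x2 = c(1, -1, 1, -1),
                     x3 = c(1, -1, -1, 1))
  v <- vif(orth, c("x1", "x2", "x3"))
  expect_equal(v$vif, rep(1, 3))

  # a duplicated predictor is infinite, not an error
  dup <- data.frame(a = rnorm(20), b = rnorm(20))
  dup$c <- dup$a
  vd <- vif(dup, c("a", "b", "c"))
  expect_true(is.infinite(vd$vif[1]) && is.infinite(vd$vif[3]))

  # cross-check against car::vif on correlated data
  set.seed(33)
  n <- 200
  x1 <- rnorm(n); x2 <- 0.7 * x1 + rnorm(n); x3 <- rnorm(n)
  y <- rnorm(n)
  d <- data.frame(y, x1, x2, x3)
  ours <- vif(d, c("x1", "x2", "x3"))
  theirs <- car::vif(lm(y ~ x1 + x2 + x3, d))
  expect_equal(ours$vif, unname(theirs[ours$term]), tolerance = 1e-8)
})

test_that("collinearity at VIF >= 2 raises the screening warning", {
  s <- small_synth(n_participants = 6, n_passages = 2, len = 30)
  set.seed(34)
  s$obs$near_copy <- s$obs$entropy + rnorm(nrow(s$obs), sd = 0.05)
  expect_warning(
    fit_mixed(model_spec("skip", fixed = c("entropy", "near_copy",
                                           "log_frequency")), s$obs),
    "VIF")
})

test_that("the zero-variance limit of the mixed model equals glm and lm", {
  lm_ <- demo_toy_lm()
  corpus <- sample_passages(lm_, 3, 50, seed = 11)
  metrics <- corpus_metrics(lm_, corpus)
  cfg <- gaze_sim_config(n_participants = 40, seed = 12,
                         sd_participant = 0, sd_item = 0, sd_text = 0)
  gaze <- simulate_gaze(corpus, metrics, cfg)
  obs <- merge_observations(corpus, gaze, metrics,
                            frequency = synthetic_frequency_table(corpus))
  rhs <- skipped ~ entropy * surprisal + log_frequency + length_letters +
    word_number_in_sentence

  beta0 <- fixed_effects_at_zero_variance(model_spec("skip"), obs)
  glm0 <- glm(rhs, binomial, data = obs)
  expect_equal(unname(beta0), unname(coef(glm0)[names(beta0)]),
               tolerance = 1e-4)

  beta0g <- fixed_effects_at_zero_variance(model_spec("gaze"), obs)
  lm0 <- lm(update(rhs, log(gaze_ms) ~ .), data = obs[!obs$skipped, ])
  expect_equal(unname(beta0g), unname(coef(lm0)[names(beta0g)]),
               tolerance = 1e-4)

  # fitting the same data estimates variance components near zero
  fit <- suppressWarnings(fit_mixed(model_spec("gaze"), obs))
  ranvar <- fit$varcomp$variance[fit$varcomp$group != "Residual"]
  expect_true(all(ranvar < 0.01))
  expect_true(fit$singular || all(ranvar == 0))
})

test_that("type-III p-values are uniform under a null word-level factor", {
  lm_ <- demo_toy_lm()
  corpus <- sample_passages(lm_, 2, 30, seed = 51)
  metrics <- corpus_metrics(lm_, corpus)
  nw <- nrow(metrics)
  pvals <- numeric(200)
  for (r in seq_len(200)) {
    cfg <- gaze_sim_config(n_participants = 8, seed = 1000 + r,
                           sd_participant = 0.1, sd_item = 0.1, sd_text = 0,
                           sd_resid = 0.2)
    gaze <- simulate_gaze(corpus, metrics, cfg)
    obs <- merge_observations(corpus, gaze, metrics,
                              frequency = synthetic_frequency_table(corpus))
    set.seed(2000 + r)
    null_cov <- stats::setNames(rnorm(nw), metrics$word_id)
    obs$null_covariate <- null_cov[obs$word_id]
    fit <- suppressWarnings(fit_mixed(
      model_spec("gaze", fixed = c("surprisal", "null_covariate")), obs,
      check_vif = FALSE))
    an <- fit$anova
    pvals[r] <- an$p_value[an$term == "null_covariate"]
  }
  ks <- suppressWarnings(stats::ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.001)
  expect_gt(mean(pvals < 0.05), 0.005)
  expect_lt(mean(pvals < 0.05), 0.15)
})

test_that("a strong simulated interaction is detected by the type-III test", {
  lm_ <- demo_toy_lm()
  corpus <- sample_passages(lm_, 5, 60, seed = 61)
  metrics <- corpus_metrics(lm_, corpus)
  cfg <- gaze_sim_config(n_participants = 60, seed = 62,
                         beta = list(first_fixation = c(entropy_surprisal = -0.1)))
  gaze <- simulate_gaze(corpus, metrics, cfg)
  obs <- merge_observations(corpus, gaze, metrics,
                            frequency = synthetic_frequency_table(corpus))
  fit <- suppressWarnings(fit_mixed(model_spec("first_fixation"), obs))
  an <- type3_wald(fit)
  expect_lt(an$p_value[an$term == "entropy:surprisal"], 0.01)
  est <- fit$coefficients[fit$coefficients$term == "entropy:surprisal", ]
  expect_lt(est$estimate, 0)
})
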