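test_that("raw text becomes a corpus with correct sentence numbering", {
  corpus <- passages_from_text("A b. C d.")
  expect_equal(corpus$word_number_in_sentence, c(1L, 2L, 1L, 2L))
  expect_equal(nrow(corpus), 4)

  two <- passages_from_text(c("one two three", "four five six"))
  expect_equal(nrow(two), 6)
  expect_equal(length(unique(two$word_id)), 6)
  expect_equal(length(unique(two$text_id)), 2)
  expect_error(passages_from_text("   "), "empty passage")
})

test_that("corpus summaries count tokens and normalized types", {
  corpus <- passages_from_text("The cat saw the cat.")
  s <- corpus_summary(corpus)
  expect_equal(s$n_tokens, 5)
  expect_equal(s$n_types, 3)   # the, cat, saw (case/punctuation-insensitive)
})

test_that("passage loading validates ids and derives positions", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(Text_ID = c(1, 1, 1, 2, 2, 2),
                   Word_Unique_ID = paste0("w", 1:6),
                   Word = c("A", "b.", "C", "d", "e", "f."),
                   stringsAsFactors = FALSE)
  write_table_utf8(df, path)
  corpus <- load_passages(path)
  expect_s3_class(corpus, "passage_corpus")
  expect_equal(corpus$position, c(1:3, 1:3))
  expect_equal(corpus$word_number_in_sentence[1:3], c(1L, 2L, 1L))

  df_dup <- df
  df_dup$Word_Unique_ID[2] <- "w1"
  write_table_utf8(df_dup, path)
  expect_error(load_passages(path), "duplicate word_id")
  expect_error(load_passages(path, column_map = list(word = "Missing")),
               "required column not found")
})

test_that("eye-movement reports are validated and cleaned on load", {
  path <- tempfile(fileext = ".tsv")
  df <- data.frame(
    Participant_ID = rep(c("p1", "p2"), each = 3),
    Word_Unique_ID = rep(c("w1", "w2", "w3"), 2),
    IA_SKIP = c(0, 1, 0, 0, 0, 0),
    IA_FIRST_FIXATION_DURATION = c(200, 0, 250, 210, 180, 220),
    IA_FIRST_RUN_DWELL_TIME = c(260, 0, 250, 240, 200, 230),
    IA_DWELL_TIME = c(400, 0, 300, 240, 450, 500))
  df$IA_REGRESSION_IN <- c(0, 0, 1, 0, 1, 0)
  write_table_utf8(df, path)
  g <- load_eye_movement_report(path)
  expect_equal(nrow(g), 6)
  expect_equal(attr(g, "n_dropped"), 0)
  expect_true(is.na(g$gaze_ms[g$skipped][1]))   # skipped -> absent durations

  # a fixated row with gaze < first fixation is dropped and counted
  df$IA_FIRST_RUN_DWELL_TIME[3] <- 100
  write_table_utf8(df, path)
  expect_message(g2 <- load_eye_movement_report(path), "dropped")
  expect_equal(nrow(g2), 5)
  expect_equal(attr(g2, "n_dropped"), 1)

  expect_error(load_eye_movement_report(path, column_map = list(skip = "NoSuch")),
               "required column not found")
})

test_that("cloze norms load with zeros preserved and bounds enforced", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(Word_Unique_ID = paste0("w", 1:5),
                   Cloze_Probability = c(0, 0.2, 0, 1, 0.5))
  utils::write.csv(df, path, row.names = FALSE)
  norms <- load_cloze_norms(path)
  expect_equal(nrow(norms), 5)
  expect_equal(sum(norms$cloze_probability == 0), 2)
  expect_equal(zero_probability_fraction(norms), 0.4)

  df$Cloze_Probability[1] <- 1.2
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(load_cloze_norms(path), "outside")
})

test_that("frequency tables are log10 per-million with case-insensitive lookup", {
  path <- tempfile(fileext = ".csv")
  df <- data.frame(Word = c("The", "cat"), SUBTLWF = c(100, 1))
  utils::write.csv(df, path, row.names = FALSE)
  ft <- load_frequency_table(path)
  expect_equal(frequency_lookup(ft, "the"), 2)
  expect_equal(frequency_lookup(ft, "CAT"), 0)
  expect_true(is.na(frequency_lookup(ft, "dog")))

  df$SUBTLWF[1] <- 0
  utils::write.csv(df, path, row.names = FALSE)
  expect_error(load_frequency_table(path), "positive")
})

test_that("delimited tables round-trip identically", {
  s <- small_synth(n_participants = 4, n_passages = 1, len = 15)
  for (tbl in list(s$corpus, s$gaze)) {
    path <- tempfile(fileext = ".tsv")
    write_table_utf8(tbl, path)
    back <- read_table_auto(path)
    expect_equal(as.data.frame(back), as.data.frame(tbl),
                 ignore_attr = TRUE)
  }
})

test_that("the merge joins metrics and covariates without inventing rows", {
  lm <- hand_lm()
  corpus <- manual_corpus(c("a", "b", "c", "a"))
  metrics <- corpus_metrics(lm, corpus, k = 3)
  gaze <- tibble::tibble(
    participant_id = rep(c("p1", "p2"), each = 4),
    word_id = rep(corpus$word_id, 2),
    skipped = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    first_fixation_ms = c(200, NA, 210, 190, 150, 160, NA, 170),
    gaze_ms = c(250, NA, 210, 220, 150, 180, NA, 200),
    total_ms = c(250, NA, 300, 220, 180, 180, NA, 260),
    regression_in = rep(FALSE, 8))
  obs <- merge_observations(corpus, gaze, metrics)
  # metrics exist for words 2-4 only: 2 participants x 3 words
  expect_equal(nrow(obs), 6)
  expect_equal(sum(obs$skipped) + sum(!obs$skipped), nrow(obs))
  expect_true(all(c("entropy", "surprisal", "similarity", "length_letters",
                    "word_number_in_sentence", "text_id") %in% names(obs)))

  # a fixated word with no metrics (and not passage-initial) is an error
  expect_error(merge_observations(corpus, gaze, metrics[-2, ]),
               "metrics missing")
  # duplicated participant x word pairs are rejected
  dup <- rbind(gaze, gaze[1, ])
  expect_error(merge_observations(corpus, dup, metrics), "duplicated")
  # unknown word ids are rejected
  alien <- gaze
  alien$word_id[1] <- "nowhere"
  expect_error(merge_observations(corpus, alien, metrics), "unknown")
})

test_that("observations missing a frequency entry are kept but flagged", {
  lm <- hand_lm()
  corpus <- manual_corpus(c("a", "b", "c"))
  metrics <- corpus_metrics(lm, corpus, k = 3)
  gaze <- tibble::tibble(
    participant_id = "p1", word_id = corpus$word_id,
    skipped = FALSE, first_fixation_ms = c(200, 210, 190),
    gaze_ms = c(200, 220, 210), total_ms = c(230, 220, 260),
    regression_in = FALSE)
  freq <- tibble::tibble(word = "b", key = "b", log_frequency = 1.5)
  expect_message(
    obs <- merge_observations(corpus, gaze, metrics, frequency = freq),
    "no frequency entry")
  expect_equal(nrow(obs), 2)              # merge conserves rows
  expect_equal(sum(is.na(obs$log_frequency)), 1)
})
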