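# toy models with hand-checkable conditional tables

hand_lm <- function() {
  toy_lm(c("a", "b", "c"), 1L, list(
    a = c(a = 0.5, b = 0.25, c = 0.25),
    b = c(a = 0.1, b = 0.2, c = 0.7),
    c = c(a = 1 / 3, b = 1 / 3, c = 1 / 3)))
}

uniform_lm <- function(vocab = c("a", "b", "c", "d")) {
  V <- length(vocab)
  rows <- stats::setNames(
    rep(list(stats::setNames(rep(1 / V, V), vocab)), V), vocab)
  toy_lm(vocab, 1L, rows)
}

# deterministic cycle: the -> end -> the -> ...
degenerate_lm <- function() {
  toy_lm(c("the", "end"), 1L, list(
    the = c(the = 0, end = 1),
    end = c(the = 1, end = 0)))
}

# toy model with a two-token word, for chain-rule checks
chain_lm <- function() {
  toy_lm(c("a", "b", "c"), 1L, list(
    a = c(a = 0.5, b = 0.25, c = 0.25),
    b = c(a = 0.1, b = 0.2, c = 0.7),
    c = c(a = 1 / 3, b = 1 / 3, c = 1 / 3)),
    subword_map = list(bc = c("b", "c")))
}

# a small corpus over an explicit vocabulary, built by hand
manual_corpus <- function(words, text_id = "text001") {
  tibble::tibble(
    text_id = text_id,
    word_id = sprintf("%s_w%04d", text_id, seq_along(words)),
    position = seq_along(words),
    word = words,
    word_number_in_sentence = seq_along(words))
}

# full synthetic slice: corpus + metrics + gaze + observation table
small_synth <- function(n_participants = 20, n_passages = 2, len = 40,
                        seed = 7, beta = NULL, sd_participant = 0.3,
                        sd_item = 0.2, sd_text = 0.1, sd_resid = 0.25) {
  lm <- demo_toy_lm()
  corpus <- sample_passages(lm, n_passages, len, seed = seed)
  metrics <- corpus_metrics(lm, corpus, k = 10)
  cfg <- gaze_sim_config(n_participants = n_participants, beta = beta,
                         sd_participant = sd_participant, sd_item = sd_item,
                         sd_text = sd_text, sd_resid = sd_resid,
                         seed = seed + 1)
  gaze <- simulate_gaze(corpus, metrics, cfg)
  obs <- merge_observations(corpus, gaze, metrics,
                            frequency = synthetic_frequency_table(corpus))
  list(lm = lm, corpus = corpus, metrics = metrics, gaze = gaze, obs = obs,
       config = cfg)
}

# map generator coefficient names to fitted term names
generative_truth <- function(b) {
  c("entropy" = unname(b[["entropy"]]),
    "surprisal" = unname(b[["surprisal"]]),
    "entropy:surprisal" = unname(b[["entropy_surprisal"]]),
    "log_frequency" = unname(b[["frequency"]]),
    "length_letters" = unname(b[["length"]]),
    "word_number_in_sentence" = unname(b[["word_number"]]))
}
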