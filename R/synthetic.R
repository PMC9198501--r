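#' Sample text passages from a toy language model
#'
#' Draws each word from the model's conditional next-word distribution
#' (the first `order` words of a passage are drawn uniformly from the
#' vocabulary). Passages are segmented into sentences of random length so
#' that `word_number_in_sentence` varies the way the analysis models
#' expect. Identical seeds reproduce the corpus bit-identically.
#'
#' @param lm a [toy_lm()] whose words are single tokens.
#' @param n_passages number of passages.
#' @param length words per passage; must exceed the model order.
#' @param seed integer seed.
#' @param sentence_lengths pool of sentence lengths to draw from.
#' @return a `passage_corpus`.
#' @export
sample_passages <- function(lm, n_passages, length, seed,
                            sentence_lengths = 5:12) {
  stopifnot(inherits(lm, "toy_lm"), n_passages >= 1, length > lm$order)
  if (!is.null(lm$subword_map)) {
    stop("passage sampling requires a model whose words are single tokens")
  }
  set.seed(seed)
  out <- vector("list", n_passages)
  for (p in seq_len(n_passages)) {
    words <- character(length)
    for (i in seq_len(length)) {
      if (i <= lm$order) {
        words[i] <- sample(lm$vocabulary, 1)
      } else {
        probs <- exp(next_token_logits(lm, words[seq_len(i - 1)]))
        words[i] <- sample(lm$vocabulary, 1, prob = probs)
      }
    }
    sl <- integer(0)
    while (sum(sl) < length) {
      sl <- c(sl, sample(sentence_lengths, 1))
    }
    sentence <- rep(seq_along(sl), sl)[seq_len(length)]
    wns <- stats::ave(seq_len(length), sentence, FUN = seq_along)
    tid <- sprintf("text%03d", p)
    out[[p]] <- tibble::tibble(
      text_id = tid,
      word_id = sprintf("%s_w%04d", tid, seq_len(length)),
      position = seq_len(length),
      word = words,
      word_number_in_sentence = as.integer(wns))
  }
  as_passage_corpus(do.call(rbind, out))
}

#' Corpus-derived frequency table for synthetic runs
#'
#' Counts normalized word forms in the corpus and expresses them per
#' million tokens, standing in for an external frequency norm when the
#' corpus is synthetic (its "language" exists nowhere else).
#'
#' @param corpus a `passage_corpus`.
#' @return tibble `word`, `key`, `log_frequency` compatible with
#'   [frequency_lookup()].
#' @export
synthetic_frequency_table <- function(corpus) {
  corpus <- as_passage_corpus(corpus)
  w <- normalize_word(corpus$word)
  tab <- table(w)
  tibble::tibble(word = names(tab), key = names(tab),
                 log_frequency = log10(as.numeric(tab) / length(w) * 1e6))
}

default_gaze_beta <- function() {
  list(
    skip = c(intercept = -0.2, entropy = -0.073, surprisal = -0.05,
             entropy_surprisal = -0.01, frequency = 0.3, length = -0.35,
             word_number = 0.005, similarity = 0),
    first_fixation = c(intercept = 5.42, entropy = 0.005, surprisal = 0.01,
                       entropy_surprisal = -0.005, frequency = -0.02,
                       length = 0.02, word_number = -0.001, similarity = 0),
    gaze = c(intercept = 5.52, entropy = 0.01, surprisal = 0.02,
             entropy_surprisal = 0, frequency = -0.02, length = 0.02,
             word_number = -0.001, similarity = 0),
    total_time = c(intercept = 5.70, entropy = 0.01, surprisal = 0.05,
                   entropy_surprisal = 0, frequency = -0.02, length = 0.02,
                   word_number = -0.001, similarity = 0),
    regression = c(intercept = -1.73, entropy = 0.077, surprisal = 0.223,
                   entropy_surprisal = 0, frequency = -0.05, length = 0.01,
                   word_number = 0.003, similarity = 0))
}

#' Configuration for the synthetic gaze generator
#'
#' Holds the generative coefficients of the five outcome models (skip
#' logit, log first fixation, log gaze, log total time, regression logit)
#' and the random-effect standard deviations. Each coefficient vector has
#' elements `intercept`, `entropy`, `surprisal`, `entropy_surprisal`,
#' `frequency`, `length`, `word_number` and `similarity` (per bit, per
#' log10 frequency unit, per letter, per sentence position, per cosine
#' unit). Defaults are plausible reading-behaviour magnitudes: entropy odds
#' ratio on skipping below 1 (constraining contexts invite skipping),
#' surprisal lengthening durations by a few percent per bit, regressions
#' drawn to high-surprisal words. User values are merged element-wise into
#' the defaults.
#'
#' @param n_participants number of simulated readers (>= 2); default 84.
#' @param beta optional list of named coefficient vectors to override, e.g.
#'   `list(skip = c(entropy = 1))`.
#' @param sd_participant,sd_item,sd_text random-intercept standard
#'   deviations (shared draws across the outcome models).
#' @param sd_resid residual standard deviation of the log-duration models.
#' @param seed integer seed.
#' @return an object of class `gaze_sim_config`.
#' @export
gaze_sim_config <- function(n_participants = 84, beta = NULL,
                            sd_participant = 0.3, sd_item = 0.2,
                            sd_text = 0.1, sd_resid = 0.25, seed = 1L) {
  stopifnot(n_participants >= 2, sd_participant >= 0, sd_item >= 0,
            sd_text >= 0, sd_resid >= 0)
  full <- default_gaze_beta()
  user <- beta %||% list()
  if (length(user)) {
    bad <- setdiff(names(user), names(full))
    if (length(bad)) stop("unknown outcome model(s): ", paste(bad, collapse = ", "))
    for (nm in names(user)) {
      u <- user[[nm]]
      badterm <- setdiff(names(u), names(full[[nm]]))
      if (length(badterm)) {
        stop("unknown coefficient(s) for ", nm, ": ", paste(badterm, collapse = ", "))
      }
      full[[nm]][names(u)] <- u
    }
  }
  structure(list(n_participants = as.integer(n_participants), beta = full,
                 sd_participant = sd_participant, sd_item = sd_item,
                 sd_text = sd_text, sd_resid = sd_resid,
                 seed = as.integer(seed)),
            class = "gaze_sim_config")
}

#' Simulate word-by-word gaze records with known generative structure
#'
#' For every participant x word cell (words carrying metrics, i.e. all
#' non-initial words), a linear predictor
#' `intercept + b_H*entropy + b_S*surprisal + b_HS*entropy*surprisal +
#' b_f*log_frequency + b_l*length + b_w*word_number + b_sim*similarity`
#' plus crossed participant/item/text random intercepts (one shared draw
#' per grouping level across all outcome models) drives each outcome:
#' skipping and regression indicators are Bernoulli draws through the
#' logistic link, and the three reading-time measures are log-normal. A
#' single residual draw is shared by the three log-duration models — the
#' three measures are nested sums of the same fixations, so their residuals
#' are treated as perfectly coupled — which, together with the intercept
#' spacing, keeps `first_fixation <= gaze <= total` while leaving each
#' outcome exactly log-normal under its own linear predictor. Skipped
#' words carry absent (not zero) durations.
#'
#' @param corpus a `passage_corpus`.
#' @param metrics prediction states from [corpus_metrics()]; must cover
#'   every non-initial word of the corpus.
#' @param config a [gaze_sim_config()].
#' @param frequency optional frequency table; defaults to
#'   [synthetic_frequency_table()] of the corpus.
#' @return tibble of gaze records, `config$n_participants` rows per word
#'   with metrics.
#' @export
simulate_gaze <- function(corpus, metrics, config = gaze_sim_config(),
                          frequency = NULL) {
  stopifnot(inherits(config, "gaze_sim_config"))
  corpus <- as_passage_corpus(corpus)
  noninitial <- corpus$word_id[corpus$position > 1]
  missing_ids <- setdiff(noninitial, metrics$word_id)
  if (length(missing_ids)) {
    stop("metrics missing for words: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }
  freq <- frequency %||% synthetic_frequency_table(corpus)

  wt <- merge(metrics[c("word_id", "entropy", "surprisal", "similarity")],
              corpus[c("word_id", "text_id", "word", "word_number_in_sentence")],
              by = "word_id", sort = FALSE)
  wt$log_frequency <- frequency_lookup(freq, wt$word)
  if (anyNA(wt$log_frequency)) {
    stop("missing covariate log_frequency for words: ",
         paste(utils::head(wt$word_id[is.na(wt$log_frequency)], 5), collapse = ", "))
  }
  wt$length_letters <- nchar(gsub("[[:punct:]]", "", wt$word))

  set.seed(config$seed)
  n <- config$n_participants
  nw <- nrow(wt)
  participants <- sprintf("P%03d", seq_len(n))
  texts <- unique(wt$text_id)
  u_p <- stats::rnorm(n, 0, config$sd_participant)
  u_i <- stats::rnorm(nw, 0, config$sd_item)
  u_t <- stats::setNames(stats::rnorm(length(texts), 0, config$sd_text), texts)

  pidx <- rep(seq_len(n), each = nw)
  widx <- rep(seq_len(nw), times = n)
  re <- u_p[pidx] + u_i[widx] + u_t[wt$text_id[widx]]

  lp <- function(b) {
    b[["intercept"]] +
      b[["entropy"]] * wt$entropy[widx] +
      b[["surprisal"]] * wt$surprisal[widx] +
      b[["entropy_surprisal"]] * wt$entropy[widx] * wt$surprisal[widx] +
      b[["frequency"]] * wt$log_frequency[widx] +
      b[["length"]] * wt$length_letters[widx] +
      b[["word_number"]] * wt$word_number_in_sentence[widx] +
      b[["similarity"]] * wt$similarity[widx]
  }

  N <- n * nw
  skip <- stats::rbinom(N, 1, stats::plogis(lp(config$beta$skip) + re)) == 1
  z <- stats::rnorm(N)
  ffd <- exp(lp(config$beta$first_fixation) + re + config$sd_resid * z)
  gaz <- exp(lp(config$beta$gaze) + re + config$sd_resid * z)
  tot <- exp(lp(config$beta$total_time) + re + config$sd_resid * z)
  n_clamped <- sum(gaz < ffd) + sum(tot < pmax(gaz, ffd))
  gaz <- pmax(gaz, ffd)
  tot <- pmax(tot, gaz)
  reg <- stats::rbinom(N, 1, stats::plogis(lp(config$beta$regression) + re)) == 1

  ffd[skip] <- NA_real_
  gaz[skip] <- NA_real_
  tot[skip] <- NA_real_

  out <- tibble::tibble(
    participant_id = participants[pidx],
    word_id = wt$word_id[widx],
    skipped = skip,
    first_fixation_ms = ffd,
    gaze_ms = gaz,
    total_ms = tot,
    regression_in = reg)
  attr(out, "n_clamped") <- n_clamped
  out
}

#' Simulate cloze norms from a toy language model
#'
#' For each non-initial word, `n_respondents` guesses are drawn from the
#' model's conditional next-word distribution given the true preceding
#' context, and the norm is the fraction of guesses matching the actual
#' word (sampled directly as a binomial count of that fraction). With few
#' respondents, low-probability words often receive an estimate of exactly
#' zero — the cloze floor effect that model-based probabilities avoid.
#'
#' @param lm a [toy_lm()].
#' @param corpus a `passage_corpus` sampled from (or compatible with) `lm`.
#' @param n_respondents number of simulated respondents (>= 1).
#' @param seed integer seed.
#' @return tibble `word_id`, `cloze_probability`, `true_probability`.
#' @export
simulate_cloze <- function(lm, corpus, n_respondents, seed) {
  stopifnot(inherits(lm, "toy_lm"), n_respondents >= 1)
  corpus <- as_passage_corpus(corpus)
  set.seed(seed)
  p <- word_true_probabilities(lm, corpus)
  correct <- stats::rbinom(nrow(p), n_respondents, p$true_probability)
  tibble::tibble(word_id = p$word_id,
                 cloze_probability = correct / n_respondents,
                 true_probability = p$true_probability)
}

#' Simulate individual cloze respondents' guesses
#'
#' The long-format companion of [simulate_cloze()]: each respondent guesses
#' the next word at every non-initial position, drawing from the model's
#' conditional distribution. Used to study per-respondent accuracy the way
#' word-by-word cloze norms are collected.
#'
#' @inheritParams simulate_cloze
#' @return tibble `respondent_id`, `word_id`, `guess`, `target`.
#' @export
simulate_cloze_responses <- function(lm, corpus, n_respondents, seed) {
  stopifnot(inherits(lm, "toy_lm"), n_respondents >= 1)
  corpus <- as_passage_corpus(corpus)
  set.seed(seed)
  parts <- lapply(split(corpus, corpus$text_id), function(pass) {
    pass <- pass[order(pass$position), ]
    rows <- vector("list", nrow(pass) - 1)
    for (i in 2:nrow(pass)) {
      probs <- exp(next_token_logits(lm, pass$word[seq_len(i - 1)]))
      guesses <- sample(lm$vocabulary, n_respondents, replace = TRUE,
                        prob = probs)
      rows[[i - 1]] <- tibble::tibble(
        respondent_id = sprintf("R%04d", seq_len(n_respondents)),
        word_id = pass$word_id[i],
        guess = guesses,
        target = pass$word[i])
    }
    do.call(rbind, rows)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}

# true conditional probability of each non-initial corpus word under lm
word_true_probabilities <- function(lm, corpus) {
  parts <- lapply(split(corpus, corpus$text_id), function(pass) {
    pass <- pass[order(pass$position), ]
    p <- numeric(nrow(pass) - 1)
    for (i in 2:nrow(pass)) {
      probs <- exp(next_token_logits(lm, pass$word[seq_len(i - 1)]))
      p[i - 1] <- probs[[match(pass$word[i], lm$vocabulary)]]
    }
    tibble::tibble(word_id = pass$word_id[-1], true_probability = p)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out
}
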