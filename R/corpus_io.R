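#' Validate and class a passage corpus table
#'
#' A passage corpus has one row per word token with columns `text_id`,
#' `word_id` (unique across the corpus), `position` (1-based within the
#' passage), `word` (non-empty surface form) and `word_number_in_sentence`
#' (1-based, resetting after each sentence-final word).
#'
#' @param df a data frame with the columns above.
#' @return the validated corpus as a tibble of class `passage_corpus`.
#' @export
as_passage_corpus <- function(df) {
  df <- tibble::as_tibble(df)
  required <- c("text_id", "word_id", "position", "word",
                "word_number_in_sentence")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("corpus is missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(df$word_id)) stop("word_id values must be unique")
  if (any(is.na(df$word)) || any(!nzchar(df$word))) {
    stop("empty surface forms are not allowed")
  }
  if (!inherits(df, "passage_corpus")) {
    class(df) <- c("passage_corpus", class(df))
  }
  df
}

#' Token and type counts for a corpus
#'
#' Types are counted on case-insensitive, punctuation-stripped forms
#' ([normalize_word()]); the normalization is the configurable piece behind
#' published token/type totals.
#'
#' @param corpus a passage corpus.
#' @return list with `n_passages`, `n_tokens`, `n_types`.
#' @export
corpus_summary <- function(corpus) {
  corpus <- as_passage_corpus(corpus)
  list(n_passages = length(unique(corpus$text_id)),
       n_tokens = nrow(corpus),
       n_types = length(unique(normalize_word(corpus$word))))
}

#' Build a passage corpus from raw text strings
#'
#' Words are split on whitespace; a word ending in `.`, `?` or `!`
#' (optionally followed by closing quotes or brackets) closes a sentence,
#' so `word_number_in_sentence` restarts at 1 on the next word.
#'
#' @param texts character vector, one passage per element.
#' @param text_ids passage identifiers.
#' @return a `passage_corpus`.
#' @export
#' @examples
#' passages_from_text("A b. C d.")$word_number_in_sentence  # 1 2 1 2
passages_from_text <- function(texts,
                               text_ids = sprintf("text%03d", seq_along(texts))) {
  stopifnot(length(texts) == length(text_ids))
  parts <- vector("list", length(texts))
  for (i in seq_along(texts)) {
    words <- strsplit(trimws(texts[[i]]), "\\s+")[[1]]
    if (!length(words) || !any(nzchar(words))) {
      stop("empty passage: ", text_ids[i])
    }
    final <- grepl("[.?!][]\"')]*$", words)
    sentence <- 1 + c(0, cumsum(utils::head(final, -1)))
    wns <- stats::ave(seq_along(words), sentence, FUN = seq_along)
    parts[[i]] <- tibble::tibble(
      text_id = text_ids[i],
      word_id = sprintf("%s_w%04d", text_ids[i], seq_along(words)),
      position = seq_along(words),
      word = words,
      word_number_in_sentence = as.integer(wns))
  }
  as_passage_corpus(do.call(rbind, parts))
}

#' Default column mapping for Provo-style passage tables
#' @return named list mapping corpus fields to source column names.
#' @export
provo_passage_columns <- function() {
  list(text_id = "Text_ID", word_id = "Word_Unique_ID", word = "Word",
       word_number_in_sentence = "Word_In_Sentence_Number")
}

#' Load a passage corpus from a delimited table
#'
#' @param path delimited file with one row per word token, in reading order
#'   within each passage.
#' @param column_map named list mapping `text_id`, `word_id`, `word` and
#'   (optionally) `word_number_in_sentence` to source column names; defaults
#'   to the Provo dialect ([provo_passage_columns()]). When the
#'   word-number column is absent, sentence positions are derived from
#'   sentence-final punctuation. Unknown extra columns are ignored.
#' @return a `passage_corpus`.
#' @export
load_passages <- function(path, column_map = NULL) {
  cm <- utils::modifyList(provo_passage_columns(), column_map %||% list())
  raw <- read_table_auto(path)
  for (field in c("text_id", "word_id", "word")) {
    if (!cm[[field]] %in% names(raw)) {
      stop("required column not found: ", cm[[field]], " (", field, ")")
    }
  }
  out <- tibble::tibble(text_id = as.character(raw[[cm$text_id]]),
                        word_id = as.character(raw[[cm$word_id]]),
                        word = as.character(raw[[cm$word]]))
  if (anyDuplicated(out$word_id)) stop("duplicate word_id in ", path)
  out$position <- stats::ave(seq_len(nrow(out)), out$text_id, FUN = seq_along)
  if (cm$word_number_in_sentence %in% names(raw)) {
    out$word_number_in_sentence <- as.integer(raw[[cm$word_number_in_sentence]])
  } else {
    final <- grepl("[.?!][]\"')]*$", out$word)
    sent <- stats::ave(as.integer(final), out$text_id,
                       FUN = function(f) 1 + c(0, cumsum(utils::head(f, -1))))
    out$word_number_in_sentence <- as.integer(
      stats::ave(seq_len(nrow(out)), paste(out$text_id, sent), FUN = seq_along))
  }
  as_passage_corpus(out)
}

#' Default column mapping for Provo/EyeLink interest-area reports
#' @return named list mapping gaze fields to source column names.
#' @export
provo_gaze_columns <- function() {
  list(participant_id = "Participant_ID", word_id = "Word_Unique_ID",
       skip = "IA_SKIP", first_fixation = "IA_FIRST_FIXATION_DURATION",
       gaze = "IA_FIRST_RUN_DWELL_TIME", total = "IA_DWELL_TIME",
       regression_in = "IA_REGRESSION_IN")
}

#' Load a word-by-word eye-movement report
#'
#' Reads an interest-area report (one row per participant x word) and
#' validates it into gaze records. On skipped words the duration fields are
#' absent by definition; zeros or missing values there are treated as
#' absent. Fixated rows must satisfy `0 < first_fixation <= gaze <= total`;
#' rows violating the ordering (or fixated rows with missing durations) are
#' dropped, counted and reported.
#'
#' @param path delimited file.
#' @param column_map named list overriding [provo_gaze_columns()]. All seven
#'   fields are required; an unmapped column is an error naming it.
#' @return tibble of gaze records (`participant_id`, `word_id`, `skipped`,
#'   `first_fixation_ms`, `gaze_ms`, `total_ms`, `regression_in`) with
#'   attribute `n_dropped`.
#' @export
load_eye_movement_report <- function(path, column_map = NULL) {
  cm <- utils::modifyList(provo_gaze_columns(), column_map %||% list())
  raw <- read_table_auto(path)
  for (field in names(provo_gaze_columns())) {
    if (!cm[[field]] %in% names(raw)) {
      stop("required column not found: ", cm[[field]], " (", field, ")")
    }
  }
  num_or_na <- function(x) {
    x <- suppressWarnings(as.numeric(x))
    ifelse(!is.na(x) & x > 0, x, NA_real_)
  }
  out <- tibble::tibble(
    participant_id = as.character(raw[[cm$participant_id]]),
    word_id = as.character(raw[[cm$word_id]]),
    skipped = as.integer(raw[[cm$skip]]) == 1L,
    first_fixation_ms = num_or_na(raw[[cm$first_fixation]]),
    gaze_ms = num_or_na(raw[[cm$gaze]]),
    total_ms = num_or_na(raw[[cm$total]]),
    regression_in = as.integer(raw[[cm$regression_in]]) == 1L)
  out$first_fixation_ms[out$skipped] <- NA_real_
  out$gaze_ms[out$skipped] <- NA_real_
  out$total_ms[out$skipped] <- NA_real_
  bad <- !out$skipped & (is.na(out$first_fixation_ms) | is.na(out$gaze_ms) |
    is.na(out$total_ms) | out$gaze_ms < out$first_fixation_ms |
    out$total_ms < out$gaze_ms)
  bad[is.na(bad)] <- TRUE
  if (any(bad)) {
    message(sum(bad), " row(s) violated the duration-ordering invariants and were dropped")
  }
  out <- out[!bad, ]
  attr(out, "n_dropped") <- sum(bad)
  out
}

#' Load word-by-word cloze norms
#'
#' @param path delimited file.
#' @param column_map named list with `word_id` and `cloze_probability`
#'   source column names (defaults `Word_Unique_ID`, `Cloze_Probability`).
#' @return tibble `word_id`, `cloze_probability`. Values must lie in
#'   `[0, 1]`; exact zeros are preserved (they carry the cloze floor
#'   information), never treated as missing.
#' @export
load_cloze_norms <- function(path, column_map = NULL) {
  cm <- utils::modifyList(
    list(word_id = "Word_Unique_ID", cloze_probability = "Cloze_Probability"),
    column_map %||% list())
  raw <- read_table_auto(path)
  for (field in names(cm)) {
    if (!cm[[field]] %in% names(raw)) {
      stop("required column not found: ", cm[[field]], " (", field, ")")
    }
  }
  p <- as.numeric(raw[[cm$cloze_probability]])
  bad <- !is.na(p) & (p < 0 | p > 1)
  if (any(bad)) {
    stop("cloze probabilities outside [0, 1]: ",
         paste(utils::head(p[bad], 3), collapse = ", "))
  }
  tibble::tibble(word_id = as.character(raw[[cm$word_id]]),
                 cloze_probability = p)
}

#' Load a SUBTLEX-style word-frequency table
#'
#' @param path delimited file with word and frequency-per-million columns.
#' @param column_map named list with `word` and `freq_per_million` source
#'   column names (defaults `Word`, `SUBTLWF`).
#' @return tibble `word`, `key` (normalized form used for case-insensitive
#'   lookup) and `log_frequency` (log10 of frequency per million).
#' @export
#' @examples
#' \dontrun{
#' ft <- load_frequency_table("subtlex.csv")
#' frequency_lookup(ft, c("The", "brain"))
#' }
load_frequency_table <- function(path, column_map = NULL) {
  cm <- utils::modifyList(list(word = "Word", freq_per_million = "SUBTLWF"),
                          column_map %||% list())
  raw <- read_table_auto(path)
  for (field in names(cm)) {
    if (!cm[[field]] %in% names(raw)) {
      stop("required column not found: ", cm[[field]], " (", field, ")")
    }
  }
  fpm <- as.numeric(raw[[cm$freq_per_million]])
  if (any(is.na(fpm) | fpm <= 0)) {
    stop("frequencies must be positive (per million)")
  }
  tibble::tibble(word = as.character(raw[[cm$word]]),
                 key = normalize_word(raw[[cm$word]]),
                 log_frequency = log10(fpm))
}

#' Case-insensitive log-frequency lookup
#'
#' @param frequency_table result of [load_frequency_table()] or
#'   [synthetic_frequency_table()].
#' @param words character vector of surface forms.
#' @return numeric vector of log10 frequencies per million; `NA` for words
#'   absent from the table.
#' @export
frequency_lookup <- function(frequency_table, words) {
  key <- if ("key" %in% names(frequency_table)) frequency_table$key
         else normalize_word(frequency_table$word)
  frequency_table$log_frequency[match(normalize_word(words), key)]
}

#' Merge gaze records, metrics and covariates into the analysis table
#'
#' Produces the observation table the mixed models consume: one row per
#' participant x word, restricted to words that carry predictability
#' metrics. Passage-initial words have no preceding context, so the moving
#' window defines no metrics for them and their observations are excluded;
#' a metric missing for any other fixatable word is an error. The merge
#' never invents or duplicates observations: output rows equal the gaze
#' rows whose word has metrics, and the skipped/fixated partition is
#' preserved.
#'
#' @param corpus a `passage_corpus`.
#' @param gaze gaze records (see [load_eye_movement_report()] or
#'   [simulate_gaze()]).
#' @param metrics prediction states from [corpus_metrics()].
#' @param cloze optional cloze norms table (`word_id`, `cloze_probability`).
#' @param frequency optional frequency table; words missing from it get
#'   `NA` log-frequency (reported) and are dropped later, at model-fit
#'   time, so the merge itself stays count-preserving.
#' @return observation table tibble.
#' @export
merge_observations <- function(corpus, gaze, metrics, cloze = NULL,
                               frequency = NULL) {
  corpus <- as_passage_corpus(corpus)
  unknown <- setdiff(unique(gaze$word_id), corpus$word_id)
  if (length(unknown)) {
    stop("gaze records reference unknown word_ids: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  if (anyDuplicated(gaze[c("participant_id", "word_id")])) {
    stop("duplicated (participant_id, word_id) pairs in gaze records")
  }
  initial_ids <- corpus$word_id[corpus$position == 1]
  has_metric <- gaze$word_id %in% metrics$word_id
  missing_ids <- setdiff(unique(gaze$word_id[!has_metric]), initial_ids)
  if (length(missing_ids)) {
    stop("metrics missing for non-initial words: ",
         paste(utils::head(missing_ids, 5), collapse = ", "))
  }

  obs <- gaze[has_metric, ]
  m <- metrics[c("word_id", "target_probability", "entropy", "surprisal",
                 "similarity")]
  obs <- merge(obs, m, by = "word_id", sort = FALSE)
  cw <- corpus[c("word_id", "text_id", "word", "word_number_in_sentence")]
  obs <- merge(obs, cw, by = "word_id", sort = FALSE)
  obs$length_letters <- nchar(gsub("[[:punct:]]", "", obs$word))

  if (!is.null(cloze)) {
    obs <- merge(obs, cloze[c("word_id", "cloze_probability")],
                 by = "word_id", all.x = TRUE, sort = FALSE)
  } else {
    obs$cloze_probability <- NA_real_
  }
  if (!is.null(frequency)) {
    obs$log_frequency <- frequency_lookup(frequency, obs$word)
    n_missing <- sum(is.na(obs$log_frequency))
    if (n_missing) {
      message(n_missing,
              " observation(s) have no frequency entry; they will be dropped from model fits")
    }
  } else {
    obs$log_frequency <- NA_real_
  }
  tibble::as_tibble(obs)
}
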