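#' Softmax normalization of logit scores
#'
#' Converts a vector of logit prediction scores into a probability vector,
#' subtracting the maximum before exponentiation for overflow safety.
#' `-Inf` logits (impossible tokens) are allowed and map to probability 0.
#'
#' @param logits numeric vector of logit scores.
#' @return probability vector of the same length, summing to 1 within 1e-9.
#' @export
#' @examples
#' softmax_normalize(c(0, 0))        # 0.5 0.5
#' softmax_normalize(c(log(2), 0))   # 2/3 1/3
softmax_normalize <- function(logits) {
  if (length(logits) == 0) stop("cannot normalize an empty logit vector")
  if (any(is.na(logits)) || any(logits == Inf)) {
    stop("logits must be finite (or -Inf for impossible tokens)")
  }
  m <- max(logits)
  if (!is.finite(m)) stop("all logits are -Inf")
  e <- exp(logits - m)
  e / sum(e)
}

#' Shannon entropy of a probability vector, in bits
#'
#' `H = -sum(p * log2(p))` with the `0 * log(0) := 0` convention. For a
#' vector over `V` outcomes, `0 <= H <= log2(V)`, with equality at the upper
#' bound iff the distribution is uniform.
#'
#' @param p probability vector (non-negative, sums to 1 within 1e-6).
#' @return entropy in bits.
#' @export
#' @examples
#' shannon_entropy(rep(1/4, 4))        # 2 bits
#' shannon_entropy(c(0.5, 0.25, 0.25)) # 1.5 bits
shannon_entropy <- function(p) {
  if (length(p) == 0) stop("empty probability vector")
  if (any(is.na(p)) || any(p < 0)) stop("probabilities must be non-negative")
  if (abs(sum(p) - 1) > 1e-6) stop("probabilities must sum to 1")
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

#' Probability and surprisal of a word in context
#'
#' The word is tokenized by the backend; its probability is the chain-rule
#' product of conditional next-token probabilities along its tokens, and its
#' surprisal is `-log2(p)` bits — so a word's surprisal is the sum of its
#' tokens' surprisals. A token probability of exactly zero would give
#' infinite surprisal; such words are capped at `cap_bits` (with
#' `probability = 2^-cap_bits` so the surprisal/probability identity is
#' preserved) and flagged.
#'
#' @param backend a language-model backend.
#' @param context character vector of preceding tokens.
#' @param target the word string to score.
#' @param cap_bits surprisal ceiling applied when a token probability is
#'   exactly zero (default 30 bits).
#' @return a list with `probability`, `surprisal` (bits) and `capped`.
#' @export
word_surprisal <- function(backend, context, target, cap_bits = 30) {
  units <- tokenize_word(backend, target)
  vocab <- backend_vocabulary(backend)
  ctx <- context
  log2p <- 0
  for (u in units) {
    prob <- softmax_normalize(next_token_logits(backend, ctx))
    pu <- prob[[match(u, vocab)]]
    log2p <- log2p + if (pu > 0) log2(pu) else -Inf
    ctx <- c(ctx, u)
  }
  capped <- !is.finite(log2p) || -log2p > cap_bits
  if (capped) log2p <- -cap_bits
  list(probability = 2^log2p, surprisal = -log2p, capped = capped)
}

#' Top-k next-word candidates given a context
#'
#' Ranks the backend's next-token distribution in decreasing probability,
#' breaking ties deterministically by vocabulary index. For the toy backend
#' tokens are words, so token ranking and word ranking coincide; a subword
#' backend would decode token continuations to words behind this same
#' interface.
#'
#' @param backend a language-model backend.
#' @param context character vector of preceding tokens.
#' @param k number of candidates, between 1 and the vocabulary size.
#' @return tibble with columns `word` and `probability` (non-increasing).
#' @export
top_k_candidates <- function(backend, context, k) {
  vocab <- backend_vocabulary(backend)
  if (k < 1 || k > length(vocab)) {
    stop("k must be between 1 and the vocabulary size (", length(vocab), ")")
  }
  p <- softmax_normalize(next_token_logits(backend, context))
  ord <- order(-p, seq_along(p))
  idx <- ord[seq_len(k)]
  tibble::tibble(word = vocab[idx], probability = unname(p[idx]))
}

#' Cosine similarity between a predicted and an observed word
#'
#' Both words are embedded by the backend in the same preceding context
#' (mean-pooled over their tokens) and compared by cosine. Symmetric in the
#' two word arguments for a fixed context.
#'
#' @param backend a language-model backend.
#' @param context character vector of preceding tokens.
#' @param predicted,target word strings.
#' @return cosine similarity in `[-1, 1]`.
#' @export
target_prediction_similarity <- function(backend, context, predicted, target) {
  cosine_similarity(word_embedding(backend, predicted, context),
                    word_embedding(backend, target, context))
}

#' Incremental moving-window predictability metrics for one passage
#'
#' Starting from the beginning of the passage, words `1..i-1` are given to
#' the backend and the prediction state for the target at position `i` is
#' extracted, for every `i` from 2 to the passage length. Entropy is
#' computed from the next-token distribution *before* the target is seen
#' (no information about the target enters it); the target's probability
#' uses the full chain rule over its tokens.
#'
#' @param backend a language-model backend.
#' @param words character vector of the passage's words, in order.
#' @param word_ids optional identifiers, same length as `words`.
#' @param k number of top candidates to retain per position.
#' @param cap_bits surprisal ceiling for zero-probability tokens.
#' @return tibble with one row per non-initial word: `word_id`, `position`,
#'   `word`, `target_probability`, `entropy` (bits), `surprisal` (bits),
#'   `similarity`, `capped`, and a `top_candidates` list column.
#' @export
incremental_metrics <- function(backend, words, word_ids = NULL, k = 10,
                                cap_bits = 30) {
  if (length(words) < 2) stop("a passage needs at least two words")
  word_ids <- word_ids %||% as.character(seq_along(words))
  stopifnot(length(word_ids) == length(words))

  rows <- vector("list", length(words) - 1)
  ctx <- tokenize_word(backend, words[1])
  for (i in 2:length(words)) {
    probs <- softmax_normalize(next_token_logits(backend, ctx))
    H <- shannon_entropy(probs)
    ws <- word_surprisal(backend, ctx, words[i], cap_bits = cap_bits)
    cand <- top_k_candidates(backend, ctx, k)
    sim <- target_prediction_similarity(backend, ctx, cand$word[1], words[i])
    rows[[i - 1]] <- tibble::tibble(
      word_id = word_ids[i], position = i, word = words[i],
      target_probability = ws$probability, entropy = H,
      surprisal = ws$surprisal, similarity = sim, capped = ws$capped,
      top_candidates = list(cand))
    ctx <- c(ctx, tokenize_word(backend, words[i]))
  }
  do.call(rbind, rows)
}

#' Predictability metrics for every passage of a corpus
#'
#' Applies [incremental_metrics()] passage by passage. Passage-initial words
#' have no preceding context and receive no metrics.
#'
#' @param backend a language-model backend.
#' @param corpus a passage corpus (see [as_passage_corpus()]).
#' @param k number of top candidates per position.
#' @param cap_bits surprisal ceiling for zero-probability tokens.
#' @return tibble of prediction states with a `text_id` column.
#' @export
corpus_metrics <- function(backend, corpus, k = 10, cap_bits = 30) {
  corpus <- as_passage_corpus(corpus)
  parts <- lapply(split(corpus, corpus$text_id), function(pass) {
    pass <- pass[order(pass$position), ]
    m <- incremental_metrics(backend, pass$word, pass$word_id, k = k,
                             cap_bits = cap_bits)
    m$text_id <- pass$text_id[1]
    m
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  n_capped <- sum(out$capped)
  if (n_capped > 0) {
    message(n_capped, " word(s) had zero model probability; surprisal capped at ",
            cap_bits, " bits")
  }
  out
}

#' Fraction of targets found among the top-k predictions
#'
#' Matching is case-insensitive on punctuation-stripped forms
#' ([normalize_word()]), the same matcher used to score human cloze
#' responses, so human and model accuracies are comparable like-for-like.
#'
#' @param states prediction states from [incremental_metrics()] or
#'   [corpus_metrics()].
#' @param k prediction window size.
#' @param targets optional target words; defaults to the states' own words.
#' @return accuracy fraction in `[0, 1]`, non-decreasing in `k`.
#' @export
top_k_accuracy <- function(states, k, targets = NULL) {
  if (is.null(states) || nrow(states) == 0) stop("no prediction states")
  targets <- targets %||% states$word
  stopifnot(length(targets) == nrow(states))
  hits <- mapply(function(cand, tgt) {
    normalize_word(tgt) %in% normalize_word(utils::head(cand$word, k))
  }, states$top_candidates, targets)
  mean(hits)
}

#' Flatten prediction states for writing to a delimited file
#'
#' Expands the `top_candidates` list column into `top1..topk` word and
#' probability columns.
#'
#' @param states prediction states.
#' @param k how many candidates to keep; defaults to all retained.
#' @return a plain tibble with no list columns.
#' @export
metrics_to_table <- function(states, k = NULL) {
  k <- k %||% max(vapply(states$top_candidates, nrow, integer(1)))
  flat <- states[setdiff(names(states), "top_candidates")]
  for (j in seq_len(k)) {
    flat[[paste0("top", j)]] <-
      vapply(states$top_candidates, function(cc) cc$word[j], character(1))
    flat[[paste0("top", j, "_p")]] <-
      vapply(states$top_candidates, function(cc) cc$probability[j], numeric(1))
  }
  flat
}
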