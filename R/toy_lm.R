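#' Construct a table-driven toy causal language model
#'
#' A toy LM is an explicit k-th order Markov model over a small vocabulary.
#' It implements the same adapter contract as a transformer backend — it can
#' score the next-token distribution given a context
#' ([next_token_logits()]), tokenize words ([tokenize_word()]) and embed
#' words for similarity ([word_embedding()]) — but because its conditional
#' table is explicit, every entropy and surprisal the pipeline emits can be
#' verified by hand.
#'
#' @param vocabulary character vector of distinct token strings.
#' @param order context length: 0 for a unigram model, 1 for a bigram model,
#'   and so on. Predictions condition on the last `order` tokens.
#' @param conditional_table named list (or matrix with rownames) mapping a
#'   context key — the last `order` tokens pasted with single spaces, `""`
#'   for order 0 — to a probability vector over `vocabulary` (named, or in
#'   vocabulary order). Every row must be non-negative and sum to 1 within
#'   1e-8.
#' @param embeddings numeric matrix with one unit-norm row per vocabulary
#'   token; defaults to one-hot rows, so distinct tokens are orthogonal and
#'   cosine similarities are exactly 0 or 1. See [related_embeddings()] for
#'   constructing "semantically related" pairs at a chosen cosine.
#' @param subword_map optional named list mapping a multi-token word to its
#'   token sequence. Words absent from the map are their own single token.
#'   Multi-token words are scored by the chain rule; passage sampling
#'   requires single-token words.
#' @return an object of class `toy_lm`.
#' @export
#' @examples
#' lm <- toy_lm(c("a", "b", "c"), 1L, list(
#'   a = c(a = 0.5, b = 0.25, c = 0.25),
#'   b = c(a = 0.1, b = 0.2, c = 0.7),
#'   c = c(a = 1/3, b = 1/3, c = 1/3)))
#' softmax_normalize(next_token_logits(lm, "a"))
toy_lm <- function(vocabulary, order, conditional_table, embeddings = NULL,
                   subword_map = NULL) {
  stopifnot(is.character(vocabulary), length(vocabulary) >= 2)
  if (anyDuplicated(vocabulary)) stop("vocabulary tokens must be distinct")
  stopifnot(length(order) == 1, order >= 0, order == round(order))
  V <- length(vocabulary)

  if (is.matrix(conditional_table)) {
    keys <- rownames(conditional_table)
    conditional_table <- stats::setNames(
      lapply(seq_len(nrow(conditional_table)), function(i) conditional_table[i, ]),
      keys)
  }
  if (is.null(names(conditional_table))) {
    stop("conditional_table must be keyed by context")
  }

  probs <- matrix(NA_real_, length(conditional_table), V,
                  dimnames = list(names(conditional_table), vocabulary))
  for (key in names(conditional_table)) {
    ctx <- context_units(key)
    if (length(ctx) != order) {
      stop(sprintf("context '%s' has length %d; the model order is %d",
                   key, length(ctx), order))
    }
    if (order > 0 && !all(ctx %in% vocabulary)) {
      stop(sprintf("context '%s' uses tokens outside the vocabulary", key))
    }
    p <- conditional_table[[key]]
    if (!is.null(names(p))) p <- p[vocabulary]
    p <- as.numeric(p)
    if (length(p) != V || anyNA(p)) {
      stop(sprintf("probability row for context '%s' does not cover the vocabulary", key))
    }
    if (any(p < 0)) stop(sprintf("negative probability in row for context '%s'", key))
    if (abs(sum(p) - 1) > 1e-8) {
      stop(sprintf("probabilities for context '%s' sum to %.10f, not 1", key, sum(p)))
    }
    probs[key, ] <- p
  }

  if (order == 0 && !("" %in% rownames(probs))) {
    stop('an order-0 model needs a single row keyed by ""')
  }
  if (order == 1) {
    missing <- setdiff(vocabulary, rownames(probs))
    if (length(missing)) {
      stop("missing conditional rows for contexts: ", paste(missing, collapse = ", "))
    }
  }

  if (is.null(embeddings)) {
    embeddings <- diag(V)
    rownames(embeddings) <- vocabulary
  }
  stopifnot(is.matrix(embeddings), nrow(embeddings) == V)
  if (is.null(rownames(embeddings))) rownames(embeddings) <- vocabulary
  norms <- sqrt(rowSums(embeddings^2))
  if (any(abs(norms - 1) > 1e-6)) stop("embedding rows must have unit norm")

  if (!is.null(subword_map)) {
    stopifnot(is.list(subword_map))
    if (is.null(names(subword_map))) stop("subword_map must be named by word")
    bad <- vapply(subword_map, function(u) !all(u %in% vocabulary), logical(1))
    if (any(bad)) {
      stop("subword_map entries use tokens outside the vocabulary: ",
           paste(names(subword_map)[bad], collapse = ", "))
    }
  }

  structure(list(vocabulary = vocabulary, order = as.integer(order),
                 probs = probs, embeddings = embeddings,
                 subword_map = subword_map),
            class = "toy_lm")
}

context_units <- function(key) {
  if (identical(key, "")) character(0) else strsplit(key, " ", fixed = TRUE)[[1]]
}

context_key <- function(units, order) {
  if (order == 0) "" else paste(utils::tail(units, order), collapse = " ")
}

#' @export
print.toy_lm <- function(x, ...) {
  cat(sprintf("<toy_lm> order-%d Markov model, %d tokens, %d contexts\n",
              x$order, length(x$vocabulary), nrow(x$probs)))
  invisible(x)
}

#' Language-model adapter contract
#'
#' Four generics define the surface every backend must implement so the
#' metric pipeline stays backend-agnostic: `backend_vocabulary()` returns
#' the token inventory, `tokenize_word()` maps a word to its token sequence,
#' `next_token_logits()` scores the next token given a context (a vector of
#' token strings), and `word_embedding()` returns a fixed-length vector for
#' a word, mean-pooled over its tokens. The toy backend's embeddings are
#' static lookups (the context argument is accepted for contract
#' compatibility); a contextual backend would condition on it.
#'
#' @param backend a language-model backend, e.g. a [toy_lm()].
#' @param word a single word string.
#' @param context character vector of preceding tokens (possibly empty).
#' @return `backend_vocabulary()`: character vector. `tokenize_word()`:
#'   character vector of tokens. `next_token_logits()`: named numeric logit
#'   vector over the vocabulary (`-Inf` marks impossible tokens).
#'   `word_embedding()`: numeric vector.
#' @name lm_adapter
NULL

#' @rdname lm_adapter
#' @export
backend_vocabulary <- function(backend) UseMethod("backend_vocabulary")

#' @rdname lm_adapter
#' @export
backend_vocabulary.toy_lm <- function(backend) backend$vocabulary

#' @rdname lm_adapter
#' @export
tokenize_word <- function(backend, word) UseMethod("tokenize_word")

#' @rdname lm_adapter
#' @export
tokenize_word.toy_lm <- function(backend, word) {
  stopifnot(length(word) == 1)
  units <- backend$subword_map[[word]] %||% word
  if (!all(units %in% backend$vocabulary)) {
    stop(sprintf("word '%s' is out of vocabulary", word))
  }
  units
}

#' @rdname lm_adapter
#' @export
next_token_logits <- function(backend, context) UseMethod("next_token_logits")

#' @rdname lm_adapter
#' @export
next_token_logits.toy_lm <- function(backend, context) {
  key <- context_key(context, backend$order)
  if (!key %in% rownames(backend$probs)) {
    stop(sprintf("unreachable context '%s'", key))
  }
  log(backend$probs[key, ])
}

#' @rdname lm_adapter
#' @export
word_embedding <- function(backend, word, context = character(0)) {
  UseMethod("word_embedding")
}

#' @rdname lm_adapter
#' @export
word_embedding.toy_lm <- function(backend, word, context = character(0)) {
  units <- tokenize_word(backend, word)
  colMeans(backend$embeddings[units, , drop = FALSE])
}

#' One-hot embeddings with designated related pairs
#'
#' Builds a unit-norm embedding matrix in which unrelated tokens are
#' orthogonal (cosine 0) and each listed pair attains an exact chosen
#' cosine: the second member of a pair is rotated toward the first in the
#' plane the two one-hot axes span.
#'
#' @param vocabulary character vector of tokens.
#' @param related_pairs list of length-2 character vectors.
#' @param cosine target cosine for each related pair (default 0.8).
#' @return numeric matrix, one unit-norm row per token.
#' @export
related_embeddings <- function(vocabulary, related_pairs = list(), cosine = 0.8) {
  stopifnot(cosine >= -1, cosine <= 1)
  V <- length(vocabulary)
  base <- diag(V)
  emb <- base
  rownames(emb) <- vocabulary
  for (pair in related_pairs) {
    ia <- match(pair[1], vocabulary)
    ib <- match(pair[2], vocabulary)
    if (anyNA(c(ia, ib))) stop("related pair outside the vocabulary")
    emb[ib, ] <- cosine * emb[ia, ] + sqrt(1 - cosine^2) * base[ib, ]
  }
  emb
}

#' A small structured demonstration language model
#'
#' A deterministic 12-token bigram model whose conditional rows range from
#' strongly peaked (entropy near 0 bits: constraining contexts) to nearly
#' flat (entropy near 3 bits: neutral contexts), so text sampled from it
#' exhibits the full spectrum of entropy and surprisal values — including
#' occasional low-entropy/high-surprisal words, the prediction-error cases.
#' Row `i` puts probability proportional to `exp(-d / conc_i)` on the token
#' `d` steps after `i` in vocabulary order, with concentrations cycling
#' through 0.25, 0.5, 1 and 3: the most constraining contexts give the top
#' word probability ~0.98 (comparable to a strong cloze constraint), so
#' failed strong predictions occur at realistic, non-negligible rates.
#' Three word pairs are embedded at cosine 0.8; all other pairs are
#' orthogonal.
#'
#' @return a [toy_lm()].
#' @export
demo_toy_lm <- function() {
  vocab <- c("the", "a", "cat", "dog", "sat", "ran",
             "on", "under", "mat", "rug", "and", "then")
  V <- length(vocab)
  conc <- rep(c(0.25, 0.5, 1, 3), length.out = V)
  rows <- lapply(seq_len(V), function(i) {
    d <- (seq_len(V) - i - 1) %% V
    p <- exp(-d / conc[i])
    p / sum(p)
  })
  names(rows) <- vocab
  emb <- related_embeddings(vocab,
    list(c("cat", "dog"), c("mat", "rug"), c("on", "under")), cosine = 0.8)
  toy_lm(vocab, 1L, rows, embeddings = emb)
}

#' Read a toy language model from a YAML/JSON spec file
#'
#' The file must contain `vocabulary`, `order` and `conditional` (a map from
#' context key to probability list); `embeddings` (map word -> vector) and
#' `subword_map` are optional.
#'
#' @param path path to a YAML (or JSON, a YAML subset) file.
#' @return a [toy_lm()].
#' @export
read_toy_lm <- function(path) {
  spec <- yaml::read_yaml(path)
  for (field in c("vocabulary", "order", "conditional")) {
    if (is.null(spec[[field]])) stop("toy LM spec is missing '", field, "'")
  }
  vocab <- as.character(unlist(spec$vocabulary))
  conditional <- lapply(spec$conditional, function(p) unlist(p))
  emb <- NULL
  if (!is.null(spec$embeddings)) {
    emb <- do.call(rbind, lapply(spec$embeddings[vocab], unlist))
    rownames(emb) <- vocab
  }
  toy_lm(vocab, as.integer(spec$order), conditional, embeddings = emb,
         subword_map = spec$subword_map)
}
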