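#' Logit transform of a probability
#'
#' `log(p / (1 - p))`. Probabilities of exactly 0 and 1 map to the `-Inf`
#' and `+Inf` sentinels, which are preserved, never clipped: on the logit
#' scale the pile-up of cloze norms at `-Inf` is precisely the signature of
#' the cloze floor (words no respondent produced). Strictly monotone on
#' `(0, 1)`, so order statistics are preserved.
#'
#' @param p numeric vector of probabilities in `[0, 1]`.
#' @return numeric vector of logits (possibly infinite).
#' @export
#' @examples
#' probability_to_logit(c(0, 0.5, 0.9, 1))
probability_to_logit <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  stats::qlogis(p)
}

#' Fraction of words with a cloze probability of exactly zero
#'
#' Measured over word tokens: the share of the norms whose estimate is 0,
#' i.e. words that no respondent produced.
#'
#' @param cloze numeric vector of cloze probabilities, or a norms table
#'   with a `cloze_probability` column.
#' @return fraction in `[0, 1]`.
#' @export
zero_probability_fraction <- function(cloze) {
  if (is.data.frame(cloze)) cloze <- cloze$cloze_probability
  if (!length(cloze)) stop("empty cloze norms")
  if (any(is.na(cloze)) || any(cloze < 0 | cloze > 1)) {
    stop("cloze probabilities must lie in [0, 1]")
  }
  mean(cloze == 0)
}

#' Per-respondent next-word prediction accuracy
#'
#' Scores each respondent's guesses against the actual next words using
#' exact match on normalized forms ([normalize_word()]) — the same matcher
#' as [top_k_accuracy()], so human and model accuracies are like-for-like.
#' Respondents with no scorable guesses are excluded (reported).
#'
#' @param responses tibble with columns `respondent_id`, `guess`, `target`
#'   (e.g. from [simulate_cloze_responses()]).
#' @return object of class `accuracy_summary`: a list with
#'   `per_respondent` (tibble of accuracies), `mean`, `sd`, `max` and
#'   `n_respondents`.
#' @export
human_accuracy_stats <- function(responses) {
  needed <- c("respondent_id", "guess", "target")
  if (!all(needed %in% names(responses))) {
    stop("responses need columns: ", paste(needed, collapse = ", "))
  }
  scorable <- !is.na(responses$guess) & !is.na(responses$target)
  n_excluded <- length(setdiff(unique(responses$respondent_id),
                               unique(responses$respondent_id[scorable])))
  if (n_excluded > 0) {
    message(n_excluded, " respondent(s) with no scorable guesses excluded")
  }
  r <- responses[scorable, ]
  hit <- normalize_word(r$guess) == normalize_word(r$target)
  acc <- tapply(hit, r$respondent_id, mean)
  per <- tibble::tibble(respondent_id = names(acc), accuracy = as.numeric(acc))
  structure(list(per_respondent = per, mean = mean(per$accuracy),
                 sd = stats::sd(per$accuracy), max = max(per$accuracy),
                 n_respondents = nrow(per)),
            class = "accuracy_summary")
}

#' @export
print.accuracy_summary <- function(x, ...) {
  cat(sprintf(
    "<accuracy_summary> %d respondents: mean %.1f%% (sd %.1f%%, max %.1f%%)\n",
    x$n_respondents, 100 * x$mean, 100 * (x$sd %||% NA_real_), 100 * x$max))
  invisible(x)
}

#' Model prediction accuracy as a function of the top-k window
#'
#' Computes [top_k_accuracy()] for `k = 1..k_max` together with the
#' standard error of the mean across grouping units (passages by default;
#' the choice of unit is configurable). Accuracy is non-decreasing in `k`.
#'
#' @param states prediction states from [corpus_metrics()].
#' @param k_max largest prediction window.
#' @param group grouping vector for the SEM (defaults to the states'
#'   `text_id`); with fewer than two groups the SEM is `NA`.
#' @return tibble with columns `k`, `accuracy`, `sem`.
#' @export
model_accuracy_curve <- function(states, k_max = 10, group = NULL) {
  if (is.null(states) || nrow(states) == 0) stop("no prediction states")
  if (is.null(group) && "text_id" %in% names(states)) group <- states$text_id
  ks <- seq_len(k_max)
  acc <- vapply(ks, function(k) top_k_accuracy(states, k), numeric(1))
  sem <- rep(NA_real_, k_max)
  if (!is.null(group) && length(unique(group)) >= 2) {
    for (k in ks) {
      by_group <- vapply(split(seq_len(nrow(states)), group), function(ix) {
        top_k_accuracy(states[ix, ], k)
      }, numeric(1))
      sem[k] <- stats::sd(by_group) / sqrt(length(by_group))
    }
  }
  tibble::tibble(k = ks, accuracy = acc, sem = sem)
}
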