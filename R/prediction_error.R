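#' Equal-frequency discretization of a continuous variable
#'
#' Cuts a vector at its sample quantiles so that the bins hold (near-)
#' equal counts. Boundaries use the default (type 7) quantile definition;
#' intervals are right-closed, so a value landing exactly on a boundary is
#' assigned to the lower bin — with heavy ties at a boundary the counts
#' become unequal, deterministically. Tied quantile boundaries are
#' collapsed (reported), reducing the number of bins.
#'
#' @param values numeric vector, non-missing and non-constant.
#' @param n_bins number of bins (>= 2); default 3 (tertiles).
#' @param ids optional identifiers parallel to `values` (e.g. `word_id`),
#'   carried along so bin labels can be broadcast to observations.
#' @param variable name of the binned variable, for display.
#' @return object of class `freq_bins`: a list with `variable`, `n_bins`,
#'   `boundaries`, `bin` (ordered factor `bin1 < bin2 < ...`) and `ids`.
#' @export
#' @examples
#' b <- equal_frequency_bins(1:9, 3)
#' table(b$bin)   # 3 3 3
equal_frequency_bins <- function(values, n_bins = 3, ids = NULL,
                                 variable = "value") {
  stopifnot(n_bins >= 2)
  if (anyNA(values)) stop("values must be non-missing")
  if (length(unique(values)) < 2) stop("cannot bin a constant vector")
  if (!is.null(ids)) stopifnot(length(ids) == length(values))
  qs <- stats::quantile(values, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE, type = 7)
  breaks <- unique(qs)
  if (length(breaks) - 1 < n_bins) {
    message("tied quantile boundaries collapsed ", n_bins, " bins into ",
            length(breaks) - 1)
  }
  idx <- cut(values, breaks = breaks, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  labels <- paste0("bin", seq_len(length(breaks) - 1))
  structure(list(variable = variable, n_bins = length(breaks) - 1L,
                 boundaries = breaks,
                 bin = factor(labels[idx], levels = labels, ordered = TRUE),
                 ids = ids),
            class = "freq_bins")
}

#' @export
print.freq_bins <- function(x, ...) {
  cat(sprintf("<freq_bins> %s in %d bins; counts: %s\n", x$variable,
              x$n_bins, paste(table(x$bin), collapse = "/")))
  invisible(x)
}

#' Select the low-entropy/high-surprisal (prediction error) subset
#'
#' Given word-level bin assignments of entropy and surprisal, keeps the
#' observations whose word falls in the lowest entropy bin *and* the
#' highest surprisal bin: the cases in which the model made a strong
#' prediction that turned out wrong. Bins must be computed on word-level
#' metric values (one value per word), then broadcast to observations via
#' the bin `ids` — on a complete design the subset row count factorizes as
#' participants x selected tokens.
#'
#' @param table observation table.
#' @param entropy_bins,surprisal_bins `freq_bins` objects carrying
#'   word-level `ids`.
#' @return the subset of `table`, with attributes `n_tokens` and
#'   `n_participants`. Empty subsets are an error.
#' @export
select_prediction_error_subset <- function(table, entropy_bins,
                                           surprisal_bins) {
  stopifnot(inherits(entropy_bins, "freq_bins"),
            inherits(surprisal_bins, "freq_bins"))
  if (is.null(entropy_bins$ids) || is.null(surprisal_bins$ids)) {
    stop("bin assignments must carry word ids")
  }
  lev_e <- levels(entropy_bins$bin)
  lev_s <- levels(surprisal_bins$bin)
  low_entropy <- entropy_bins$ids[entropy_bins$bin == lev_e[1]]
  high_surprisal <- surprisal_bins$ids[surprisal_bins$bin == lev_s[length(lev_s)]]
  sel <- intersect(low_entropy, high_surprisal)
  out <- table[table$word_id %in% sel, ]
  if (!nrow(out)) {
    stop("no observations fall in the low-entropy/high-surprisal cell")
  }
  attr(out, "n_tokens") <- length(intersect(sel, unique(table$word_id)))
  attr(out, "n_participants") <- length(unique(out$participant_id))
  out
}

#' Bin word-level metrics and select the prediction-error subset
#'
#' Convenience wrapper: computes equal-frequency bins of entropy and
#' surprisal on the word-level metric values (one per word, not per
#' observation) and applies [select_prediction_error_subset()].
#'
#' @param table observation table.
#' @param metrics word-level prediction states (`word_id`, `entropy`,
#'   `surprisal`).
#' @param n_bins number of equal-frequency bins (default 3).
#' @return the subset, as from [select_prediction_error_subset()].
#' @export
prediction_error_subset <- function(table, metrics, n_bins = 3) {
  m <- metrics[!duplicated(metrics$word_id), ]
  eb <- equal_frequency_bins(m$entropy, n_bins, ids = m$word_id,
                             variable = "entropy")
  sb <- equal_frequency_bins(m$surprisal, n_bins, ids = m$word_id,
                             variable = "surprisal")
  select_prediction_error_subset(table, eb, sb)
}

#' Target-prediction similarity models on the prediction-error subset
#'
#' Fits, per outcome, `DV ~ similarity + log_frequency + length_letters +
#' word_number_in_sentence` with the usual crossed random intercepts, via
#' [fit_mixed()]. Run on the low-entropy/high-surprisal subset this asks:
#' when a strong prediction fails, is the cost smaller if the actual word
#' is semantically close to the predicted one?
#'
#' @param subset observation table (normally the prediction-error subset).
#' @param outcomes outcomes to fit.
#' @param ... passed to [fit_mixed()].
#' @return named list of `predread_fit` objects.
#' @export
similarity_effect_fit <- function(subset,
                                  outcomes = c("first_fixation", "gaze",
                                               "total_time", "regression"),
                                  ...) {
  fits <- lapply(outcomes, function(o) {
    fit_mixed(model_spec(o, fixed = c("similarity", "log_frequency",
                                      "length_letters",
                                      "word_number_in_sentence")),
              subset, ...)
  })
  names(fits) <- outcomes
  fits
}
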