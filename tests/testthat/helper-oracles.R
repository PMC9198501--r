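# brute-force oracles computed straight from the toy model's conditional
# table, independent of the metric pipeline

oracle_entropy_bits <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p)) / log(2)
}

# per-position probability/entropy/surprisal for a word sequence under an
# order-1 toy model (reads lm$probs directly)
oracle_bigram_metrics <- function(lm, words) {
  stopifnot(lm$order == 1)
  n <- length(words)
  out <- data.frame(position = 2:n, p = NA_real_, H = NA_real_, S = NA_real_)
  for (i in 2:n) {
    row <- lm$probs[words[i - 1], ]
    out$H[i - 1] <- oracle_entropy_bits(row)
    out$p[i - 1] <- row[[words[i]]]
    out$S[i - 1] <- -log2(row[[words[i]]])
  }
  out
}
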