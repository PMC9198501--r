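---
title: "Predictability metrics and eye movements: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predictability metrics and eye movements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(predread)
```

## The scientific question

Skilled readers move their eyes through text in a way that tracks how
predictable each upcoming word is: predictable words are skipped more often
and fixated more briefly. `predread` implements a pipeline for studying this
with a causal language model as the source of predictability, separating two
quantities that cloze norms conflate:

* **entropy** `H = -sum(p_i * log2(p_i))` of the model's next-word
  distribution *before* the target word is seen — a property of the context
  alone, so any effect of it on eye movements must reflect prediction, not
  the ease of integrating the word once seen;
* **surprisal** `S = -log2(p(target))` *at* the target word, which may
  reflect prediction and/or integration.

A third metric, **target-prediction similarity**, is the cosine between
embeddings of the model's top predicted word and the word actually printed.
On the subset of words where the model made a strong prediction that turned
out wrong (low entropy, high surprisal — the *prediction error* cases), it
asks whether a semantically close miss is cheaper than a distant one.

## The moving window and the units

Metrics are computed with an incremental moving window
(`incremental_metrics()`, `corpus_metrics()`): words `1..i-1` are given to
the backend and the state for the word at position `i` is extracted, from
the second word of each passage onward. Passage-initial words have no
preceding context and carry no metrics; they are excluded from the analysis
table, and the merge treats them as legitimately metric-free.

All information quantities are reported in **bits**; the log2/loge
conversion is exact, so nothing hinges on it. A word's probability is the
chain-rule product over its tokens, which makes word surprisal additive
over tokens. Entropy is computed over the next-token distribution at the
target's first position — the distribution the model actually holds before
any part of the target is revealed; the asymmetry with the chain-rule
target probability is deliberate. A token probability of exactly zero
would yield infinite surprisal; such cases are capped at a configurable
ceiling (default 30 bits, roughly one in a billion) with `p = 2^-30`
emitted so the surprisal/probability identity survives, and the occurrence
is counted and reported.

## The backend contract and the toy model

Every metric goes through four generics — `backend_vocabulary()`,
`tokenize_word()`, `next_token_logits()`, `word_embedding()` — so the
language model is pluggable. The package ships one backend, `toy_lm()`: an
explicit k-th order Markov model whose conditional table *is* the ground
truth. This is what makes the test suite meaningful: every entropy and
surprisal the pipeline emits is compared against brute-force computation
from the table, at 1e-9.

Toy embeddings are static unit vectors (one-hot by default), with
"semantic relatedness" constructed exactly: `related_embeddings()` places
chosen pairs at a chosen cosine (0.8 by default) and leaves everything else
orthogonal. A transformer backend would supply contextual embeddings
through the same generic; which hidden layer to pool is a genuinely open
choice there, which is why the embedding call is isolated behind one
function. Likewise `top_k_candidates()` ranks next *tokens* — identical to
next words for the toy backend — and is the single place where a subword
backend's word decoding would live; that decoding is the main reproduction
risk when comparing against published top-k accuracies, and it is
deliberately quarantined.

`demo_toy_lm()` is the standard fixture: 12 tokens, bigram rows ranging
from strongly constraining (top-word probability ~0.98, entropy near 0
bits) to neutral (entropy ~2.9 bits). The constraining rows are strong but
not deterministic on purpose: real constraining contexts have cloze values
around 0.9, not 0.999, and the low-entropy/high-surprisal cell of the
analysis is only populated if strong predictions occasionally fail.

## The synthetic gaze generator

`simulate_gaze()` is the generative mirror of the analysis models. For
each participant x word cell it builds one linear predictor per outcome,

```
intercept + b_H*H + b_S*S + b_HS*H*S + b_f*log10_freq + b_l*length
          + b_w*word_number + b_sim*similarity
          + u_participant + u_item + u_text
```

and draws skipping and regression indicators through a logistic link and
the three reading-time measures log-normally. Random intercepts are
i.i.d. normal, one shared draw per grouping level across all outcomes.
Skipped words carry absent (not zero) durations, so the skipped/fixated
split of the observation table is structural.

Two design points deserve explanation:

* **Duration ordering.** First fixation <= gaze <= total is a definitional
  constraint of the eye-movement record (they are nested sums of the same
  fixations). The generator shares a single residual draw across the three
  log-duration models and spaces their intercepts (log 225, 250, 300 ms),
  so each outcome is *exactly* log-normal under its own linear predictor
  while the ordering holds by construction (violations under user-supplied
  coefficient sets are clamped and counted). Treating the three residuals
  as perfectly coupled is the simplest structure consistent with nesting;
  the analysis models never exploit it.
* **Five coefficient vectors, four named models.** The generator carries
  skip, first-fixation, gaze, total-time and regression coefficients; the
  total-time vector exists because the record requires `total >= gaze`,
  even though the headline parameter-recovery study concerns the skip,
  first-fixation, gaze and regression formulas.

Default coefficients are stated in raw units (per bit, per log10
frequency, per letter, per sentence position): entropy odds ratio on
skipping 0.93/bit (constraining contexts invite skipping), surprisal
+2%/bit on gaze and +5%/bit on total time, regression odds ratios 1.08/bit
(entropy) and 1.25/bit (surprisal), small negative entropy-by-surprisal
interactions on skipping and first fixations, zero interactions elsewhere,
and zero similarity effects unless asked for. No published study reports
effects in generative units, so these are fixed once as plausible
magnitudes for reading behaviour and are configuration, not calibration:
the test suite recovers whatever is configured. Random-intercept standard
deviations default to 0.3 (participant), 0.2 (item), 0.1 (text) and the
log-duration residual to 0.25 — a ~28% coefficient of variation, in the
range of empirical fixation-duration variability. The default 84
participants matches the scale of the eye-tracking corpora this design
emulates.

`simulate_cloze()` draws the norm for each word as the fraction of
`n_respondents` guesses (from the true conditional distribution) that
match the actual word, sampled as the equivalent binomial count. With few
respondents, low-probability words are estimated at exactly zero with
substantial probability — the *cloze floor*: a 2%-probability word is
floored at zero two times in three with 20 respondents. This is the
phenomenon that makes model-based probabilities preferable in the low
range, and the logit-scale comparison (`probability_to_logit()`, which
preserves the `-Inf` sentinel rather than clipping it) makes the pile-up
visible. `simulate_cloze_responses()` is the long-format companion used to
score per-respondent accuracy with the same normalized exact-match rule
(`normalize_word()`: lower-case, punctuation stripped) as model top-k
accuracy, so the human/model comparison is like-for-like.

What the generator does *not* emulate: saccade planning, parafoveal
preview, landing positions, refixation dynamics, or any dependence of
skipping on upcoming-word preview beyond what the covariates carry. A
passing suite therefore certifies the statistical pipeline — metrics,
merging, model fitting, subset selection — not the cognitive realism of
the generator.

## The mixed models

`fit_mixed()` estimates, per outcome,

```
DV ~ entropy * surprisal + log_frequency + length_letters
   + word_number_in_sentence + (1|participant_id) + (1|word_id) + (1|text_id)
```

by maximum likelihood (not REML, so fixed effects are comparable across
models), with a logistic link and Laplace approximation for the binary
outcomes. Duration outcomes are modelled on the natural-log scale — a
Box-Cox profile (`choose_transform()`) decides between log and identity,
choosing log when the profile-maximizing lambda lies in [-0.5, 0.5] — and
back-transformed by exponentiation for presentation. Duration models use
fixated rows only. Predictors enter unscaled so coefficients read in
natural units (an odds ratio per bit); a centering option is unnecessary
for the default continuous predictors but collinearity is screened:
`vif()` implements `1/(1 - R_j^2)` from regressing each main-effect
predictor on the others (infinite, not an error, under perfect
collinearity) and `fit_mixed()` warns at VIF >= 2. Interaction columns are
excluded from the screen — a raw `H x S` column is always correlated with
its main effects, and the screen is meant to detect redundancy among the
measured covariates, not that arithmetic fact.

Inference is by type-III Wald chi-squares (`type3_wald()`, computed under
sum-to-zero-compatible contrasts; with continuous predictors the coding is
moot), so for single-df terms the chi-square equals the squared Wald
statistic — an identity the tests assert on every fit, along with
`OR = exp(beta)`. Convergence and singularity are flagged honestly on the
returned object rather than silently accepted; rank-deficient designs fail
before fitting with the aliased columns named.

Two numerical choices matter for reproducibility:

* The optimizer is bobyqa with the expensive derivative-based convergence
  check disabled (the fits are deterministic given data; the flag reflects
  the optimizer's own status).
* The zero-variance degenerate limit is verified through
  `fixed_effects_at_zero_variance()`, which pins all three random-intercept
  variances at zero via the modular lme4 interface and must reproduce an
  ordinary `glm()`/`lm()` on the same rows to ~1e-9. Fitting data
  *generated* with zero variances cannot test this identity sharply: the
  variance-component MLE at a boundary truth is positive with probability
  about one half per component, which moves fitted fixed effects away from
  the single-level oracle by sampling noise, not by implementation error.

## Prediction-error subset

`equal_frequency_bins()` cuts a variable at its sample quantiles (type 7,
right-closed intervals, so boundary ties fall to the lower bin —
deterministic and permutation-invariant; tied boundaries collapse with a
message). Bins are computed on the *word-level* metric values and broadcast
to observations, which is what makes the subset factorize as participants
x tokens on a complete design. The default is tertiles (configurable 2-5):
with tertiles the low-entropy/high-surprisal cell is genuinely "strong
prediction, failed", and on real corpus data the published subset size is
the natural empirical calibration target for the bin count.
`similarity_effect_fit()` then fits
`DV ~ similarity + log_frequency + length_letters + word_number_in_sentence`
with the same random-effects structure on that subset.

A small-world caveat: with a 12-word vocabulary the cell contains few word
*types*, and a similarity model on a subset with fewer distinct tokens than
fixed-effect columns is rank-deficient (reported as such, with the aliased
columns named). The shipped tests and the acceptance run therefore use
corpora of several hundred words, which keep 20+ tokens in the cell across
seeds.

## Problem sizes and what is tested where

The test suite exercises every module against oracles: identities at 1e-9,
brute-force metric equivalence over whole corpora, conservation laws for
the merge and the subset, the mixed-model contracts above, a
Kolmogorov-Smirnov check that type-III p-values are uniform under a null
word-level covariate (200 small replicates), and a parameter-recovery
study: 20 replicates of 100 participants x 300 words in which each nonzero
generative coefficient of the skip, first-fixation, gaze and regression
models must land within 2 standard errors in at least 90% of replicates,
while null terms exceed |z| = 2 at roughly the nominal rate. The recovery
study estimates its binary models with the joint-Laplace (PIRLS, `nAGQ =
0`) variant of the logistic mixed model, which is several times faster
than the default full-Laplace fit at this size; `fit_mixed()` defaults to
Laplace.

The acceptance script (`scripts/acceptance.R`) runs the pipeline at 10
passages x 70 words, 60 readers, 40 cloze respondents per word — sizes at
which every stage, including the prediction-error cell, is well populated
across seeds.

## Applying the pipeline to real data

The loaders (`load_passages()`, `load_eye_movement_report()`,
`load_cloze_norms()`, `load_frequency_table()`) default to the column
dialect of the Provo-style interest-area export and are fully remappable
via `column_map` arguments; unknown extra columns are ignored. Rows
violating the duration-ordering invariants are dropped and counted, words
missing from the frequency table are kept through the merge with `NA`
log-frequency and dropped only at fit time (imputing a frequency would
distort that covariate), and type counts use the configurable
normalization — published token/type totals depend on tokenization choices
(case, punctuation, numerals) that corpora rarely state, so the reader's
normalization is the tunable piece. Reproducing published
transformer-based numbers additionally requires the original model's
weights and a word-decoding convention for top-k candidates; both live
behind the backend adapter.

## Known limitations

* One backend (the toy Markov model) is implemented; transformer backends
  plug into the adapter but are not bundled.
* The generator's effect sizes are conventions, not estimates; nothing in
  the package claims empirical magnitudes for real readers.
* Regressions are simulated for all words (skipped words can be regressed
  into); analyses of regression restricted to fixated words are a
  filtering choice left to the user.
* The similarity metric on the toy backend is context-independent by
  construction; contextual similarity is a property of richer backends.
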