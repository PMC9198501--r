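#' Box-Cox check of the duration transform
#'
#' Profiles the Box-Cox likelihood of a positive duration vector over a
#' lambda grid and decides between the log and identity transforms: log is
#' chosen when the profile-maximizing lambda falls in `[-0.5, 0.5]` (the
#' log transform is the lambda = 0 member of the family), identity
#' otherwise.
#'
#' @param durations positive durations in ms (NAs ignored).
#' @param lambda_grid grid over which the profile likelihood is evaluated.
#' @return list with `lambda` (the profile maximizer) and `transform`
#'   (`"log"` or `"identity"`).
#' @export
choose_transform <- function(durations, lambda_grid = seq(-2, 2, 0.01)) {
  x <- durations[!is.na(durations)]
  if (!length(x)) stop("no durations supplied")
  if (any(x <= 0)) stop("durations must be positive")
  if (stats::sd(x) == 0) stop("constant durations: the transform is undefined")
  prof <- MASS::boxcox(x ~ 1, lambda = lambda_grid, plotit = FALSE)
  lambda <- prof$x[which.max(prof$y)]
  list(lambda = lambda,
       transform = if (abs(lambda) <= 0.5) "log" else "identity")
}

#' Specify a mixed-effects analysis of one eye-movement outcome
#'
#' Encodes the model formulas of the analysis: a binary-logit model for
#' skipping and regressions-in, gaussian models on the natural-log scale
#' for the three reading-time measures, each with the entropy-by-surprisal
#' interaction plus frequency, length and sentence-position covariates and
#' crossed random intercepts for participants, word items and texts.
#'
#' @param outcome one of `"skip"`, `"first_fixation"`, `"gaze"`,
#'   `"total_time"`, `"regression"`.
#' @param fixed character vector of fixed-effect terms (R formula syntax);
#'   the default is `entropy * surprisal + log_frequency + length_letters +
#'   word_number_in_sentence`. Interaction terms may only involve declared
#'   main effects.
#' @param grouping random-intercept grouping columns.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(outcome = c("skip", "first_fixation", "gaze",
                                   "total_time", "regression"),
                       fixed = NULL,
                       grouping = c("participant_id", "word_id", "text_id")) {
  outcome <- match.arg(outcome)
  fixed <- fixed %||% c("entropy * surprisal", "log_frequency",
                        "length_letters", "word_number_in_sentence")
  pure_int <- grepl(":", fixed, fixed = TRUE)
  mains <- if (all(pure_int)) character(0)
           else all.vars(stats::reformulate(fixed[!pure_int]))
  for (term in fixed[pure_int]) {
    comps <- trimws(strsplit(term, ":", fixed = TRUE)[[1]])
    if (!all(comps %in% mains)) {
      stop("interaction '", term, "' involves undeclared main effects")
    }
  }
  family <- if (outcome %in% c("skip", "regression")) "binomial" else "gaussian_log"
  structure(list(outcome = outcome, fixed = fixed, grouping = grouping,
                 family = family),
            class = "model_spec")
}

outcome_lhs <- function(outcome) {
  switch(outcome,
         skip = "skipped",
         regression = "regression_in",
         first_fixation = "log(first_fixation_ms)",
         gaze = "log(gaze_ms)",
         total_time = "log(total_ms)")
}

outcome_column <- function(outcome) {
  switch(outcome,
         skip = "skipped",
         regression = "regression_in",
         first_fixation = "first_fixation_ms",
         gaze = "gaze_ms",
         total_time = "total_ms")
}

prepare_mixed_data <- function(spec, table) {
  dat <- tibble::as_tibble(table)
  binary <- spec$family == "binomial"
  ycol <- outcome_column(spec$outcome)
  if (!binary) {
    dat <- dat[!dat$skipped & !is.na(dat[[ycol]]), ]
  }
  covars <- all.vars(stats::reformulate(spec$fixed))
  need <- unique(c(covars, spec$grouping, ycol))
  missing_cols <- setdiff(need, names(dat))
  if (length(missing_cols)) {
    stop("observation table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  keep <- stats::complete.cases(dat[need])
  if (any(!keep)) {
    message(sum(!keep), " row(s) with missing covariates dropped from the ",
            spec$outcome, " fit")
  }
  dat <- dat[keep, ]
  if (binary) dat[[ycol]] <- as.integer(dat[[ycol]])
  for (g in spec$grouping) dat[[g]] <- factor(dat[[g]])

  X <- stats::model.matrix(stats::reformulate(spec$fixed), dat)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    aliased <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient fixed-effect design; aliased terms: ",
         paste(aliased, collapse = ", "))
  }

  rhs <- paste(c(spec$fixed, sprintf("(1 | %s)", spec$grouping)),
               collapse = " + ")
  fml <- stats::as.formula(paste(outcome_lhs(spec$outcome), "~", rhs))
  list(dat = dat, fml = fml, covars = covars, binary = binary)
}

#' Fit a crossed random-intercept mixed model to the observation table
#'
#' Binary outcomes (skipping, regressions) are fit with a logistic mixed
#' model (Laplace approximation); reading-time outcomes are fit on the
#' natural-log scale by maximum likelihood (not REML, so fixed-effect
#' comparisons across models are coherent). Duration models use fixated
#' rows only; rows with missing covariates (e.g. words absent from the
#' frequency table) are dropped and counted. Predictors enter unscaled, in
#' their raw units (bits, log10 frequency, letters, sentence position).
#' The returned fit carries type-III Wald chi-squares, odds ratios for
#' binary fits, variance components, a collinearity screen (max VIF over
#' the main-effect predictors; a warning is raised at VIF >= 2) and honest
#' convergence/singularity flags.
#'
#' @param spec a [model_spec()].
#' @param table observation table from [merge_observations()].
#' @param nAGQ integration setting passed to [lme4::glmer()] for binary
#'   outcomes (1 = Laplace).
#' @param check_vif raise a warning when the maximum VIF is 2 or more.
#' @return object of class `predread_fit`.
#' @export
fit_mixed <- function(spec, table, nAGQ = 1L, check_vif = TRUE) {
  stopifnot(inherits(spec, "model_spec"))
  prep <- prepare_mixed_data(spec, table)
  dat <- prep$dat
  fml <- prep$fml
  covars <- prep$covars
  binary <- prep$binary

  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  if (binary) {
    model <- lme4::glmer(fml, data = dat, family = stats::binomial(),
                         nAGQ = nAGQ,
                         control = lme4::glmerControl(optimizer = "bobyqa",
                                                      calc.derivs = FALSE))
  } else {
    model <- lme4::lmer(fml, data = dat, REML = FALSE,
                        control = lme4::lmerControl(optimizer = "bobyqa",
                                                    calc.derivs = FALSE))
  }

  conv_msgs <- model@optinfo$conv$lme4$messages
  converged <- (model@optinfo$conv$opt == 0) &&
    (is.null(conv_msgs) || length(conv_msgs) == 0)
  singular <- lme4::isSingular(model)

  co <- summary(model)$coefficients
  coefs <- tibble::tibble(
    term = rownames(co),
    estimate = co[, 1],
    se = co[, 2],
    statistic = co[, 3],
    p_value = if (binary) co[, 4] else NA_real_,
    odds_ratio = if (binary) exp(co[, 1]) else NA_real_)

  an <- car::Anova(model, type = 3)
  pcol <- grep("^Pr", names(an), value = TRUE)
  anova_tbl <- tibble::tibble(term = rownames(an), chisq = an[["Chisq"]],
                              df = an[["Df"]], p_value = an[[pcol]])

  vc <- as.data.frame(lme4::VarCorr(model))
  varcomp <- tibble::tibble(group = vc$grp, variance = vc$vcov, sd = vc$sdcor)

  vif_tbl <- vif(dat, covars)
  max_vif <- max(vif_tbl$vif)
  if (check_vif && max_vif >= 2) {
    warning(sprintf("maximum VIF %.2f >= 2: the %s model may suffer from collinearity",
                    max_vif, spec$outcome))
  }

  structure(list(spec = spec, formula = fml, n = nrow(dat),
                 coefficients = coefs, anova = anova_tbl, varcomp = varcomp,
                 vif = vif_tbl, max_vif = max_vif, converged = converged,
                 singular = singular, family = spec$family, model = model),
            class = "predread_fit")
}

#' @export
print.predread_fit <- function(x, ...) {
  cat(sprintf("<predread_fit> %s (%s), n = %d%s%s\n", x$spec$outcome,
              x$family, x$n,
              if (x$converged) "" else " [NOT CONVERGED]",
              if (x$singular) " [singular]" else ""))
  print(x$coefficients)
  cat("Type-III Wald tests:\n")
  print(x$anova)
  invisible(x)
}

#' Fixed effects of the mixed model in its zero-variance limit
#'
#' Evaluates the mixed-model machinery with every random-intercept
#' variance pinned at zero (via lme4's modular interface) and returns the
#' resulting fixed effects. In this degenerate limit the model reduces
#' exactly to a single-level regression, so these coefficients must agree
#' with an ordinary `glm()`/`lm()` on the same rows — a plumbing
#' diagnostic for the formula construction, row filtering and link choice
#' shared with [fit_mixed()].
#'
#' @param spec a [model_spec()].
#' @param table observation table.
#' @return named numeric vector of fixed-effect coefficients.
#' @export
fixed_effects_at_zero_variance <- function(spec, table) {
  stopifnot(inherits(spec, "model_spec"))
  prep <- prepare_mixed_data(spec, table)
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)
  theta0 <- rep(0, length(spec$grouping))
  if (prep$binary) {
    parts <- lme4::glFormula(prep$fml, data = prep$dat,
                             family = stats::binomial())
    devfun <- do.call(lme4::mkGlmerDevfun, parts)
    devfun(theta0)
  } else {
    parts <- lme4::lFormula(prep$fml, data = prep$dat, REML = FALSE)
    devfun <- do.call(lme4::mkLmerDevfun, parts)
    devfun(theta0)
  }
  beta <- environment(devfun)$pp$beta(1)
  stats::setNames(beta, colnames(parts$X))
}

#' Type-III Wald chi-square tests for a mixed-model fit
#'
#' Per-factor Wald chi-squares marginal to all other terms
#' (sum-to-zero-compatible parameterization; all default predictors are
#' continuous, so the coding only matters for factor covariates). For a
#' single-df term the chi-square equals the squared Wald statistic of its
#' coefficient.
#'
#' @param fit a `predread_fit`.
#' @return tibble with columns `term`, `chisq`, `df`, `p_value`.
#' @export
type3_wald <- function(fit) {
  stopifnot(inherits(fit, "predread_fit"))
  if (!fit$converged) {
    stop("type-III tests are only reported for converged fits")
  }
  fit$anova
}

#' Variance inflation factors of a set of predictors
#'
#' `VIF_j = 1 / (1 - R_j^2)` where `R_j^2` comes from regressing predictor
#' `j` on all the others. Perfectly collinear predictors yield `Inf`, not
#' an error.
#'
#' @param data data frame holding the predictors.
#' @param terms character vector of at least two predictor column names.
#' @return tibble with columns `term` and `vif`.
#' @export
vif <- function(data, terms) {
  if (length(terms) < 2) stop("need at least two predictors for a VIF")
  missing_cols <- setdiff(terms, names(data))
  if (length(missing_cols)) {
    stop("predictors not found: ", paste(missing_cols, collapse = ", "))
  }
  X <- as.data.frame(lapply(as.data.frame(data)[terms], as.numeric))
  out <- vapply(seq_along(terms), function(j) {
    fit <- stats::lm(stats::reformulate(terms[-j], response = terms[j]),
                     data = X)
    r2 <- suppressWarnings(summary(fit)$r.squared)  # perfect fits give Inf
    if (r2 > 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  tibble::tibble(term = terms, vif = out)
}

#' Flatten a fit into a one-row-per-term summary table
#'
#' Joins the coefficient table with the type-III chi-squares for export.
#'
#' @param fit a `predread_fit`.
#' @return tibble.
#' @export
fit_summary_table <- function(fit) {
  stopifnot(inherits(fit, "predread_fit"))
  out <- fit$coefficients
  an <- fit$anova
  ix <- match(out$term, an$term)
  out$chisq <- an$chisq[ix]
  out$chisq_df <- an$df[ix]
  out$chisq_p <- an$p_value[ix]
  out$outcome <- fit$spec$outcome
  out$n <- fit$n
  out$converged <- fit$converged
  out
}
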