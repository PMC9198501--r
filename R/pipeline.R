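#' Default pipeline configuration
#'
#' A single configuration list drives the whole pipeline; there are no
#' hidden defaults outside this schema. Fields:
#' \describe{
#'   \item{seed}{integer master seed; stage seeds are derived from it.}
#'   \item{outdir}{output directory for tables and the run manifest.}
#'   \item{backend}{`list(path = NULL)`: a [read_toy_lm()] spec file, or
#'     `NULL` for [demo_toy_lm()].}
#'   \item{corpus}{`mode = "simulate"` with `n_passages`/`length`, or
#'     `mode = "load"` with `path`/`column_map`.}
#'   \item{metrics}{`k` (top candidates retained), `cap_bits`.}
#'   \item{cloze}{`mode = "simulate"` with `n_respondents`, `mode = "load"`
#'     with `path`/`column_map`, or `mode = "off"`.}
#'   \item{gaze}{`mode = "simulate"` with `n_participants` and optional
#'     `beta`/`sd_*` overrides, or `mode = "load"` with
#'     `path`/`column_map`.}
#'   \item{frequency}{`path`/`column_map` of a frequency table, or `NULL`
#'     to derive one from the corpus ([synthetic_frequency_table()]).}
#'   \item{models}{`outcomes` to fit.}
#'   \item{prederror}{`n_bins` and `outcomes` for the similarity models.}
#'   \item{stages}{which optional stages to run; the trunk stages
#'     (corpus, metrics, gaze, merge) always run, the leaf stages
#'     (cloze, validation, models, prederror) can be toggled off.}
#' }
#'
#' @param outdir output directory.
#' @param seed master seed.
#' @return configuration list.
#' @export
default_pipeline_config <- function(outdir = tempfile("predread_run_"),
                                    seed = 1L) {
  list(
    seed = as.integer(seed),
    outdir = outdir,
    backend = list(path = NULL),
    corpus = list(mode = "simulate", n_passages = 4L, length = 50L,
                  path = NULL, column_map = NULL),
    metrics = list(k = 10L, cap_bits = 30),
    cloze = list(mode = "simulate", n_respondents = 40L, path = NULL,
                 column_map = NULL),
    gaze = list(mode = "simulate", n_participants = 20L, path = NULL,
                column_map = NULL, beta = NULL),
    frequency = list(path = NULL, column_map = NULL),
    models = list(outcomes = c("skip", "first_fixation", "gaze",
                               "total_time", "regression")),
    prederror = list(n_bins = 3L, outcomes = c("gaze", "total_time")),
    stages = c("cloze", "validation", "models", "prederror"))
}

merge_config <- function(user) {
  cfg <- default_pipeline_config()
  for (nm in names(user)) {
    if (is.list(cfg[[nm]]) && is.list(user[[nm]])) {
      cfg[[nm]] <- utils::modifyList(cfg[[nm]], user[[nm]])
    } else {
      cfg[[nm]] <- user[[nm]]
    }
  }
  cfg
}

pipeline_error <- function(stage, parent_message) {
  cond <- structure(
    list(message = sprintf("stage '%s' failed: %s", stage, parent_message),
         call = NULL),
    class = c("pipeline_error", "error", "condition"))
  attr(cond, "stage") <- stage
  stop(cond)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order — corpus, metrics, cloze, gaze,
#' merge, validation, mixed models, prediction-error analysis — logging
#' row counts per stage, writing every table to `outdir` and emitting a
#' JSON run manifest (seeds, row counts, output md5 hashes, package
#' version). Re-running with the same configuration reproduces identical
#' outputs. A stage failure halts the run with a condition of class
#' `pipeline_error` carrying the stage name.
#'
#' @param config configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML file with the same schema. Partial configurations are
#'   merged into the defaults.
#' @return the manifest list, invisibly. Side effects: tables and
#'   `manifest.json` under `config$outdir`.
#' @export
run_pipeline <- function(config = default_pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  note <- function(...) message("[predread] ", ...)
  manifest <- list(seed = cfg$seed,
                   package_version = as.character(utils::packageVersion("predread")),
                   stages = list())
  outputs <- character(0)
  emit <- function(x, name) {
    path <- file.path(cfg$outdir, name)
    write_table_utf8(x, path)
    outputs[[name]] <<- path
    path
  }
  record <- function(stage, rows, extra = list()) {
    manifest$stages[[stage]] <<- c(list(rows = rows), extra)
    note(stage, ": ", rows, " rows")
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      if (inherits(e, "pipeline_error")) stop(e)
      pipeline_error(stage, conditionMessage(e))
    })
  }
  wants <- function(stage) stage %in% cfg$stages

  backend <- run_stage("backend", {
    if (!is.null(cfg$backend$path)) read_toy_lm(cfg$backend$path)
    else demo_toy_lm()
  })

  corpus <- run_stage("corpus", {
    if (identical(cfg$corpus$mode, "load")) {
      load_passages(cfg$corpus$path, cfg$corpus$column_map)
    } else {
      sample_passages(backend, cfg$corpus$n_passages, cfg$corpus$length,
                      seed = cfg$seed)
    }
  })
  emit(corpus, "corpus.tsv")
  record("corpus", nrow(corpus),
         list(summary = corpus_summary(corpus)))

  metrics <- run_stage("metrics", {
    corpus_metrics(backend, corpus, k = cfg$metrics$k,
                   cap_bits = cfg$metrics$cap_bits)
  })
  emit(metrics_to_table(metrics), "metrics.tsv")
  record("metrics", nrow(metrics))

  cloze <- NULL
  if (wants("cloze") || identical(cfg$cloze$mode, "load")) {
    cloze <- run_stage("cloze", {
      if (identical(cfg$cloze$mode, "load")) {
        load_cloze_norms(cfg$cloze$path, cfg$cloze$column_map)
      } else {
        simulate_cloze(backend, corpus, cfg$cloze$n_respondents,
                       seed = cfg$seed + 1L)
      }
    })
    emit(cloze, "cloze.tsv")
    record("cloze", nrow(cloze))
  }

  gaze <- run_stage("gaze", {
    if (identical(cfg$gaze$mode, "load")) {
      load_eye_movement_report(cfg$gaze$path, cfg$gaze$column_map)
    } else {
      sim_cfg <- gaze_sim_config(n_participants = cfg$gaze$n_participants,
                                 beta = cfg$gaze$beta,
                                 seed = cfg$seed + 2L)
      simulate_gaze(corpus, metrics, sim_cfg)
    }
  })
  emit(gaze, "gaze.tsv")
  record("gaze", nrow(gaze))

  frequency <- run_stage("frequency", {
    if (!is.null(cfg$frequency$path)) {
      load_frequency_table(cfg$frequency$path, cfg$frequency$column_map)
    } else {
      synthetic_frequency_table(corpus)
    }
  })

  obs <- run_stage("merge", {
    merge_observations(corpus, gaze, metrics, cloze = cloze,
                       frequency = frequency)
  })
  emit(obs, "observations.tsv")
  n_skipped <- sum(obs$skipped)
  record("merge", nrow(obs),
         list(n_skipped = n_skipped, n_fixated = nrow(obs) - n_skipped))
  stopifnot(n_skipped + sum(!obs$skipped) == nrow(obs))

  if (wants("validation")) {
    validation <- run_stage("validation", {
      curve <- model_accuracy_curve(metrics,
                                    k_max = min(10L, length(backend_vocabulary(backend))))
      v <- list(accuracy_curve = curve)
      if (!is.null(cloze)) {
        v$zero_cloze_fraction <- zero_probability_fraction(cloze)
      }
      v
    })
    emit(validation$accuracy_curve, "accuracy_curve.tsv")
    record("validation", nrow(validation$accuracy_curve),
           list(zero_cloze_fraction = validation$zero_cloze_fraction))
  }

  fits <- NULL
  if (wants("models")) {
    fits <- run_stage("models", {
      lapply(stats::setNames(nm = cfg$models$outcomes), function(o) {
        fit_mixed(model_spec(o), obs)
      })
    })
    coef_tbl <- do.call(rbind, lapply(fits, fit_summary_table))
    emit(coef_tbl, "model_coefficients.tsv")
    record("models", nrow(coef_tbl),
           list(converged = vapply(fits, `[[`, logical(1), "converged")))
  }

  if (wants("prederror")) {
    pe <- run_stage("prederror", {
      subset <- prediction_error_subset(obs, metrics,
                                        n_bins = cfg$prederror$n_bins)
      sim_fits <- similarity_effect_fit(subset, cfg$prederror$outcomes)
      list(subset = subset, fits = sim_fits)
    })
    emit(do.call(rbind, lapply(pe$fits, fit_summary_table)),
         "prederror_coefficients.tsv")
    record("prederror", nrow(pe$subset),
           list(n_tokens = attr(pe$subset, "n_tokens"),
                n_participants = attr(pe$subset, "n_participants")))
  }

  manifest$outputs <- as.list(tools::md5sum(unlist(outputs)))
  names(manifest$outputs) <- basename(names(manifest$outputs))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  note("manifest written to ", file.path(cfg$outdir, "manifest.json"))
  invisible(manifest)
}
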