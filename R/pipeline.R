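# End-to-end orchestration: simulate or ingest gaze data, preprocess,
# detect, baseline-correct, fit the model suite and write run artifacts.
# A single master seed fans out to named substreams (design, cohort,
# shuffles) so each stage is independently reproducible.

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline with the study defaults: 100
#' shuffled window placements, group anticipation leads of 300/200 ms,
#' a 75% attention threshold, at most 4 excluded trials per participant,
#' a 100 ms minimum fixation and a 75 ms segmentation gap tolerance.
#'
#' @param seed master seed.
#' @param output_dir directory for run artifacts, or `NULL` to skip writing.
#' @param design_path path to a design YAML; `NULL` generates a design from
#'   the seed.
#' @param gaze_path path to a gaze table to ingest; `NULL` simulates a cohort.
#' @param gaze_dialect dialect for `gaze_path`, see [read_gaze_table()].
#' @param n_toddlers,n_adults simulated cohort sizes (ignored when ingesting).
#' @param params_toddler,params_adult simulation parameters per group.
#' @param n_shuffles shuffled placements per conversation x group.
#' @param leads named group leads in ms.
#' @param attention_threshold trial exclusion threshold.
#' @param max_excluded_trials participant exclusion threshold.
#' @param min_fix_ms,gap_tolerance_ms,strict_prior detector settings.
#' @param drop_participants input-level drop list (e.g. equipment errors).
#' @param exclude_items item ids excluded from the model suite.
#' @param layout AOI layout.
#' @param per_participant_shuffles redraw shuffled placements per participant.
#' @return A list of class `run_config`.
#' @export
run_config <- function(seed = 1L, output_dir = NULL, design_path = NULL,
                       gaze_path = NULL, gaze_dialect = "xy",
                       n_toddlers = 21L, n_adults = 16L,
                       params_toddler = sim_params("TODDLER"),
                       params_adult = sim_params("ADULT"),
                       n_shuffles = 100L, leads = GROUP_LEADS_MS,
                       attention_threshold = 0.75, max_excluded_trials = 4L,
                       min_fix_ms = 100, gap_tolerance_ms = 75,
                       strict_prior = FALSE,
                       drop_participants = character(0),
                       exclude_items = character(0),
                       layout = default_aoi_layout(),
                       per_participant_shuffles = FALSE) {
  check_that(attention_threshold > 0, "attention threshold must be positive")
  check_that(min_fix_ms > 0 && gap_tolerance_ms >= 0 && n_shuffles >= 1,
             "detector thresholds must be positive")
  check_that(all(c("TODDLER", "ADULT") %in% names(leads)),
             "leads must be defined per group")
  structure(as.list(environment()), class = "run_config")
}

#' Read a run configuration from a YAML file
#'
#' Scalar fields of the YAML document override the [run_config()] defaults;
#' nested `params_toddler`/`params_adult` blocks are passed to [sim_params()].
#'
#' @param path YAML config path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  args <- doc
  for (g in c("toddler", "adult")) {
    key <- paste0("params_", g)
    if (!is.null(doc[[key]])) {
      args[[key]] <- do.call(sim_params, c(list(group = toupper(g)), doc[[key]]))
    }
  }
  if (!is.null(doc$leads)) args$leads <- unlist(doc$leads)
  do.call(run_config, args)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) load or generate and validate the design; (2) ingest or
#' simulate gaze recordings; (3) apply the attention-based trial and
#' participant exclusions; (4) segment fixations, detect anticipatory
#' switches and subtract the shuffled-window chance baseline; (5) fit the
#' mixed-model suite and condition summaries. All artifacts (observation
#' table, audit table, model tables, summary, report, log) are written to
#' `config$output_dir` when set. Fully deterministic given the seed.
#'
#' @param config a [run_config()].
#' @return A list of class `pipeline_run` with `design`, `samples`, `audit`,
#'   `observations`, `suite`, `summary`, `truth` (when simulated), `seeds`
#'   and the `log` of stage messages.
#' @export
run_pipeline <- function(config = run_config()) {
  log <- character(0)
  say <- function(...) {
    line <- sprintf(...)
    log <<- c(log, line)
    message("[turngaze] ", line)
  }
  seeds <- substream_seeds(config$seed, c("design", "cohort", "shuffles"))

  # --- design ---
  if (!is.null(config$design_path)) {
    design <- load_design(config$design_path)
    say("stage design: loaded %s", config$design_path)
  } else {
    design <- generate_design(seeds[["design"]])
    say("stage design: generated from seed %d", seeds[["design"]])
  }
  violations <- validate_design(design)
  if (length(violations) > 0L) {
    stop(paste0("stage design: invalid design:\n  - ",
                paste(violations, collapse = "\n  - ")), call. = FALSE)
  }

  # --- gaze data ---
  truth <- NULL
  if (!is.null(config$gaze_path)) {
    samples <- read_gaze_table(config$gaze_path, config$gaze_dialect)
    say("stage ingest: read %d samples from %s", nrow(samples),
        config$gaze_path)
  } else {
    spec <- cohort_spec(config$n_toddlers, config$n_adults, design = design,
                        params_toddler = config$params_toddler,
                        params_adult = config$params_adult,
                        seed = seeds[["cohort"]])
    sim <- simulate_cohort(spec, leads = config$leads,
                           min_fix_ms = config$min_fix_ms,
                           gap_tolerance_ms = config$gap_tolerance_ms,
                           layout = config$layout)
    samples <- sim$samples
    truth <- sim$truth
    say("stage simulate: %d toddlers + %d adults, %d samples",
        config$n_toddlers, config$n_adults, nrow(samples))
  }

  # --- preprocessing / exclusions ---
  pre <- preprocess_samples(samples, layout = config$layout,
                            threshold = config$attention_threshold,
                            max_excluded = config$max_excluded_trials,
                            drop_participants = config$drop_participants)
  n_trials_excluded <- sum(pre$audit$excluded)
  n_part_excluded <- length(unique(
    pre$audit$participant_id[pre$audit$participant_excluded]))
  say("stage preprocess: %d/%d trials excluded, %d participants excluded",
      n_trials_excluded, nrow(pre$audit), n_part_excluded)
  if (nrow(pre$kept) == 0L) {
    stop("stage preprocess: no trials remain after exclusion; check the attention threshold and the input data",
         call. = FALSE)
  }

  # --- detection + baseline correction ---
  observations <- compute_switch_observations(
    pre$kept, design, n_shuffles = config$n_shuffles,
    min_fix_ms = config$min_fix_ms,
    gap_tolerance_ms = config$gap_tolerance_ms,
    strict_prior = config$strict_prior, leads = config$leads,
    seed = seeds[["shuffles"]],
    per_participant = config$per_participant_shuffles)
  say("stage detect/baseline: %d observations (%d participants x targets)",
      nrow(observations), length(unique(observations$participant_id)))

  # --- statistics ---
  suite <- run_model_suite(observations, exclude_items = config$exclude_items)
  for (nm in names(suite)) {
    say("stage fit: model %s, n = %d%s", nm, suite[[nm]]$n_obs,
        if (suite[[nm]]$singular) " (singular)" else "")
  }
  summary_tab <- condition_summary(observations)

  run <- structure(
    list(design = design, samples = samples, audit = pre$audit,
         observations = observations, suite = suite, summary = summary_tab,
         truth = truth, seeds = seeds, config = config, log = log),
    class = "pipeline_run"
  )
  if (!is.null(config$output_dir)) write_run_artifacts(run, config$output_dir)
  run
}

#' Write the artifacts of a pipeline run
#'
#' Writes the design (YAML), the observation table, the exclusion audit, the
#' per-model coefficient tables, the condition summary (all CSV), a
#' plain-text report and the run log.
#'
#' @param run a `pipeline_run`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_artifacts <- function(run, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  save_design(run$design, file.path(dir, "design.yaml"))
  utils::write.csv(run$observations, file.path(dir, "observations.csv"),
                   row.names = FALSE)
  utils::write.csv(run$audit, file.path(dir, "exclusion_audit.csv"),
                   row.names = FALSE)
  utils::write.csv(run$summary, file.path(dir, "condition_summary.csv"),
                   row.names = FALSE)
  for (nm in names(run$suite)) {
    utils::write.csv(run$suite[[nm]]$coefficients,
                     file.path(dir, paste0("model_", nm, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(run$truth)) {
    utils::write.csv(run$truth, file.path(dir, "truth.csv"),
                     row.names = FALSE)
  }
  report <- utils::capture.output({
    cat("turngaze pipeline report\n")
    cat("========================\n\n")
    print(run$design)
    cat("\nCondition summary (participant-level means +/- SEM)\n")
    print(run$summary)
    cat("\n")
    print(run$suite)
  })
  writeLines(report, file.path(dir, "report.txt"))
  writeLines(run$log, file.path(dir, "run.log"))
  invisible(dir)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("turngaze pipeline run (seed ", x$config$seed, ")\n", sep = "")
  cat("  ", nrow(x$observations), " observations from ",
      length(unique(x$observations$participant_id)), " participants\n",
      sep = "")
  cat("  models:", paste(names(x$suite), collapse = ", "), "\n")
  invisible(x)
}
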