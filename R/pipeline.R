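# End-to-end pipeline: (optional) simulation -> activity matrices ->
# toroidal smoothing -> sleep labels -> feature table -> practice
# adjustment -> modeling, with a manifest recording seeds, per-stage row
# counts, filter decisions, and output-file hashes.  Rerunning with the
# same config reproduces all outputs byte for byte.

#' Pipeline configuration
#'
#' @param seed global seed propagated to every stochastic stage.
#' @param out_dir output directory.
#' @param simulate `NULL` to read input files, or a list of
#'   [cohort_config()] arguments for a synthetic cohort.
#' @param input named list of file paths (`keystrokes`, `accel`, `tasks`,
#'   `phq`) used when `simulate` is `NULL`.
#' @param smoothing list: `alpha`, `rank`.
#' @param filters list: `min_active_frac`, `min_median_daily`.
#' @param features list: `half_width`, `min_keystrokes`, `nighttime`,
#'   `regularity`.
#' @param tasks list: `max_tasks`, `percentile`.
#' @param model list: `kinds`, `select_k`, `fraction`, `grids` (named
#'   list of grids or `NULL` for defaults).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("keyclock_run_"),
                            simulate = list(), input = NULL,
                            smoothing = list(), filters = list(),
                            features = list(), tasks = list(),
                            model = list()) {
  defaults <- function(user, def) {
    if (is.null(user)) return(NULL)
    def[names(user)] <- user
    def
  }
  cfg <- list(
    seed = seed, out_dir = out_dir, input = input,
    simulate = simulate,
    smoothing = defaults(smoothing, list(alpha = 100, rank = 1L)),
    filters = defaults(filters, list(min_active_frac = 0.20,
                                     min_median_daily = 50)),
    features = defaults(features, list(half_width = 3,
                                       min_keystrokes = 20L,
                                       nighttime = c(0, 6),
                                       regularity = TRUE)),
    tasks = defaults(tasks, list(max_tasks = 6L, percentile = 0.95)),
    model = defaults(model, list(kinds = c("rf", "baseline_mean"),
                                 select_k = 10L, fraction = 0.2,
                                 grids = NULL)))
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys mirror the arguments of [pipeline_config()].
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

#' Run the full pipeline
#'
#' @param config a [pipeline_config()].
#' @return the run manifest (list), invisibly; all outputs are written
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
  }

  ## ingest ------------------------------------------------------------
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    cohort <- generate_cohort(do.call(cohort_config, sim_args))
    write_cohort(cohort, file.path(out, "streams"))
    note("simulate", n_participants = length(cohort$truth$participants),
         n_keystrokes = nrow(cohort$keystrokes),
         n_tasks = nrow(cohort$tasks), seed = sim_args$seed)
  } else {
    cohort <- list(
      keystrokes = read_records(config$input$keystrokes, "keystroke"),
      accel = read_records(config$input$accel, "accel"),
      tasks = read_records(config$input$tasks, "task"),
      phq = if (!is.null(config$input$phq))
        read_records(config$input$phq, "phq") else NULL)
    note("ingest", n_keystrokes = nrow(cohort$keystrokes),
         n_tasks = nrow(cohort$tasks))
  }

  ## matrices, smoothing, sleep, features, adjustment ------------------
  ft <- build_feature_table(
    cohort$keystrokes, cohort$accel, cohort$tasks,
    regularity = config$features$regularity,
    alpha = config$smoothing$alpha, rank = config$smoothing$rank,
    half_width = config$features$half_width,
    min_keystrokes = config$features$min_keystrokes,
    min_active_frac = config$filters$min_active_frac,
    min_median_daily = config$filters$min_median_daily,
    nighttime = config$features$nighttime,
    max_tasks = config$tasks$max_tasks,
    percentile = config$tasks$percentile,
    seed = config$seed)
  note("features",
       n_tasks_in = nrow(ft$tasks),
       n_tasks_included = sum(ft$tasks$included),
       n_rows = if (is.null(ft$table)) 0L else nrow(ft$table),
       n_participants_smoothed = length(ft$fits),
       filter_log = ft$filter_log)
  .write_matrix_stack(lapply(ft$fits, function(f) f$Wstar),
                      file.path(out, "wstar.csv"))
  .write_matrix_stack(lapply(ft$sleeps, function(s) {
    m <- s$labels; rownames(m) <- as.character(s$dates); m
  }), file.path(out, "sleep_labels.csv"))
  tasks_out <- ft$tasks
  tasks_out$timestamp <- .format_time(tasks_out$timestamp)
  write.csv(tasks_out, file.path(out, "tasks_adjusted.csv"),
            row.names = FALSE)
  if (!is.null(ft$table)) {
    tab_out <- ft$table
    tab_out$task_timestamp <- .format_time(tab_out$task_timestamp)
    write.csv(tab_out, file.path(out, "feature_table.csv"),
              row.names = FALSE)
  }

  ## modeling ----------------------------------------------------------
  model_report <- NULL
  tab <- ft$table
  mc <- config$model
  if (!is.null(tab) &&
      length(unique(tab$participant_id)) >= 5L && nrow(tab) >= 20L) {
    cand <- candidate_features(config$features$regularity)
    cand <- cand[cand %in% names(tab)]
    usable <- tab[complete.cases(tab[c(cand, "adjusted_time")]), ,
                  drop = FALSE]
    if (length(unique(usable$participant_id)) >= 5L) {
      plan <- split_cohort(usable, fraction = mc$fraction,
                           seed = config$seed)
      train <- usable[usable$participant_id %in% plan$train, ,
                      drop = FALSE]
      test <- usable[usable$participant_id %in% plan$test, ,
                     drop = FALSE]
      sel <- select_features_mi(train, cand, k = mc$select_k,
                                seed = config$seed)
      reports <- list()
      for (kind in mc$kinds) {
        feats <- if (kind == "lasso") cand else sel$feature
        tm <- tune_model(train, feats, kind = kind,
                         grid = mc$grids[[kind]], seed = config$seed)
        reports[[kind]] <- evaluate_model(tm, test)
      }
      model_report <- list(
        split = list(train = plan$train, test = plan$test,
                     task_fraction = plan$task_fraction),
        selected = sel,
        metrics = lapply(reports, function(r)
          r$metrics[c("rmse", "mae", "explained_variance", "r2")]))
      jsonlite::write_json(model_report,
                           file.path(out, "model_report.json"),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
      preds <- do.call(rbind, lapply(names(reports), function(k)
        cbind(model = k, reports[[k]]$predictions)))
      write.csv(preds, file.path(out, "predictions.csv"),
                row.names = FALSE)
      note("model", n_train = nrow(train), n_test = nrow(test),
           kinds = mc$kinds, selected = sel$feature)
    }
  }

  ## manifest ----------------------------------------------------------
  files <- sort(setdiff(list.files(out, recursive = TRUE),
                        "manifest.json"))
  hashes <- tools::md5sum(file.path(out, files))
  manifest$files <- setNames(as.list(unname(hashes)), files)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# Stack per-participant days x 24 matrices into one long CSV.
.write_matrix_stack <- function(mats, path) {
  if (!length(mats)) {
    write.csv(data.frame(), path, row.names = FALSE)
    return(invisible(path))
  }
  rows <- lapply(names(mats), function(pid) {
    m <- mats[[pid]]
    data.frame(participant_id = pid, date = rownames(m),
               as.data.frame(unname(m)) |>
                 setNames(sprintf("h%02d", 0:23)),
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
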