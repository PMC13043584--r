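# Cohort-level orchestration: from raw streams to the per-task feature
# table (one row per retained task, raw features plus gm/sc expansion,
# joined to the practice-adjusted completion time).

#' Build the per-task feature table for a cohort
#'
#' Runs, per participant: sessionization, the orientation model, and
#' (optionally) the activity-matrix filters, toroidal smoothing, and sleep
#' estimation; then, per retained task: the six-hour typing window match,
#' typing and orientation features, and regularity features from the week
#' before the task; finally the per-task-number practice adjustment and
#' gm/sc expansion.
#'
#' @param keystrokes,accel,tasks validated record streams.
#' @param regularity compute `W*`-based regularity features (default
#'   `TRUE`).
#' @param alpha,rank smoothing parameters, see [torus_svd()].
#' @param half_width,min_keystrokes task-window parameters, see
#'   [match_typing_window()].
#' @param min_active_frac,min_median_daily activity filters, see
#'   [participant_filter()].
#' @param nighttime nighttime hour window for the non-upright fraction.
#' @param max_tasks,percentile task filters, see
#'   [number_and_filter_tasks()].
#' @param seed seed for the orientation clustering.
#' @return list of class `feature_table` with `table` (one row per
#'   included task with a complete typing window), `tasks` (all tasks with
#'   inclusion flags), `fits`, `sleeps`, `orientation` (per-participant
#'   model objects), and `filter_log`.
#' @export
build_feature_table <- function(keystrokes, accel, tasks,
                                regularity = TRUE, alpha = 100, rank = 1L,
                                half_width = 3, min_keystrokes = 20L,
                                min_active_frac = 0.20,
                                min_median_daily = 50,
                                nighttime = c(0, 6), max_tasks = 6L,
                                percentile = 0.95, seed = 1L) {
  sz <- sessionize(keystrokes, accel)
  events <- sz$events; sessions <- sz$sessions; accel <- sz$accel
  ev_by_pid <- split(events, events$participant_id)
  ac_by_pid <- if (!is.null(accel)) split(accel, accel$participant_id)
               else list()
  se_by_pid <- split(sessions, sessions$participant_id)
  pids <- sort(unique(tasks$participant_id))

  orientation <- list(); fits <- list(); sleeps <- list()
  filter_log <- list()
  for (p in seq_along(pids)) {
    pid <- pids[[p]]
    ac <- ac_by_pid[[pid]]
    orientation[[pid]] <- if (!is.null(ac) && nrow(ac))
      fit_orientation_model(ac, seed = seed + p) else NULL
    if (regularity && !is.null(ev_by_pid[[pid]])) {
      res <- tryCatch({
        m <- build_activity_matrices(ev_by_pid[[pid]])
        pf <- participant_filter(m$counts, min_active_frac,
                                 min_median_daily)
        if (!pf$keep) {
          filter_log[[pid]] <- paste("participant filter:",
                                     paste(pf$reasons, collapse = "; "))
          NULL
        } else {
          wf <- week_filter(m$counts, m$speed, min_active_frac,
                            min_median_daily)
          if (!wf$keep) {
            filter_log[[pid]] <- wf$reason
            NULL
          } else {
            fit <- torus_svd(wf$counts, wf$speed, alpha = alpha,
                             rank = rank)
            list(fit = fit, sleep = suppressWarnings(estimate_sleep(fit)))
          }
        }
      }, error = function(e) {
        filter_log[[pid]] <<- conditionMessage(e)
        NULL
      })
      if (!is.null(res)) {
        fits[[pid]] <- res$fit
        sleeps[[pid]] <- res$sleep
      }
    }
  }

  tk <- number_and_filter_tasks(tasks, max_tasks = max_tasks,
                                percentile = percentile)
  rows <- vector("list", nrow(tk))
  for (i in seq_len(nrow(tk))) {
    if (!tk$included[i]) next
    pid <- tk$participant_id[i]
    ev <- ev_by_pid[[pid]]
    if (is.null(ev)) {
      tk$included[i] <- FALSE
      tk$exclusion_reason[i] <- "no keystroke data"
      next
    }
    win <- match_typing_window(tk$timestamp[i], ev, half_width,
                               min_keystrokes)
    if (!win$accepted) {
      tk$included[i] <- FALSE
      tk$exclusion_reason[i] <- win$reason
      next
    }
    t0 <- tk$timestamp[i]
    se <- se_by_pid[[pid]]
    win_sess <- se[se$start >= t0 - half_width * 3600 &
                     se$start <= t0 + half_width * 3600, , drop = FALSE]
    prior_sess <- se[se$start >= t0 - 7 * 86400 & se$start < t0, ,
                     drop = FALSE]
    ac <- ac_by_pid[[pid]]
    win_ac <- if (!is.null(ac))
      ac[ac$session_id %in% win_sess$session_id, , drop = FALSE]
    else data.frame()
    prior_ac <- if (!is.null(ac))
      ac[ac$session_id %in% prior_sess$session_id, , drop = FALSE]
    else data.frame()
    tf <- typing_features(win$events)
    af <- if (!is.null(orientation[[pid]]) && nrow(win_ac))
      accel_features(win_ac, win_sess, orientation[[pid]], prior_ac,
                     prior_sess, nighttime)
    else list(nClusters = NA_real_,
              normalized_n_cluster_transitions = NA_real_,
              avg_n_cluster_transitions_perSession = NA_real_,
              medianX = NA_real_,
              fraction_nighttime_nonUpright_sessions = NA_real_,
              fraction_upright = NA_real_, no_nighttime_sessions = TRUE)
    rf <- if (regularity && !is.null(fits[[pid]]))
      regularity_features(fits[[pid]], sleeps[[pid]], t0)
    else list(varCircVar = NA_real_, medAmt_noActivity = NA_real_,
              varAmt_noActivity = NA_real_,
              medianCosineSimilarity_1diff = NA_real_,
              medianCosineSimilarity_4diff = NA_real_,
              insufficient_regularity_rows = TRUE)
    rows[[i]] <- data.frame(participant_id = pid,
                            task_timestamp = t0,
                            task_number = tk$task_number[i],
                            n_window_keystrokes = nrow(win$events),
                            c(tf, af, rf),
                            stringsAsFactors = FALSE)
  }
  tk <- adjust_task_times(tk)
  table <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  if (!is.null(table) && nrow(table)) {
    key_t <- paste(tk$participant_id, as.numeric(tk$timestamp))
    key_f <- paste(table$participant_id, as.numeric(table$task_timestamp))
    table$adjusted_time <- tk$adjusted_time[match(key_f, key_t)]
    table <- center_features(table)
  }
  structure(list(table = table, tasks = tk, fits = fits, sleeps = sleeps,
                 orientation = orientation, filter_log = filter_log),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  n_row <- if (is.null(x$table)) 0L else nrow(x$table)
  cat(sprintf("<feature_table: %d task row(s), %d participant(s), %d smoothed participant(s)>\n",
              n_row,
              if (n_row) length(unique(x$table$participant_id)) else 0L,
              length(x$fits)))
  invisible(x)
}

#' Names of the expanded candidate predictor columns
#'
#' The 13 typing/orientation features and 5 regularity features, each as
#' `_gm` and `_sc`, giving 36 candidates (or 26 when regularity features
#' are excluded).
#'
#' @param regularity include the regularity features (default `TRUE`).
#' @return character vector of column names.
#' @export
candidate_features <- function(regularity = TRUE) {
  base <- TYPING_FEATURES
  if (regularity) base <- c(base, REGULARITY_FEATURES)
  as.vector(t(outer(base, c("_gm", "_sc"), paste0)))
}
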