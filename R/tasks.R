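# Numbering, filtering, and practice adjustment of dTMT-B task records.
# Task numbers are assigned chronologically per participant before any
# filtering; at most the first six administrations are retained; tasks at
# or above the 95th percentile in errors or completion time are excluded;
# remaining times are z-scored within task-number groups so that the
# practice effect (systematic improvement with repetition) is removed.

#' Number and filter task records
#'
#' @param tasks validated task data frame.
#' @param max_tasks retain at most this many earliest tasks per
#'   participant (default 6).
#' @param percentile percentile for the outlier cut (default 0.95).
#' @param percentile_mode `"data"` recomputes the cutoffs from the pool of
#'   retained tasks; `"fixed"` uses `cutoffs`.
#' @param cutoffs named list `time`, `errors` used when
#'   `percentile_mode = "fixed"`.
#' @param strict_above drop only tasks strictly above the cutoff instead
#'   of at-or-above (default `FALSE`: at-or-above, matching printed ">="
#'   cutoffs).
#' @return data frame of all tasks with columns `task_number`, `included`
#'   (logical), and `exclusion_reason`.
#' @export
number_and_filter_tasks <- function(tasks, max_tasks = 6L,
                                    percentile = 0.95,
                                    percentile_mode = c("data", "fixed"),
                                    cutoffs = list(time = 30.91, errors = 6),
                                    strict_above = FALSE) {
  percentile_mode <- match.arg(percentile_mode)
  if (!nrow(tasks)) {
    tasks$task_number <- integer(0)
    tasks$included <- logical(0)
    tasks$exclusion_reason <- character(0)
    return(tasks)
  }
  tasks <- tasks[order(tasks$participant_id, tasks$timestamp), ,
                 drop = FALSE]
  rownames(tasks) <- NULL
  tasks$task_number <- ave(seq_len(nrow(tasks)), tasks$participant_id,
                           FUN = seq_along)
  tasks$included <- tasks$task_number <= max_tasks
  tasks$exclusion_reason <- ifelse(tasks$included, "",
                                   sprintf("beyond first %d tasks",
                                           max_tasks))
  pool <- tasks$included
  if (percentile_mode == "data") {
    time_cut <- quantile(tasks$completion_time[pool], percentile,
                         names = FALSE)
    err_cut <- quantile(tasks$n_errors[pool], percentile, names = FALSE)
  } else {
    time_cut <- cutoffs$time; err_cut <- cutoffs$errors
  }
  over <- if (strict_above)
    (tasks$completion_time > time_cut | tasks$n_errors > err_cut)
  else (tasks$completion_time >= time_cut | tasks$n_errors >= err_cut)
  drop <- pool & over
  tasks$included[drop] <- FALSE
  tasks$exclusion_reason[drop] <- sprintf(
    "at/above %gth percentile (time >= %.4g s or errors >= %.4g)",
    100 * percentile, time_cut, err_cut)
  attr(tasks, "cutoffs") <- list(time = time_cut, errors = err_cut)
  tasks
}

#' Match a task to its typing window
#'
#' Returns the keystrokes within `half_width` hours either side of the
#' task timestamp (closed interval), provided at least `min_keystrokes`
#' fall inside; otherwise the task is rejected.
#'
#' @param task_time task timestamp (`POSIXct`).
#' @param events keystrokes of the task's participant.
#' @param half_width half of the window width, hours (default 3: a six
#'   hour range around the task).
#' @param min_keystrokes inclusion threshold (default 20).
#' @return list with `accepted`, `events` (the window keystrokes), and
#'   `reason` when rejected.
#' @export
match_typing_window <- function(task_time, events, half_width = 3,
                                min_keystrokes = 20L) {
  lo <- task_time - half_width * 3600
  hi <- task_time + half_width * 3600
  inside <- events$timestamp >= lo & events$timestamp <= hi
  n <- sum(inside)
  if (n < min_keystrokes) {
    return(list(accepted = FALSE, events = events[inside, , drop = FALSE],
                reason = sprintf("only %d keystrokes in the %g h window (need %d)",
                                 n, 2 * half_width, min_keystrokes)))
  }
  list(accepted = TRUE, events = events[inside, , drop = FALSE],
       reason = NULL)
}

#' Practice-adjust task completion times
#'
#' Z-scores completion times within each task-number group across
#' participants using the population standard deviation, so that every
#' group of two or more tasks has mean exactly 0 and SD exactly 1, and so
#' the pooled adjusted times have mean 0 and SD 1.  Groups of size one or
#' with zero spread get adjusted time 0 and a flag.
#'
#' @param tasks numbered, filtered task data frame (rows with
#'   `included = FALSE` are carried through with `NA` adjusted time).
#' @return the data frame with columns `adjusted_time` and
#'   `degenerate_group`.
#' @export
adjust_task_times <- function(tasks) {
  tasks$adjusted_time <- NA_real_
  tasks$degenerate_group <- FALSE
  inc <- which(tasks$included)
  for (g in unique(tasks$task_number[inc])) {
    ix <- inc[tasks$task_number[inc] == g]
    t <- tasks$completion_time[ix]
    m <- mean(t)
    s <- sqrt(mean((t - m)^2))      # population SD
    if (length(t) < 2L || s == 0) {
      tasks$adjusted_time[ix] <- 0
      tasks$degenerate_group[ix] <- TRUE
    } else {
      tasks$adjusted_time[ix] <- (t - m) / s
    }
  }
  tasks
}
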