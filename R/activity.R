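# Days x 24 typing-activity matrices and the participant / week filters
# applied before smoothing.  Rows are calendar days (chronological, possibly
# non-contiguous after filtering), columns are hours 00-23; cells with no
# activity are zero-filled.

#' Construct an activity matrix object
#'
#' @param values numeric matrix with 24 columns.
#' @param dates `Date` vector, one per row, strictly increasing.
#' @param participant_id participant the matrix belongs to.
#' @param kind `"count"` (keystrokes per hour) or `"speed"` (median
#'   alphanumeric-to-alphanumeric interkey delay per hour, seconds) or
#'   `"normalized"` (counts divided by the participant total).
#' @return object of class `activity_matrix`.
#' @export
activity_matrix <- function(values, dates, participant_id,
                            kind = c("count", "speed", "normalized")) {
  kind <- match.arg(kind)
  values <- as.matrix(values)
  if (ncol(values) != 24L) stop("activity matrix must have 24 columns",
                                call. = FALSE)
  if (length(dates) != nrow(values))
    stop("one date per row required", call. = FALSE)
  if (is.unsorted(dates, strictly = TRUE))
    stop("rows must be in chronological order with no duplicate dates",
         call. = FALSE)
  if (any(values < 0)) stop("activity cells must be nonnegative",
                            call. = FALSE)
  dimnames(values) <- list(as.character(dates), sprintf("h%02d", 0:23))
  structure(list(values = values, dates = as.Date(dates),
                 participant_id = participant_id, kind = kind),
            class = "activity_matrix")
}

#' @export
print.activity_matrix <- function(x, ...) {
  cat(sprintf("<activity_matrix: %s, %s, %d days x 24 hours>\n",
              x$participant_id, x$kind, nrow(x$values)))
  invisible(x)
}

#' @export
dim.activity_matrix <- function(x) dim(x$values)

#' Build count and typing-speed matrices for one participant
#'
#' Tabulates keystrokes into a days-by-hours count matrix and computes the
#' hourly typing speed as the median interkey delay over consecutive
#' alphanumeric-to-alphanumeric transitions within each session, assigned
#' to the hour of the earlier keystroke; hours with no such transition are
#' zero.  The first and last calendar days are removed as potentially
#' incomplete.
#'
#' @param events keystroke data frame for a single participant, with
#'   `session_id` assigned (see [sessionize()]).
#' @return list with elements `counts` and `speed`, both
#'   [activity_matrix()] objects sharing identical date rows.
#' @export
build_activity_matrices <- function(events) {
  pid <- unique(events$participant_id)
  if (length(pid) != 1L)
    stop("build_activity_matrices expects a single participant",
         call. = FALSE)
  day <- as.Date(events$timestamp, tz = "UTC")
  all_days <- seq(min(day), max(day), by = "day")
  if (length(all_days) < 3L)
    stop("insufficient data: need at least 3 calendar days so that trimming the first and last leaves at least one",
         call. = FALSE)
  keep_days <- all_days[-c(1L, length(all_days))]
  hour <- as.integer(format(events$timestamp, "%H", tz = "UTC"))
  di <- match(day, keep_days)
  inside <- !is.na(di)
  counts <- matrix(0, nrow = length(keep_days), ncol = 24L)
  if (any(inside)) {
    tab <- table(factor(di[inside], levels = seq_along(keep_days)),
                 factor(hour[inside], levels = 0:23))
    counts <- matrix(as.numeric(tab), nrow = length(keep_days))
  }
  # Interkey delays within session between consecutive alphanumeric keys.
  ev <- events[order(events$session_id, events$timestamp), , drop = FALSE]
  n <- nrow(ev)
  speed <- matrix(0, nrow = length(keep_days), ncol = 24L)
  if (n > 1L) {
    same_sess <- ev$session_id[-1L] == ev$session_id[-n]
    aa <- ev$key_category[-1L] == "alphanumeric" &
      ev$key_category[-n] == "alphanumeric"
    dt <- as.numeric(diff(ev$timestamp), units = "secs")
    sel <- same_sess & aa
    if (any(sel)) {
      tr_day <- as.Date(ev$timestamp[-n], tz = "UTC")[sel]
      tr_hour <- as.integer(format(ev$timestamp[-n], "%H",
                                   tz = "UTC"))[sel]
      tr_di <- match(tr_day, keep_days)
      ok <- !is.na(tr_di)
      if (any(ok)) {
        key <- (tr_di[ok] - 1L) * 24L + tr_hour[ok]
        med <- tapply(dt[sel][ok], key, median)
        idx <- as.integer(names(med))
        speed[cbind(idx %/% 24L + 1L, idx %% 24L + 1L)] <- med
      }
    }
  }
  list(counts = activity_matrix(counts, keep_days, pid, "count"),
       speed = activity_matrix(speed, keep_days, pid, "speed"))
}

.day_stats <- function(values) {
  list(active_frac = rowMeans(values > 0),
       daily_total = rowSums(values))
}

#' Participant-level inclusion filter
#'
#' A participant is kept iff the mean over days of the fraction of hours
#' with any typing is at least `min_active_frac` (default 20%) and the
#' median daily keystroke total is at least `min_median_daily` (default
#' 50).  Both boundaries are inclusive.
#'
#' @param counts count [activity_matrix()] (trimmed, unnormalized).
#' @param min_active_frac minimum mean active-hour fraction.
#' @param min_median_daily minimum median daily keystroke count.
#' @return list with `keep` (logical), `reasons` (character vector of
#'   failed checks, empty when kept), and the two observed statistics.
#' @export
participant_filter <- function(counts, min_active_frac = 0.20,
                               min_median_daily = 50) {
  stopifnot(inherits(counts, "activity_matrix"))
  st <- .day_stats(counts$values)
  frac <- mean(st$active_frac)
  med <- median(st$daily_total)
  reasons <- character(0)
  if (frac < min_active_frac) reasons <- c(reasons, "active-hour fraction")
  if (med < min_median_daily) reasons <- c(reasons, "median daily keystrokes")
  list(keep = !length(reasons), reasons = reasons,
       mean_active_frac = frac, median_daily = med)
}

#' Week-level day filter
#'
#' Evaluates every window of 7 consecutive retained days (stride 1).  A
#' window passes iff, within the window, the mean active-hour fraction and
#' the median daily keystroke total meet the same thresholds as the
#' participant filter.  Days contained in no passing window are removed
#' from both matrices; if fewer than `min_days` (default 7) remain, the
#' participant is dropped.
#'
#' @param counts,speed matching count and speed matrices.
#' @param min_active_frac,min_median_daily thresholds, as in
#'   [participant_filter()].
#' @param min_days minimum surviving days.
#' @return list with filtered `counts` and `speed` (or `NULL`s when the
#'   participant is dropped), `keep`, `removed_dates`, and `reason`.
#' @export
week_filter <- function(counts, speed, min_active_frac = 0.20,
                        min_median_daily = 50, min_days = 7L) {
  stopifnot(inherits(counts, "activity_matrix"),
            inherits(speed, "activity_matrix"),
            identical(counts$dates, speed$dates))
  n <- nrow(counts$values)
  st <- .day_stats(counts$values)
  keep_day <- rep(FALSE, n)
  if (n >= 7L) {
    for (s in seq_len(n - 6L)) {
      w <- s:(s + 6L)
      if (mean(st$active_frac[w]) >= min_active_frac &&
          median(st$daily_total[w]) >= min_median_daily)
        keep_day[w] <- TRUE
    }
  }
  removed <- counts$dates[!keep_day]
  if (sum(keep_day) < min_days) {
    return(list(counts = NULL, speed = NULL, keep = FALSE,
                removed_dates = removed,
                reason = sprintf("fewer than %d days survive the 7-day window filter",
                                 min_days)))
  }
  list(counts = activity_matrix(counts$values[keep_day, , drop = FALSE],
                                counts$dates[keep_day],
                                counts$participant_id, "count"),
       speed = activity_matrix(speed$values[keep_day, , drop = FALSE],
                               speed$dates[keep_day],
                               speed$participant_id, "speed"),
       keep = TRUE, removed_dates = removed, reason = NULL)
}

#' Normalize a count matrix by the participant's total keystrokes
#'
#' @param counts count [activity_matrix()].
#' @return [activity_matrix()] of kind `"normalized"`; cells sum to 1.
#' @export
normalize_counts <- function(counts) {
  stopifnot(inherits(counts, "activity_matrix"), counts$kind == "count")
  tot <- sum(counts$values)
  if (tot <= 0) stop("degenerate input: all-zero count matrix",
                     call. = FALSE)
  activity_matrix(counts$values / tot, counts$dates,
                  counts$participant_id, "normalized")
}
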