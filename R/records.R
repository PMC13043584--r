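# Record schemas and stream I/O for the four raw data kinds the pipeline
# consumes: keystroke events, accelerometer samples, task records, PHQ
# self-reports.  All timestamps are the participant's local wall clock;
# hour-of-day semantics drive everything downstream, so no timezone
# arithmetic is ever performed (times are parsed in UTC purely as a fixed
# anchor).

KEY_CATEGORIES <- c("alphanumeric", "backspace", "autocorrect",
                    "punctuation", "special", "other")
HAND_MODES <- c("one", "two", "unknown")
RECORD_KINDS <- c("keystroke", "accel", "task", "phq")

TIME_FMT <- "%Y-%m-%dT%H:%M:%OS"

.parse_time <- function(x) {
  as.POSIXct(x, format = TIME_FMT, tz = "UTC")
}

.format_time <- function(x) {
  format(x, format = "%Y-%m-%dT%H:%M:%OS3", tz = "UTC")
}

.schema <- function(kind) {
  switch(kind,
    keystroke = list(
      required = c("participant_id", "timestamp", "key_category",
                   "press_duration"),
      optional = c("session_id", "hand_mode")),
    accel = list(
      required = c("participant_id", "timestamp", "x", "y", "z"),
      optional = "session_id"),
    task = list(
      required = c("participant_id", "timestamp", "completion_time",
                   "n_errors", "layout_variant"),
      optional = character()),
    phq = list(
      required = c("participant_id", "timestamp", paste0("item", 1:8)),
      optional = "total"),
    stop("unknown record kind: ", kind, call. = FALSE))
}

#' Validate a data frame of records against its schema
#'
#' Checks field presence, parses timestamps, and enforces the per-kind
#' invariants (key categories, nonnegative press durations, accelerometer
#' sanity bounds of 4 g, positive completion times, layout variants 1--12,
#' PHQ items in 0--3 with total equal to the item sum).
#'
#' @param df data frame of raw records.
#' @param kind one of `"keystroke"`, `"accel"`, `"task"`, `"phq"`.
#' @return the validated data frame, sorted by participant then timestamp,
#'   with a `total` column added for PHQ records when absent.
#' @export
validate_records <- function(df, kind) {
  kind <- match.arg(kind, RECORD_KINDS)
  sch <- .schema(kind)
  missing_cols <- setdiff(sch$required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("schema error [%s]: missing required field(s): %s",
                 kind, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (!inherits(df$timestamp, "POSIXct")) {
    parsed <- .parse_time(as.character(df$timestamp))
    bad <- which(is.na(parsed) & !is.na(df$timestamp) & nzchar(df$timestamp))
    if (length(bad)) {
      stop(sprintf("format error [%s]: unparsable timestamp at line(s) %s",
                   kind, paste(head(bad, 5L), collapse = ", ")),
           call. = FALSE)
    }
    df$timestamp <- parsed
  }
  .fail <- function(bad, what) {
    if (length(bad)) {
      stop(sprintf("schema error [%s]: %s at line(s) %s", kind, what,
                   paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
    }
  }
  .fail(which(is.na(df$timestamp)), "missing timestamp")
  if (kind == "keystroke") {
    .fail(which(!df$key_category %in% KEY_CATEGORIES), "invalid key_category")
    .fail(which(!is.finite(df$press_duration) | df$press_duration < 0),
          "press_duration must be finite and >= 0")
    if (is.null(df$session_id)) df$session_id <- NA_character_
    if (is.null(df$hand_mode)) df$hand_mode <- "unknown"
    .fail(which(!df$hand_mode %in% HAND_MODES), "invalid hand_mode")
  } else if (kind == "accel") {
    for (ax in c("x", "y", "z")) {
      .fail(which(!is.finite(df[[ax]])), sprintf("%s-axis not finite", ax))
      .fail(which(abs(df[[ax]]) > 4), sprintf("|%s| exceeds 4 g bound", ax))
    }
    if (is.null(df$session_id)) df$session_id <- NA_character_
  } else if (kind == "task") {
    .fail(which(!is.finite(df$completion_time) | df$completion_time <= 0),
          "completion_time must be > 0")
    .fail(which(df$n_errors < 0 | df$n_errors != round(df$n_errors)),
          "n_errors must be a nonnegative integer")
    .fail(which(df$layout_variant < 1 | df$layout_variant > 12),
          "layout_variant must be in 1..12")
  } else if (kind == "phq") {
    items <- as.matrix(df[paste0("item", 1:8)])
    .fail(which(apply(items, 1L, function(r)
      any(!r %in% 0:3))), "PHQ item scores must be in 0..3")
    sums <- rowSums(items)
    if (is.null(df$total)) {
      df$total <- sums
    } else {
      .fail(which(df$total != sums), "PHQ total must equal the item sum")
    }
  }
  df[order(df$participant_id, df$timestamp), , drop = FALSE] |>
    `rownames<-`(NULL)
}

#' Read a stream of records from CSV or JSONL
#'
#' One record per CSV row or JSON line; the format is chosen by file
#' extension (`.jsonl`/`.json` versus anything else, read as CSV with a
#' header).  Records are validated and returned sorted by
#' `(participant_id, timestamp)`.
#'
#' @param path file to read.
#' @param kind record kind, see [validate_records()].
#' @return validated, sorted data frame.  An empty file yields a zero-row
#'   data frame with the schema's columns.
#' @export
read_records <- function(path, kind) {
  kind <- match.arg(kind, RECORD_KINDS)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "json")) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) return(.empty_records(kind))
    rows <- lapply(seq_along(lines), function(i) {
      rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
                      error = function(e)
                        stop(sprintf("format error [%s]: bad JSON at line %d",
                                     kind, i), call. = FALSE))
      as.data.frame(rec, stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows)
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE)
    if (!nrow(df)) return(.empty_records(kind))
  }
  validate_records(df, kind)
}

#' Write a stream of records to CSV or JSONL
#'
#' Inverse of [read_records()]; `write_records` then `read_records` is a
#' field-for-field round trip.
#'
#' @param df validated record data frame.
#' @param path output file; extension selects the format.
#' @param kind record kind.
#' @return `path`, invisibly.
#' @export
write_records <- function(df, path, kind) {
  kind <- match.arg(kind, RECORD_KINDS)
  out <- df
  out$timestamp <- .format_time(out$timestamp)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jsonl", "json")) {
    lines <- vapply(seq_len(nrow(out)), function(i)
      as.character(jsonlite::toJSON(as.list(out[i, , drop = FALSE]),
                                    auto_unbox = TRUE, digits = NA)),
      character(1L))
    writeLines(lines, path)
  } else {
    write.csv(out, path, row.names = FALSE)
  }
  invisible(path)
}

.empty_records <- function(kind) {
  sch <- .schema(kind)
  cols <- c(sch$required, sch$optional)
  df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
  df$timestamp <- as.POSIXct(character(0), tz = "UTC")
  df
}

#' Group keystrokes (and accelerometer samples) into typing sessions
#'
#' If the events already carry `session_id`s those are honoured; otherwise a
#' new session starts whenever the gap to the previous keystroke of the same
#' participant exceeds `gap_threshold` seconds.  Accelerometer samples are
#' assigned to the session whose `[start, end]` interval contains them, else
#' to the nearest session within 60 s, else dropped with a warning.
#'
#' @param events keystroke data frame (validated).
#' @param accel optional accelerometer data frame (validated).
#' @param gap_threshold seconds separating sessions (default 5).
#' @return list with `events` (keystrokes with filled `session_id`),
#'   `sessions` (one row per session: `session_id`, `participant_id`,
#'   `start`, `end`, `hand_mode`, `n_keystrokes`), and `accel` (samples with
#'   assigned `session_id`).
#' @export
sessionize <- function(events, accel = NULL, gap_threshold = 5) {
  stopifnot(gap_threshold > 0)
  if (!nrow(events)) {
    return(list(events = events,
                sessions = data.frame(session_id = character(0),
                                      participant_id = character(0),
                                      start = as.POSIXct(character(0), tz = "UTC"),
                                      end = as.POSIXct(character(0), tz = "UTC"),
                                      hand_mode = character(0),
                                      n_keystrokes = integer(0)),
                accel = accel))
  }
  events <- events[order(events$participant_id, events$timestamp), ,
                   drop = FALSE]
  rownames(events) <- NULL
  has_id <- !is.na(events$session_id) & nzchar(events$session_id)
  if (!all(has_id)) {
    # Gap-based sessionization per participant for unlabelled events.
    new_part <- c(TRUE, events$participant_id[-1L] !=
                          events$participant_id[-nrow(events)])
    gaps <- c(Inf, as.numeric(diff(events$timestamp), units = "secs"))
    brk <- new_part | gaps > gap_threshold
    # Events that carry an id keep it; runs of unlabelled events get fresh ids.
    run <- cumsum(brk)
    fresh <- paste0(events$participant_id, "_s",
                    formatC(run, width = 6L, flag = "0"))
    events$session_id <- ifelse(has_id, events$session_id, fresh)
  }
  if (is.null(events$hand_mode)) events$hand_mode <- "unknown"
  # Vectorized per-session summary: order by (session, time) so each
  # session is a contiguous block with known first/last positions.
  o <- order(events$session_id, events$timestamp)
  sid <- events$session_id[o]
  first <- !duplicated(sid)
  last <- !duplicated(sid, fromLast = TRUE)
  n_one <- rowsum((events$hand_mode[o] == "one") + 0L, sid)
  n_two <- rowsum((events$hand_mode[o] == "two") + 0L, sid)
  hand <- ifelse(n_one + n_two == 0L, "unknown",
                 ifelse(n_two >= n_one, "two", "one"))
  sessions <- data.frame(
    session_id = sid[first],
    participant_id = events$participant_id[o][first],
    start = events$timestamp[o][first],
    end = events$timestamp[o][last],
    hand_mode = as.vector(hand),
    n_keystrokes = as.vector(rowsum(rep(1L, length(sid)), sid)),
    stringsAsFactors = FALSE)
  sessions <- sessions[order(sessions$participant_id, sessions$start), ,
                       drop = FALSE]
  rownames(sessions) <- NULL
  if (!is.null(accel) && nrow(accel) &&
      (is.null(accel$session_id) || anyNA(accel$session_id))) {
    if (is.null(accel$session_id)) accel$session_id <- NA_character_
    keep_ix <- !is.na(accel$session_id)
    for (pid in unique(accel$participant_id[!keep_ix])) {
      ss <- sessions[sessions$participant_id == pid, , drop = FALSE]
      ai <- which(accel$participant_id == pid & !keep_ix)
      if (!nrow(ss)) next
      t <- as.numeric(accel$timestamp[ai])
      s0 <- as.numeric(ss$start); s1 <- as.numeric(ss$end)
      for (k in seq_along(ai)) {
        hit <- which(t[k] >= s0 & t[k] <= s1)
        if (length(hit)) {
          accel$session_id[ai[k]] <- ss$session_id[hit[1L]]
        } else {
          d <- pmin(abs(t[k] - s0), abs(t[k] - s1))
          j <- which.min(d)
          if (d[j] <= 60) accel$session_id[ai[k]] <- ss$session_id[j]
        }
      }
    }
    n_drop <- sum(is.na(accel$session_id))
    if (n_drop) {
      warning(sprintf("%d accelerometer sample(s) matched no session within 60 s and were dropped",
                      n_drop), call. = FALSE)
      accel <- accel[!is.na(accel$session_id), , drop = FALSE]
    }
  }
  list(events = events, sessions = sessions, accel = accel)
}
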