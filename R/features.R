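# Feature engineering: per-task windows of typing and accelerometer
# metadata are reduced to the 13 typing/orientation features, and the
# smoothed trajectory plus sleep labels to the 5 regularity features;
# every feature is then expanded into a grand-mean (gm, the participant's
# average -- a between-person predictor) and a subject-centred (sc, the
# deviation from that average -- a within-person predictor) column.

TYPING_FEATURES <- c("nClusters", "normalized_n_cluster_transitions",
                     "avg_n_cluster_transitions_perSession", "medianX",
                     "fraction_nighttime_nonUpright_sessions",
                     "fraction_upright", "nSessions", "avgNkeypresses",
                     "backspaceRate", "autocorrectRate", "typingSpeed",
                     "varAAIKD", "medianPressDuration")
REGULARITY_FEATURES <- c("varCircVar", "medAmt_noActivity",
                         "varAmt_noActivity", "medianCosineSimilarity_1diff",
                         "medianCosineSimilarity_4diff")

# Interkey delays between consecutive keystrokes of the same session where
# both keys are alphanumeric.
.aa_ikds <- function(events) {
  if (nrow(events) < 2L)
    return(data.frame(dt = numeric(0), hand_mode = character(0)))
  ev <- events[order(events$session_id, events$timestamp), , drop = FALSE]
  n <- nrow(ev)
  sel <- ev$session_id[-1L] == ev$session_id[-n] &
    ev$key_category[-1L] == "alphanumeric" &
    ev$key_category[-n] == "alphanumeric"
  data.frame(dt = as.numeric(diff(ev$timestamp), units = "secs")[sel],
             hand_mode = if (is.null(ev$hand_mode)) rep("unknown", sum(sel))
                         else ev$hand_mode[-1L][sel],
             stringsAsFactors = FALSE)
}

#' Fit a personalized phone-orientation model
#'
#' A centroid-partition stand-in for personalized orientation discovery:
#' each session with accelerometer data is summarised by its per-axis
#' median; the representatives are clustered by k-means for candidate
#' cluster counts (default 2--6, capped by the data), and the count with
#' the best mean silhouette width is kept.  Deterministic given `seed`.
#'
#' @param accel accelerometer samples with `session_id` assigned.
#' @param k_range candidate cluster counts.
#' @param seed RNG seed for the k-means starts (global RNG state is
#'   preserved).
#' @return object of class `orientation_model` with `centroids`
#'   (`nClusters x 3`), `assignment` (named cluster index per session),
#'   `nClusters`, and `silhouette` (mean width per candidate).
#' @export
fit_orientation_model <- function(accel, k_range = 2:6, seed = 1L) {
  reps <- session_representatives(accel)
  n <- nrow(reps)
  if (n < 2L) {
    warning("fewer than 2 sessions with accelerometer data: single-cluster model",
            call. = FALSE)
    cent <- matrix(colMeans(reps[, c("x", "y", "z"), drop = FALSE]),
                   nrow = 1L, dimnames = list(NULL, c("x", "y", "z")))
    return(structure(list(centroids = cent,
                          assignment = setNames(rep(1L, n), reps$session_id),
                          nClusters = 1L, silhouette = NA_real_),
                     class = "orientation_model"))
  }
  xyz <- as.matrix(reps[, c("x", "y", "z")])
  ks <- k_range[k_range >= 2L & k_range <= n - 1L]
  res <- .with_seed(seed, {
    if (!length(ks)) {
      km <- kmeans(xyz, centers = min(2L, n), nstart = 10L)
      list(km = km, sil = NA_real_, widths = NA_real_)
    } else {
      d <- dist(xyz)
      fits <- lapply(ks, function(k) kmeans(xyz, centers = k, nstart = 10L,
                                            iter.max = 50L))
      widths <- vapply(seq_along(ks), function(i) {
        s <- cluster::silhouette(fits[[i]]$cluster, d)
        mean(s[, "sil_width"])
      }, numeric(1L))
      best <- which.max(widths)
      list(km = fits[[best]], sil = widths[best],
           widths = setNames(widths, ks))
    }
  })
  km <- res$km
  colnames(km$centers) <- c("x", "y", "z")
  structure(list(centroids = km$centers,
                 assignment = setNames(km$cluster, reps$session_id),
                 nClusters = nrow(km$centers),
                 silhouette = res$widths),
            class = "orientation_model")
}

#' @export
print.orientation_model <- function(x, ...) {
  cat(sprintf("<orientation_model: %d cluster(s), %d session(s)>\n",
              x$nClusters, length(x$assignment)))
  invisible(x)
}

#' Assign orientations to new data
#'
#' @param object an `orientation_model`.
#' @param newdata matrix or data frame with columns `x`, `y`, `z`.
#' @param ... unused.
#' @return integer vector of nearest-centroid indices.
#' @export
predict.orientation_model <- function(object, newdata, ...) {
  pts <- as.matrix(as.data.frame(newdata)[, c("x", "y", "z")])
  cent <- object$centroids
  d2 <- outer(rowSums(pts^2), rep(1, nrow(cent))) -
    2 * pts %*% t(cent) + outer(rep(1, nrow(pts)), rowSums(cent^2))
  max.col(-d2, ties.method = "first")
}

#' Per-session accelerometer representatives
#'
#' @param accel accelerometer samples with `session_id`.
#' @return data frame with `session_id` and per-axis medians `x`, `y`, `z`.
#' @export
session_representatives <- function(accel) {
  # vectorized grouped median: within each session sort the axis values;
  # the median sits at the (possibly averaged) middle positions
  sid <- accel$session_id
  ids <- sort(unique(sid))
  gmed <- function(v) {
    o <- order(sid, v)
    vs <- v[o]; gs <- sid[o]
    starts <- which(!duplicated(gs))
    sizes <- diff(c(starts, length(gs) + 1L))
    lo <- starts + (sizes - 1L) %/% 2L
    hi <- starts + sizes %/% 2L
    (vs[lo] + vs[hi]) / 2
  }
  data.frame(session_id = ids, x = gmed(accel$x), y = gmed(accel$y),
             z = gmed(accel$z), stringsAsFactors = FALSE)
}

.is_upright <- function(x, z) x >= -0.2 & x <= 0.2 & z <= 0.1
.is_non_upright <- function(x, z) (x > 0.5 | x < -0.5) & z >= 0.1

#' Typing features of a task window
#'
#' @param events keystrokes inside the window, with `session_id` and
#'   `hand_mode`.
#' @return named list of the seven typing features plus a
#'   `typing_speed_missing` flag (no two-handed session in the window).
#' @export
typing_features <- function(events) {
  total <- nrow(events)
  sess <- unique(events$session_id)
  ikds <- .aa_ikds(events)
  two <- ikds$dt[ikds$hand_mode == "two"]
  list(nSessions = length(sess),
       avgNkeypresses = total / max(length(sess), 1L),
       backspaceRate = sum(events$key_category == "backspace") / total,
       autocorrectRate = sum(events$key_category == "autocorrect") / total,
       typingSpeed = if (length(two)) median(two) else NA_real_,
       varAAIKD = if (length(ikds$dt) > 1L) var(ikds$dt) else 0,
       medianPressDuration = median(events$press_duration),
       typing_speed_missing = !length(two))
}

#' Accelerometer and orientation features of a task window
#'
#' Upright is defined as a session representative with
#' `-0.2 <= x <= 0.2` and `z <= 0.1`; non-upright as `(x > 0.5 or
#' x < -0.5)` and `z >= 0.1`.  The nighttime fraction uses sessions that
#' started between `nighttime[1]`:00 and `nighttime[2]`:00 up to one week
#' before the task.
#'
#' @param window_accel accelerometer samples inside the window.
#' @param window_sessions session table (chronological) for the window.
#' @param model an `orientation_model`.
#' @param prior_accel,prior_sessions the same for the week before the task.
#' @param nighttime half-open hour interval, default `c(0, 6)` (00:00 to
#'   05:59).
#' @return named list of the six orientation features plus a
#'   `no_nighttime_sessions` flag.
#' @export
accel_features <- function(window_accel, window_sessions, model,
                           prior_accel = NULL, prior_sessions = NULL,
                           nighttime = c(0, 6)) {
  reps <- if (nrow(window_accel)) session_representatives(window_accel)
          else data.frame(session_id = character(0), x = numeric(0),
                          y = numeric(0), z = numeric(0))
  ws <- window_sessions[order(window_sessions$start), , drop = FALSE]
  reps <- reps[match(ws$session_id, reps$session_id), , drop = FALSE]
  reps <- reps[!is.na(reps$session_id), , drop = FALSE]
  n_sess <- nrow(ws)
  # session-to-session orientation transitions
  cl <- if (nrow(reps)) predict(model, reps) else integer(0)
  transitions <- if (length(cl) > 1L) sum(diff(cl) != 0L) else 0L
  # within-session per-sample transitions
  per_sess <- if (nrow(window_accel)) {
    vapply(split(seq_len(nrow(window_accel)), window_accel$session_id),
           function(ix) {
             a <- window_accel[ix, , drop = FALSE]
             a <- a[order(a$timestamp), , drop = FALSE]
             cls <- predict(model, a)
             if (length(cls) > 1L) sum(diff(cls) != 0L) else 0L
           }, numeric(1L))
  } else numeric(0)
  # nighttime non-upright fraction over the prior week
  night_frac <- 0; no_night <- TRUE
  if (!is.null(prior_sessions) && nrow(prior_sessions)) {
    hr <- as.integer(format(prior_sessions$start, "%H", tz = "UTC"))
    night <- prior_sessions[hr >= nighttime[1L] & hr < nighttime[2L], ,
                            drop = FALSE]
    if (nrow(night) && !is.null(prior_accel) && nrow(prior_accel)) {
      nreps <- session_representatives(
        prior_accel[prior_accel$session_id %in% night$session_id, ,
                    drop = FALSE])
      if (nrow(nreps)) {
        night_frac <- mean(.is_non_upright(nreps$x, nreps$z))
        no_night <- FALSE
      }
    }
  }
  list(nClusters = model$nClusters,
       normalized_n_cluster_transitions =
         if (n_sess) transitions / n_sess else 0,
       avg_n_cluster_transitions_perSession =
         if (length(per_sess)) mean(per_sess) else 0,
       medianX = if (nrow(window_accel)) median(abs(window_accel$x))
                 else NA_real_,
       fraction_nighttime_nonUpright_sessions = night_frac,
       fraction_upright = if (nrow(reps))
         mean(.is_upright(reps$x, reps$z)) else NA_real_,
       no_nighttime_sessions = no_night)
}

#' Weighted circular variance of an hourly activity row
#'
#' `1 - R` where `R` is the length of the mean resultant of the hour
#' angles `2*pi*h/24` weighted by the row values: 0 when all activity sits
#' at one hour, 1 when activity is uniform over the day.
#'
#' @param w nonnegative weights over hours 0..23.
#' @return circular variance in `[0, 1]`, or `NA` for an all-zero row.
#' @export
circular_variance <- function(w) {
  s <- sum(w)
  if (s <= 0) return(NA_real_)
  ang <- 2 * pi * (seq_len(length(w)) - 1L) / length(w)
  1 - Mod(sum(w * exp(1i * ang))) / s
}

#' Typing-regularity and estimated-sleep features for one task
#'
#' Uses the `W*` rows and sleep periods dated within the week before the
#' task.  Requires at least `min_rows` rows (default 5), else the task is
#' flagged.
#'
#' @param fit a [torus_svd()] fit for the participant.
#' @param sleep matching [estimate_sleep()] labels.
#' @param task_time task timestamp (`POSIXct`).
#' @param min_rows minimum `W*` rows in the look-back window.
#' @return named list of the five regularity features plus an
#'   `insufficient_regularity_rows` flag.
#' @export
regularity_features <- function(fit, sleep, task_time, min_rows = 5L) {
  task_date <- as.Date(task_time, tz = "UTC")
  in_win <- fit$dates >= task_date - 7L & fit$dates < task_date
  W <- fit$Wstar[in_win, , drop = FALSE]
  na_out <- list(varCircVar = NA_real_, medAmt_noActivity = NA_real_,
                 varAmt_noActivity = NA_real_,
                 medianCosineSimilarity_1diff = NA_real_,
                 medianCosineSimilarity_4diff = NA_real_,
                 insufficient_regularity_rows = TRUE)
  if (nrow(W) < min_rows) return(na_out)
  cv <- apply(W, 1L, circular_variance)
  cv <- cv[!is.na(cv)]
  per <- sleep$periods
  ph <- per$sleep_hours[per$full & per$date >= task_date - 7L &
                          per$date < task_date]
  cos_sim <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(NA_real_)
    sum(a * b) / (na * nb)
  }
  sims <- function(gap) {
    n <- nrow(W)
    if (n <= gap) return(NA_real_)
    v <- vapply(seq_len(n - gap), function(d)
      cos_sim(W[d, ], W[d + gap, ]), numeric(1L))
    v <- v[!is.na(v)]
    if (length(v)) median(v) else NA_real_
  }
  list(varCircVar = if (length(cv) > 1L) var(cv) else NA_real_,
       medAmt_noActivity = if (length(ph)) median(ph) else NA_real_,
       varAmt_noActivity = if (length(ph) > 1L) var(ph) else NA_real_,
       medianCosineSimilarity_1diff = sims(1L),
       medianCosineSimilarity_4diff = sims(4L),
       insufficient_regularity_rows = FALSE)
}

#' Expand raw features into grand-mean and subject-centred columns
#'
#' For every feature column, `gm` is the participant's mean of the raw
#' values (constant within participant, uncentred) and `sc` is the raw
#' value minus that mean (zero mean within participant).  `gm + sc`
#' reconstructs the raw value exactly.
#'
#' @param table data frame with a `participant_id` column and the raw
#'   feature columns.
#' @param features character vector of feature column names (default: all
#'   typing and regularity features present).
#' @return the table with `<feature>_gm` and `<feature>_sc` columns
#'   appended.
#' @export
center_features <- function(table,
                            features = intersect(c(TYPING_FEATURES,
                                                   REGULARITY_FEATURES),
                                                 names(table))) {
  for (f in features) {
    gm <- ave(table[[f]], table$participant_id,
              FUN = function(v) mean(v, na.rm = TRUE))
    gm[is.nan(gm)] <- NA_real_
    table[[paste0(f, "_gm")]] <- gm
    table[[paste0(f, "_sc")]] <- table[[f]] - gm
  }
  table
}
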