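# Synthetic cohort generator.  Emits keystroke / accelerometer / task / PHQ
# streams with the statistical structure the pipeline assumes -- circadian
# hourly keystroke intensity with a planted nightly inactivity window,
# 7-day periodicity via a weekend factor, lognormal interkey delays,
# per-participant phone-orientation clusters, task completion times with a
# decaying practice effect plus dependence on a shared latent state, and PHQ
# totals correlated with that state -- together with the planted ground
# truth needed for recovery tests.

# Default relative circadian intensity by hour of day (waking hours; sleep
# hours are forced to zero per night).  Mild morning ramp, midday and
# evening peaks.
.default_profile <- c(0.2, 0.1, 0.1, 0.1, 0.1, 0.2, 0.4, 0.7, 1.0, 1.1,
                      1.2, 1.3, 1.4, 1.3, 1.2, 1.1, 1.2, 1.3, 1.5, 1.6,
                      1.5, 1.2, 0.8, 0.4)

# Candidate phone-orientation centroids in g-units: upright portrait, flat
# on a table, landscape on the side, lying down holding the phone overhead.
.orientation_library <- rbind(
  upright  = c(x = 0.00, y = -0.55, z = -0.15),
  flat     = c(x = 0.02, y = -0.05, z = -0.95),
  side     = c(x = 0.75, y = -0.35, z = 0.05),
  reclined = c(x = -0.65, y = -0.30, z = 0.25))

#' Configuration for the synthetic cohort generator
#'
#' All arguments have defaults describing the study conditions the package
#' is tested under: 60 participants observed for 30 days, a planted 8 h
#' nightly sleep window with about one hour of onset jitter, roughly 400
#' expected keystrokes per day concentrated in waking hours, lognormal
#' interkey delays with a participant-level median near 0.2 s, and task
#' completion times with a 5% per-administration practice decay.  Two
#' independent standard-normal latent states per participant plant the
#' signal the pipeline is meant to recover: a typing/mood state couples
#' typing speed, task time, and PHQ (so the mood-augmentation experiment is
#' exercisable), and a sleep-regularity state drives nightly onset jitter
#' and contributes its own, typing-independent share of task time (so
#' regularity features carry incremental information, emulating the role
#' they play in the study design).
#'
#' @param n_participants number of participants.
#' @param n_days days of observation per participant.
#' @param seed integer seed fixing the full stream.
#' @param sleep list: `onset_mean` (hour, default 23), `onset_sd` between
#'   participants, `duration` hours in 1..12, `jitter_sd` nightly onset
#'   jitter in hours, `jitter_max` whole-hour bound on nightly jitter
#'   (default 1), `jitter_link` exponent tying nightly jitter to the
#'   sleep-regularity latent state (irregular sleepers are also slower on
#'   the task through `regularity_coef`).
#' @param circadian list: `profile` (24 relative intensities),
#'   `keystrokes_per_day` expected count over waking hours,
#'   `weekend_factor` multiplier applied on Saturdays and Sundays.
#' @param ikd list: `median_ref` reference median interkey delay (s),
#'   `latent_coef` log-scale effect of the latent state, `participant_sd`
#'   residual between-participant log spread, `sdlog` within-participant
#'   lognormal dispersion.
#' @param keys list of key-category probabilities: `backspace`,
#'   `autocorrect`, `punctuation`, `special` (remainder alphanumeric).
#' @param press list: lognormal `meanlog`, `sdlog` for press durations (s).
#' @param session list: `mean_size` expected keystrokes per typing burst,
#'   `two_hand_prob` probability a session is two-handed.
#' @param orientation list: `k_range` candidate cluster counts per
#'   participant, `within_sd` within-cluster axis SD (g), `stay_prob`
#'   session-to-session probability of keeping the orientation,
#'   `samples_per_session` accelerometer samples per session.
#' @param task list: `n_tasks` per participant (at most 6 are modelled
#'   downstream), `baseline` seconds, `decay` multiplicative practice decay
#'   per administration, `latent_coef` effect of the typing latent state on
#'   log-time, `regularity_coef` effect of the sleep-regularity latent
#'   state, `noise_sd` lognormal noise, `error_rate` Poisson mean of
#'   errors, `hour_mean`/`hour_sd` daytime task timing.
#' @param phq list: `mean`, `sd`, `latent_cor` correlation with the latent
#'   state, `n_reports` per participant.
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 60, n_days = 30, seed = 1,
                          sleep = list(), circadian = list(), ikd = list(),
                          keys = list(), press = list(), session = list(),
                          orientation = list(), task = list(), phq = list()) {
  merge_defaults <- function(user, def) {
    bad <- setdiff(names(user), names(def))
    if (length(bad)) stop("unknown config field(s): ",
                          paste(bad, collapse = ", "), call. = FALSE)
    def[names(user)] <- user
    def
  }
  cfg <- list(
    n_participants = n_participants, n_days = n_days, seed = seed,
    origin = as.Date("2023-01-02"),  # a Monday, so weeks align
    sleep = merge_defaults(sleep, list(
      onset_mean = 23, onset_sd = 1, duration = 8,
      jitter_sd = 0.5, jitter_max = 1L, jitter_link = 0.3)),
    circadian = merge_defaults(circadian, list(
      profile = .default_profile, keystrokes_per_day = 400,
      weekend_factor = 1.15)),
    ikd = merge_defaults(ikd, list(
      median_ref = 0.2, latent_coef = 0.25, participant_sd = 0.08,
      sdlog = 0.45)),
    keys = merge_defaults(keys, list(
      backspace = 0.08, autocorrect = 0.04, punctuation = 0.05,
      special = 0.02)),
    press = merge_defaults(press, list(meanlog = log(0.08), sdlog = 0.3)),
    session = merge_defaults(session, list(
      mean_size = 30, two_hand_prob = 0.7)),
    orientation = merge_defaults(orientation, list(
      k_range = 2:3, within_sd = 0.05, stay_prob = 0.8,
      samples_per_session = 8)),
    task = merge_defaults(task, list(
      n_tasks = 6, baseline = 20, decay = 0.95, latent_coef = 0.2,
      regularity_coef = 0.15, noise_sd = 0.2, error_rate = 1.0,
      hour_mean = 14, hour_sd = 3)),
    phq = merge_defaults(phq, list(
      mean = 6, sd = 4.8, latent_cor = 0.5, n_reports = 2)))
  if (cfg$n_participants < 1 || cfg$n_days < 1)
    stop("config error: need at least 1 participant and 1 day",
         call. = FALSE)
  if (cfg$sleep$duration < 1 || cfg$sleep$duration > 12)
    stop("config error: sleep duration must be in [1, 12] hours",
         call. = FALSE)
  probs <- unlist(cfg$keys)
  if (any(probs < 0) || sum(probs) > 1)
    stop("config error: key-category probabilities must lie in [0,1] and sum to at most 1",
         call. = FALSE)
  if (length(cfg$circadian$profile) != 24L || any(cfg$circadian$profile < 0))
    stop("config error: circadian profile must be 24 nonnegative values",
         call. = FALSE)
  structure(cfg, class = "cohort_config")
}

#' Generate a synthetic cohort
#'
#' Draws the full keystroke, accelerometer, task, and PHQ streams for every
#' participant described by `config`, plus the planted ground truth.
#' Hourly keystroke counts are Poisson with a circadian intensity that is
#' zero inside the jittered nightly sleep window; counts are partitioned
#' into typing sessions (bursts) whose interkey delays are lognormal with a
#' participant-specific median; each session carries a hand mode and
#' accelerometer samples drawn around the session's orientation centroid.
#' The stream is a deterministic function of `config` (including its seed).
#'
#' @param config a [cohort_config()].
#' @return list with data frames `keystrokes`, `accel`, `tasks`, `phq`, and
#'   `truth`, an object of class `cohort_truth` holding per participant the
#'   latent state `z`, the median interkey delay `mu_ikd`, the nightly
#'   sleep-onset hours, a `days x 24` logical sleep matrix, and per-task
#'   latent expected completion times.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  n_p <- config$n_participants
  pids <- sprintf("P%03d", seq_len(n_p))
  dates <- config$origin + seq_len(config$n_days) - 1L
  weekend <- format(dates, "%u") %in% c("6", "7")
  ks_list <- vector("list", n_p); ac_list <- vector("list", n_p)
  tk_list <- vector("list", n_p); ph_list <- vector("list", n_p)
  truth <- vector("list", n_p); names(truth) <- pids

  for (p in seq_len(n_p)) {
    pid <- pids[p]
    z <- rnorm(1L)        # typing/mood latent state
    z_reg <- rnorm(1L)    # independent sleep-regularity latent state
    g <- .generate_participant(pid, z, z_reg, dates, weekend, config)
    ks_list[[p]] <- g$keystrokes; ac_list[[p]] <- g$accel
    tk_list[[p]] <- g$tasks; ph_list[[p]] <- g$phq
    truth[[p]] <- g$truth
  }
  tasks <- do.call(rbind, tk_list)
  truth_obj <- structure(list(
    participants = truth,
    tasks = tasks[, c("participant_id", "timestamp", "task_number",
                      "expected_time")],
    dates = dates), class = "cohort_truth")
  tasks$task_number <- NULL; tasks$expected_time <- NULL
  list(keystrokes = do.call(rbind, ks_list),
       accel = do.call(rbind, ac_list),
       tasks = tasks,
       phq = do.call(rbind, ph_list),
       truth = truth_obj)
}

# Single-participant stream, fully vectorized.
.generate_participant <- function(pid, z, z_reg, dates, weekend, cfg) {
  n_days <- length(dates)
  day0 <- as.POSIXct(paste(dates[1L], "00:00:00"), tz = "UTC")

  ## --- planted sleep -------------------------------------------------
  sl <- cfg$sleep
  onset <- round(rnorm(1L, sl$onset_mean, sl$onset_sd)) %% 24
  jit_sd <- sl$jitter_sd * exp(sl$jitter_link * z_reg)
  # Nights are indexed 0..n_days-1; night d starts on day d.  Night -1
  # covers the first morning.  Onset jitter is in whole hours (the grid is
  # hourly); duration is fixed so truth stays one contiguous block.
  nights <- seq(-1L, n_days - 1L)
  jitter <- pmin(pmax(round(rnorm(length(nights), 0, jit_sd)),
                      -sl$jitter_max), sl$jitter_max)
  sleep_start <- 24 * nights + onset + jitter          # absolute hour index
  sleep_hours <- unlist(lapply(seq_along(nights), function(k)
    seq(sleep_start[k], length.out = sl$duration)))
  sleep_hours <- sleep_hours[sleep_hours >= 0 & sleep_hours < 24 * n_days]
  asleep <- rep(FALSE, 24 * n_days)
  asleep[sleep_hours + 1L] <- TRUE
  sleep_matrix <- matrix(asleep, nrow = n_days, ncol = 24, byrow = TRUE,
                         dimnames = list(as.character(dates), NULL))

  ## --- hourly intensities and counts ---------------------------------
  circ <- cfg$circadian
  prof <- circ$profile / sum(circ$profile)
  lam_day <- circ$keystrokes_per_day * prof        # per-hour expectation
  lam <- rep(lam_day, n_days) *
    rep(ifelse(weekend, circ$weekend_factor, 1), each = 24L)
  lam[asleep] <- 0
  counts <- rpois(length(lam), lam)

  ## --- keystrokes, partitioned into sessions -------------------------
  N <- sum(counts)
  ikd_mu <- cfg$ikd$median_ref *
    exp(cfg$ikd$latent_coef * z + cfg$ikd$participant_sd * rnorm(1L))
  cell_of <- rep.int(seq_along(counts), counts)      # absolute-hour cell
  first_in_cell <- c(TRUE, diff(cell_of) != 0L)
  new_session <- first_in_cell | runif(N) < 1 / cfg$session$mean_size
  sess_idx <- cumsum(new_session)
  n_sess <- sess_idx[N]
  sess_first <- which(new_session)
  sess_size <- diff(c(sess_first, N + 1L))
  # Session start: uniform in the first 80% of its hour; keystrokes follow
  # at cumulative lognormal interkey delays.
  sess_cell <- cell_of[sess_first]
  sess_start <- (sess_cell - 1L) * 3600 + runif(n_sess) * 3600 * 0.8
  ikd <- rlnorm(N, log(ikd_mu), cfg$ikd$sdlog)
  ikd[sess_first] <- 0
  cs <- cumsum(ikd)
  offset <- cs - cs[sess_first][sess_idx]
  t_sec <- sess_start[sess_idx] + offset
  kprobs <- unlist(cfg$keys)
  kcat <- sample(c(names(kprobs), "alphanumeric"), N, replace = TRUE,
                 prob = c(kprobs, 1 - sum(kprobs)))
  sess_id <- sprintf("%s_s%05d", pid, sess_idx)
  sess_hand <- ifelse(runif(n_sess) < cfg$session$two_hand_prob,
                      "two", "one")
  keystrokes <- data.frame(
    participant_id = pid,
    timestamp = day0 + t_sec,
    key_category = kcat,
    press_duration = rlnorm(N, cfg$press$meanlog, cfg$press$sdlog),
    session_id = sess_id,
    hand_mode = sess_hand[sess_idx],
    stringsAsFactors = FALSE)

  ## --- accelerometer -------------------------------------------------
  ori <- cfg$orientation
  k <- sample(ori$k_range, 1L)
  cent <- .orientation_library[sample(nrow(.orientation_library), k), ,
                               drop = FALSE]
  # Markov chain over centroids across sessions.
  cl <- integer(n_sess)
  if (n_sess) {
    cl[1L] <- sample.int(k, 1L)
    stay <- runif(n_sess) < ori$stay_prob
    jump <- sample.int(k, n_sess, replace = TRUE)
    for (s in seq_len(n_sess)[-1L])
      cl[s] <- if (stay[s]) cl[s - 1L] else jump[s]
  }
  m <- ori$samples_per_session
  acc_sess <- rep(seq_len(n_sess), each = m)
  acc_t <- sess_start[acc_sess] + (rep(seq_len(m), n_sess) - 1) * 1.5
  accel <- data.frame(
    participant_id = pid,
    session_id = sprintf("%s_s%05d", pid, acc_sess),
    timestamp = day0 + acc_t,
    x = cent[cl[acc_sess], "x"] + rnorm(n_sess * m, 0, ori$within_sd),
    y = cent[cl[acc_sess], "y"] + rnorm(n_sess * m, 0, ori$within_sd),
    z = cent[cl[acc_sess], "z"] + rnorm(n_sess * m, 0, ori$within_sd),
    stringsAsFactors = FALSE)
  rownames(accel) <- NULL

  ## --- tasks ----------------------------------------------------------
  tk <- cfg$task
  n_t <- min(tk$n_tasks, n_days - 2L)
  task_days <- unique(round(seq(2, n_days - 1, length.out = n_t)))
  n_t <- length(task_days)
  task_hour <- pmin(pmax(round(rnorm(n_t, tk$hour_mean, tk$hour_sd)), 9), 21)
  expected <- tk$baseline * tk$decay^(seq_len(n_t) - 1L) *
    exp(tk$latent_coef * z + tk$regularity_coef * z_reg)
  tasks <- data.frame(
    participant_id = pid,
    timestamp = day0 + ((task_days - 1L) * 24 + task_hour) * 3600 +
      runif(n_t) * 3000,
    completion_time = expected * exp(tk$noise_sd * rnorm(n_t)),
    n_errors = rpois(n_t, tk$error_rate),
    layout_variant = sample.int(12L, n_t, replace = TRUE),
    task_number = seq_len(n_t),
    expected_time = expected,
    stringsAsFactors = FALSE)

  ## --- PHQ ------------------------------------------------------------
  ph <- cfg$phq
  tot <- pmin(pmax(round(
    ph$mean + ph$sd * (ph$latent_cor * z +
                         sqrt(1 - ph$latent_cor^2) * rnorm(ph$n_reports))),
    0), 24)
  items <- t(vapply(tot, .spread_phq_items, integer(8L)))
  phq <- data.frame(
    participant_id = pid,
    timestamp = day0 + (round(seq(3, n_days - 1,
                                  length.out = ph$n_reports)) * 24 + 18) * 3600,
    stringsAsFactors = FALSE)
  phq[paste0("item", 1:8)] <- as.data.frame(items)
  phq$total <- tot

  list(keystrokes = keystrokes, accel = accel,
       tasks = tasks, phq = phq,
       truth = list(z = z, z_reg = z_reg, mu_ikd = ikd_mu, onset = onset,
                    jitter = jitter, sleep_matrix = sleep_matrix,
                    orientation_centroids = cent,
                    session_cluster = cl))
}

# Distribute a PHQ total over 8 items each capped at 3.
.spread_phq_items <- function(total, n_items = 8L, cap = 3L) {
  items <- integer(n_items)
  for (i in seq_len(total)) {
    open <- which(items < cap)
    if (!length(open)) break
    pick <- if (length(open) == 1L) open else sample(open, 1L)
    items[pick] <- items[pick] + 1L
  }
  items
}

#' Write cohort streams to a directory
#'
#' Serializes the four record streams (CSV) and the ground truth (JSON)
#' produced by [generate_cohort()].
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory, created if needed.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_records(cohort$keystrokes, file.path(dir, "keystrokes.csv"),
                "keystroke")
  write_records(cohort$accel, file.path(dir, "accel.csv"), "accel")
  write_records(cohort$tasks, file.path(dir, "tasks.csv"), "task")
  write_records(cohort$phq, file.path(dir, "phq.csv"), "phq")
  tr <- cohort$truth
  tr_json <- list(
    dates = as.character(tr$dates),
    participants = lapply(tr$participants, function(t)
      list(z = t$z, mu_ikd = t$mu_ikd, onset = t$onset,
           jitter = t$jitter,
           sleep_matrix = unname(apply(t$sleep_matrix, 1L, as.integer,
                                       simplify = FALSE)))),
    tasks = tr$tasks)
  jsonlite::write_json(tr_json, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, POSIXt = "ISO8601")
  invisible(dir)
}
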