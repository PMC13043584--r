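test_that("the generator is deterministic and validates its config", {
  cfg <- cohort_config(n_participants = 2, n_days = 8, seed = 99)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  expect_error(cohort_config(n_participants = 0), "config error")
  expect_error(cohort_config(sleep = list(duration = 15)), "config error")
  expect_error(cohort_config(keys = list(backspace = 1.5)), "config error")
  expect_error(cohort_config(circadian = list(profile = 1:5)),
               "config error")
})

test_that("a jitter-free sleep window contains no keystrokes", {
  cfg <- cohort_config(n_participants = 2, n_days = 10, seed = 5,
                       sleep = list(onset_mean = 23, onset_sd = 0,
                                    jitter_sd = 0, duration = 8))
  co <- generate_cohort(cfg)
  hrs <- as.integer(format(co$keystrokes$timestamp, "%H", tz = "UTC"))
  # window 23:00 - 07:00
  expect_false(any(hrs >= 23 | hrs < 7))
  # planted truth matches: all sleep cells fall in the window
  for (tr in co$truth$participants) {
    asleep_hours <- which(colSums(tr$sleep_matrix) > 0) - 1L
    expect_true(all(asleep_hours >= 23 | asleep_hours < 7))
  }
})

test_that("ground truth sleep is one contiguous block per night", {
  co <- small_cohort()
  for (tr in co$truth$participants) {
    flat <- as.integer(t(tr$sleep_matrix))
    runs <- rle(flat)
    # number of sleep runs is at most the number of nights + 1 (edges)
    n_nights <- nrow(tr$sleep_matrix) + 1L
    expect_lte(sum(runs$values == 1L), n_nights)
    # every sleep run is at most the configured duration
    expect_lte(max(runs$lengths[runs$values == 1L]), 8L)
  }
})

test_that("hour-of-day histogram bottoms out inside the sleep window", {
  co <- small_cohort()
  hrs <- as.integer(format(co$keystrokes$timestamp, "%H", tz = "UTC"))
  hist24 <- tabulate(hrs + 1L, nbins = 24L)
  min_hour <- which.min(hist24) - 1L
  # the pooled sleep windows (onset ~23, 8 h) cover 21:00-09:00 at most
  expect_true(min_hour >= 21 || min_hour < 9)
})

test_that("participant median interkey delays recover the planted medians", {
  co <- small_cohort()
  sp <- split(co$keystrokes, co$keystrokes$participant_id)
  sp <- sp[vapply(sp, nrow, integer(1)) >= 2000L]
  expect_gte(length(sp), 3L)
  for (pid in names(sp)) {
    ev <- sp[[pid]]
    ord <- order(ev$session_id, ev$timestamp)
    ev <- ev[ord, ]
    same <- ev$session_id[-1L] == ev$session_id[-nrow(ev)]
    dt <- as.numeric(diff(ev$timestamp), units = "secs")[same]
    expect_equal(median(dt), co$truth$participants[[pid]]$mu_ikd,
                 tolerance = 0.05)
  }
})

test_that("weekend modulation of 1 leaves weekday and weekend rates equal", {
  cfg <- cohort_config(n_participants = 1, n_days = 200, seed = 17,
                       circadian = list(weekend_factor = 1))
  co <- generate_cohort(cfg)
  day <- as.Date(co$keystrokes$timestamp, tz = "UTC")
  totals <- table(day)
  wd <- format(as.Date(names(totals)), "%u") %in% c("6", "7")
  p <- t.test(as.vector(totals)[wd], as.vector(totals)[!wd])$p.value
  expect_gt(p, 0.01)
})

test_that("task times follow the practice-decay model", {
  # decay < 1, no noise, no latent effect: strictly decreasing times
  cfg <- cohort_config(n_participants = 3, n_days = 20, seed = 31,
                       task = list(decay = 0.9, noise_sd = 0,
                                   latent_coef = 0, error_rate = 0))
  co <- generate_cohort(cfg)
  for (pid in unique(co$tasks$participant_id)) {
    tt <- co$tasks$completion_time[co$tasks$participant_id == pid]
    expect_true(all(diff(tt) < 0))
  }
  expect_true(all(co$tasks$n_errors == 0L))

  # decay = 1, no latent effect: group means equal within sampling error
  # (ANOVA p is uniform under this null, so aggregate over three seeds)
  ps <- vapply(c(33, 34, 35), function(s) {
    cfg2 <- cohort_config(n_participants = 50, n_days = 20, seed = s,
                          task = list(decay = 1, latent_coef = 0,
                                      noise_sd = 0.2))
    co2 <- generate_cohort(cfg2)
    co2$tasks$task_number <- ave(seq_len(nrow(co2$tasks)),
                                 co2$tasks$participant_id, FUN = seq_along)
    fit <- aov(log(completion_time) ~ factor(task_number),
               data = co2$tasks)
    summary(fit)[[1]][["Pr(>F)"]][1]
  }, numeric(1))
  expect_gte(sum(ps > 0.01), 2L)
})

test_that("PHQ reports respect item bounds and correlate with the latent state", {
  co <- small_cohort()
  items <- as.matrix(co$phq[paste0("item", 1:8)])
  expect_true(all(items %in% 0:3))
  expect_equal(rowSums(items), co$phq$total, ignore_attr = TRUE)
  z <- vapply(co$truth$participants, function(t) t$z, numeric(1))
  phq_mean <- tapply(co$phq$total, co$phq$participant_id, mean)
  expect_gt(cor(z, phq_mean[names(z)]), 0)
})

test_that("cohort streams write and re-read as valid records", {
  co <- small_cohort()
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(dir,
    c("keystrokes.csv", "accel.csv", "tasks.csv", "phq.csv",
      "ground_truth.json")))))
  tk <- read_records(file.path(dir, "tasks.csv"), "task")
  expect_equal(nrow(tk), nrow(co$tasks))
})
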