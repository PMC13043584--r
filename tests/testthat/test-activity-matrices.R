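test_that("matrix construction trims edge days and computes hourly medians", {
  # keystrokes on 5 calendar days -> 3 rows after trimming
  offs <- c(0, 86400 * 1 + 3600 * 10 + c(0, 0.1, 0.4),   # day 2, 10:00
            86400 * 2 + 3600 * 15,                        # day 3, single key
            86400 * 3 + 3600 * 8 + c(0, 0.2),             # day 4
            86400 * 4)
  ks <- sessionize(make_keystrokes(offs))$events
  m <- build_activity_matrices(ks)
  expect_equal(nrow(m$counts$values), 3L)
  expect_identical(m$counts$dates, m$speed$dates)
  # day 2 hour 10: interkey delays 0.1 and 0.3 -> median 0.2
  expect_equal(m$counts$values[1L, 11L], 3)
  expect_equal(m$speed$values[1L, 11L], 0.2, tolerance = 1e-6)
  # single keystroke hour: count 1, no transition -> speed 0
  expect_equal(m$counts$values[2L, 16L], 1)
  expect_equal(m$speed$values[2L, 16L], 0)
  expect_error(build_activity_matrices(make_keystrokes(c(0, 86400))),
               "insufficient data")
})

test_that("speed cells only use alphanumeric-to-alphanumeric transitions", {
  offs <- 86400 + 3600 * 12 + c(0, 0.1, 0.2, 0.3)
  ks <- make_keystrokes(c(0, offs, 86400 * 2),
                        key_category = c("alphanumeric", "alphanumeric",
                                         "backspace", "alphanumeric",
                                         "alphanumeric", "alphanumeric"))
  ks <- sessionize(ks)$events
  m <- build_activity_matrices(ks)
  # transitions within day 2 hour 12: aa pairs are (1,2)? no - key2 is
  # backspace, so only the 0.3-0.2 = 0.1 s pair counts
  expect_equal(m$speed$values[1L, 13L], 0.1, tolerance = 1e-6)
})

test_that("participant filter applies inclusive 20% / 50-keystroke bounds", {
  mk <- function(mat) activity_matrix(mat, as.Date("2023-03-07") +
                                        seq_len(nrow(mat)) - 1, "P1", "count")
  # exactly 5 active hours of 10 keystrokes: 5/24 >= 0.2, median 50 -> keep
  m1 <- mk(matrix(rep(c(rep(10, 5), rep(0, 19)), 4), nrow = 4,
                  byrow = TRUE))
  f1 <- participant_filter(m1)
  expect_true(f1$keep)
  # 4 active hours -> active-hour fraction fails
  m2 <- mk(matrix(rep(c(rep(20, 4), rep(0, 20)), 4), nrow = 4,
                  byrow = TRUE))
  f2 <- participant_filter(m2)
  expect_false(f2$keep)
  expect_true("active-hour fraction" %in% f2$reasons)
  # median is robust: daily totals 10, 10, 400 -> median 10 < 50
  m3 <- mk(rbind(c(rep(2, 5), rep(0, 19)), c(rep(2, 5), rep(0, 19)),
                 c(rep(80, 5), rep(0, 19))))
  f3 <- participant_filter(m3)
  expect_false(f3$keep)
  expect_true("median daily keystrokes" %in% f3$reasons)
})

test_that("week filter removes days in no passing window", {
  dates <- as.Date("2023-03-06") + 0:13
  active_day <- c(rep(10, 6), rep(0, 18))
  mk2 <- function(mat) {
    counts <- activity_matrix(mat, dates[seq_len(nrow(mat))], "P1", "count")
    speed <- activity_matrix(mat * 0.01, dates[seq_len(nrow(mat))], "P1",
                             "speed")
    list(counts = counts, speed = speed)
  }
  # 14 uniformly active days: every window passes, nothing removed
  m <- mk2(matrix(rep(active_day, 14), nrow = 14, byrow = TRUE))
  wf <- week_filter(m$counts, m$speed)
  expect_true(wf$keep)
  expect_equal(nrow(wf$counts$values), 14L)
  expect_length(wf$removed_dates, 0L)
  # 7 active (exactly 5 active hours, the 20% boundary) then 7 empty
  # days: enumerating the 8 windows by hand, window 1 passes (frac
  # 5/24 = 0.2083, median 50) but window 2 already fails (6/7 * 5/24 =
  # 0.179 < 0.2), as do all later ones; so days 8-14 lie in no passing
  # window and are removed; 7 days remain
  edge_day <- c(rep(10, 5), rep(0, 19))
  m2 <- mk2(rbind(matrix(rep(edge_day, 7), nrow = 7, byrow = TRUE),
                  matrix(0, 7, 24)))
  wf2 <- week_filter(m2$counts, m2$speed)
  expect_true(wf2$keep)
  expect_equal(nrow(wf2$counts$values), 7L)
  expect_equal(wf2$removed_dates, dates[8:14])
  # fewer than 7 surviving days: participant dropped (boundary-level
  # activity on only 6 days means no 7-day window can pass)
  m3 <- mk2(rbind(matrix(rep(edge_day, 6), nrow = 6, byrow = TRUE),
                  matrix(0, 8, 24)))
  wf3 <- week_filter(m3$counts, m3$speed)
  expect_false(wf3$keep)
  expect_null(wf3$counts)
})

test_that("week filter windows use within-window statistics (hand-checked)", {
  # days 1-7 active, day 8 empty, days 9-14 active: windows 2..8 each
  # contain the empty day but 6 active days; mean active fraction
  # 6/7 * 6/24 = 0.214 >= 0.2 and median daily total 60 >= 50, so every
  # window passes and all 14 days survive
  dates <- as.Date("2023-03-06") + 0:13
  active_day <- c(rep(10, 6), rep(0, 18))
  mat <- matrix(rep(active_day, 14), nrow = 14, byrow = TRUE)
  mat[8L, ] <- 0
  counts <- activity_matrix(mat, dates, "P1", "count")
  speed <- activity_matrix(mat * 0, dates, "P1", "speed")
  wf <- week_filter(counts, speed)
  expect_equal(nrow(wf$counts$values), 14L)
})

test_that("filters are monotone in their thresholds", {
  set.seed(11)
  for (rep in 1:20) {
    mat <- matrix(rpois(24 * 10, lambda = runif(1, 0.5, 4)), nrow = 10)
    m <- activity_matrix(mat, as.Date("2023-01-02") + 0:9, "P", "count")
    base <- participant_filter(m, 0.2, 50)$keep
    stricter <- participant_filter(m, 0.3, 80)$keep
    if (!base) expect_false(stricter)
  }
})

test_that("normalization divides by the grand total", {
  m <- activity_matrix(matrix(2, 3, 24), as.Date("2023-01-02") + 0:2,
                       "P1", "count")
  nm <- normalize_counts(m)
  expect_equal(sum(nm$values), 1)
  expect_true(all(nm$values == 1 / (3 * 24)))
  single <- matrix(0, 3, 24); single[2, 5] <- 7
  ns <- normalize_counts(activity_matrix(single,
                                         as.Date("2023-01-02") + 0:2,
                                         "P1", "count"))
  expect_equal(ns$values[2, 5], 1)
  expect_equal(sum(ns$values), 1)
  expect_error(normalize_counts(activity_matrix(matrix(0, 3, 24),
                                                as.Date("2023-01-02") + 0:2,
                                                "P1", "count")),
               "degenerate")
})
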