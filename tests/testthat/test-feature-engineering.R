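make_accel <- function(session_ids, centers, sd = 0.02, n_per = 6,
                       origin = as.POSIXct("2023-03-06 12:00:00",
                                           tz = "UTC")) {
  rows <- lapply(seq_along(session_ids), function(i) {
    data.frame(participant_id = "P1", session_id = session_ids[i],
               timestamp = origin + (i - 1) * 600 + seq_len(n_per),
               x = rnorm(n_per, centers[i, 1], sd),
               y = rnorm(n_per, centers[i, 2], sd),
               z = rnorm(n_per, centers[i, 3], sd),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

test_that("orientation clustering recovers well-separated groups", {
  set.seed(9)
  c1 <- c(0, -0.6, -0.1); c2 <- c(0.8, -0.6, -0.1)  # 0.8 g apart in x
  truth <- rep(c(1, 2), each = 10)
  centers <- rbind(matrix(c1, 10, 3, byrow = TRUE),
                   matrix(c2, 10, 3, byrow = TRUE))
  acc <- make_accel(sprintf("s%02d", 1:20), centers, sd = 0.02)
  model <- fit_orientation_model(acc, seed = 3)
  expect_equal(model$nClusters, 2L)
  found <- model$assignment[sprintf("s%02d", 1:20)]
  expect_equal(length(unique(found[truth == 1])), 1L)
  expect_equal(length(unique(found[truth == 2])), 1L)
  expect_false(found[1] == found[11])
  # deterministic under a fixed seed
  expect_identical(model$centroids,
                   fit_orientation_model(acc, seed = 3)$centroids)
  # nearest-centroid prediction is consistent with the assignment
  reps <- session_representatives(acc)
  expect_equal(unname(predict(model, reps)),
               unname(model$assignment[reps$session_id]))
})

test_that("degenerate orientation inputs fall back gracefully", {
  acc1 <- make_accel("only", matrix(c(0, -0.6, 0), 1, 3))
  expect_warning(m1 <- fit_orientation_model(acc1), "single-cluster")
  expect_equal(m1$nClusters, 1L)
})

test_that("typing features compute rates, medians, and variances", {
  ks <- make_keystrokes(c(0, 0.1, 0.3, 0.6, 1.0, 3, 3.1, 3.2, 3.3, 3.4),
                        key_category = c("alphanumeric", "alphanumeric",
                                         "backspace", "backspace",
                                         "alphanumeric", rep("alphanumeric", 5)),
                        session_id = rep(c("a", "b"), each = 5),
                        hand_mode = "two")
  tf <- typing_features(ks)
  expect_equal(tf$nSessions, 2L)
  expect_equal(tf$avgNkeypresses, 5)
  expect_equal(tf$backspaceRate, 0.2)
  expect_equal(tf$autocorrectRate, 0)
  expect_equal(tf$medianPressDuration, 0.08)
  expect_false(tf$typing_speed_missing)
  # aa transitions: session a has 0-0.1 only; session b has 4 gaps of 0.1
  expect_equal(tf$typingSpeed, 0.1, tolerance = 1e-6)
  # identical interkey delays give zero variance
  ks2 <- make_keystrokes(seq(0, 0.9, by = 0.1), session_id = "s")
  expect_equal(typing_features(ks2)$varAAIKD, 0, tolerance = 1e-12)
  # no two-handed session: typing speed undefined and flagged
  ks3 <- make_keystrokes(c(0, 0.1, 0.2), session_id = "s",
                         hand_mode = "one")
  tf3 <- typing_features(ks3)
  expect_true(tf3$typing_speed_missing)
  expect_true(is.na(tf3$typingSpeed))
})

test_that("upright and non-upright follow the axis bounds", {
  # representative (0.1, -0.3, 0.05): upright
  # representative (0.6, 0.1, 0.2): non-upright
  set.seed(4)
  sess <- data.frame(session_id = c("u", "n"), participant_id = "P1",
                     start = as.POSIXct("2023-03-06 12:00:00",
                                        tz = "UTC") + c(0, 600),
                     end = as.POSIXct("2023-03-06 12:05:00",
                                      tz = "UTC") + c(0, 600),
                     hand_mode = "two", n_keystrokes = 30L)
  acc <- make_accel(c("u", "n"), rbind(c(0.1, -0.3, 0.05),
                                       c(0.6, 0.1, 0.2)), sd = 1e-6)
  model <- structure(list(centroids = matrix(c(0, -0.5, 0), 1, 3,
                                             dimnames = list(NULL,
                                                             c("x", "y", "z"))),
                          nClusters = 1L), class = "orientation_model")
  af <- accel_features(acc, sess, model)
  expect_equal(af$fraction_upright, 0.5)
  # nighttime non-upright over prior week: session n starting 01:00
  night_sess <- sess
  night_sess$start <- as.POSIXct("2023-03-06 01:00:00", tz = "UTC") +
    c(0, 600)
  af2 <- accel_features(acc, sess, model, prior_accel = acc,
                        prior_sessions = night_sess)
  expect_equal(af2$fraction_nighttime_nonUpright_sessions, 0.5)
  expect_false(af2$no_nighttime_sessions)
})

test_that("cluster transitions are counted per session sequence", {
  set.seed(5)
  cent <- rbind(c(0, -0.6, -0.1), c(0.8, 0, 0.3))
  # session orientation sequence A, A, B, A -> 2 transitions over 4
  acc <- make_accel(c("s1", "s2", "s3", "s4"),
                    cent[c(1, 1, 2, 1), ], sd = 0.01)
  sess <- data.frame(session_id = paste0("s", 1:4), participant_id = "P1",
                     start = as.POSIXct("2023-03-06 12:00:00",
                                        tz = "UTC") + (0:3) * 600,
                     end = as.POSIXct("2023-03-06 12:05:00",
                                      tz = "UTC") + (0:3) * 600,
                     hand_mode = "two", n_keystrokes = 30L)
  model <- structure(list(centroids = `colnames<-`(cent, c("x", "y", "z")),
                          nClusters = 2L), class = "orientation_model")
  af <- accel_features(acc, sess, model)
  expect_equal(af$normalized_n_cluster_transitions, 0.5)
  expect_equal(af$nClusters, 2L)
})

test_that("circular variance spans its 0-1 range", {
  one_hour <- rep(0, 24); one_hour[4] <- 5
  expect_equal(circular_variance(one_hour), 0)
  expect_equal(circular_variance(rep(1, 24)), 1)
  expect_true(is.na(circular_variance(rep(0, 24))))
  mid <- circular_variance(c(rep(1, 12), rep(0, 12)))
  expect_gt(mid, 0); expect_lt(mid, 1)
})

test_that("regularity features respond to identical versus varying days", {
  dates <- as.Date("2023-03-06") + 0:9
  row <- c(rep(0, 7), rep(0.02, 10), rep(0, 7))
  W <- matrix(rep(row, 10), nrow = 10, byrow = TRUE,
              dimnames = list(as.character(dates), NULL))
  fit <- structure(list(Wstar = W, dates = dates), class = "torus_svd")
  sleep <- structure(list(periods = data.frame(
    period = 0:9, start_day = 1:10, full = TRUE, sleep_hours = 7L,
    date = dates)), class = "sleep_labels")
  task_time <- as.POSIXct("2023-03-14 12:00:00", tz = "UTC")
  rf <- regularity_features(fit, sleep, task_time)
  expect_false(rf$insufficient_regularity_rows)
  expect_equal(rf$medianCosineSimilarity_1diff, 1)
  expect_equal(rf$medianCosineSimilarity_4diff, 1)
  expect_equal(rf$varCircVar, 0)
  expect_equal(rf$medAmt_noActivity, 7)
  expect_equal(rf$varAmt_noActivity, 0)
  # too few rows in the look-back window: flagged
  early <- as.POSIXct("2023-03-08 12:00:00", tz = "UTC")
  expect_true(regularity_features(fit, sleep,
                                  early)$insufficient_regularity_rows)
  # cosine similarity bounded in [-1, 1] on arbitrary rows
  set.seed(31)
  W2 <- matrix(runif(240), nrow = 10,
               dimnames = list(as.character(dates), NULL))
  fit2 <- structure(list(Wstar = W2, dates = dates), class = "torus_svd")
  rf2 <- regularity_features(fit2, sleep, task_time)
  expect_true(rf2$medianCosineSimilarity_1diff >= -1 &&
                rf2$medianCosineSimilarity_1diff <= 1)
})

test_that("gm/sc centering reconstructs raw values and zero-centres within subject", {
  tab <- data.frame(participant_id = c("a", "a", "b"),
                    typingSpeed = c(1, 3, 5),
                    backspaceRate = c(0.1, 0.2, 0.4))
  cc <- center_features(tab)
  expect_equal(cc$typingSpeed_gm, c(2, 2, 5))
  expect_equal(cc$typingSpeed_sc, c(-1, 1, 0))
  expect_equal(cc$typingSpeed_gm + cc$typingSpeed_sc, tab$typingSpeed)
  # single-task participant has sc exactly zero
  expect_equal(cc$backspaceRate_sc[3], 0)
  # sc columns are zero-mean within every participant
  for (pid in c("a", "b"))
    expect_lt(abs(mean(cc$typingSpeed_sc[cc$participant_id == pid])),
              1e-10)
})

test_that("the candidate predictor inventory has 36 columns (26 without regularity)", {
  expect_length(candidate_features(TRUE), 36L)
  expect_length(candidate_features(FALSE), 26L)
  expect_true(all(grepl("_(gm|sc)$", candidate_features())))
})

test_that("a cohort feature table carries complete rows with sane ranges", {
  co <- small_cohort()
  ft <- build_feature_table(co$keystrokes, co$accel, co$tasks, seed = 2)
  tab <- ft$table
  expect_gt(nrow(tab), 10)
  expect_true(all(tab$n_window_keystrokes >= 20))
  rates <- tab[, c("backspaceRate", "autocorrectRate", "fraction_upright",
                   "fraction_nighttime_nonUpright_sessions")]
  expect_true(all(rates >= 0 & rates <= 1, na.rm = TRUE))
  expect_true(all(tab$typingSpeed > 0, na.rm = TRUE))
  cands <- candidate_features()
  expect_true(all(cands %in% names(tab)))
  # adjusted times joined from the task table
  expect_true(all(is.finite(tab$adjusted_time)))
})
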