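# Synthetic regression table with participant structure and a planted
# linear signal in a couple of features.
make_model_table <- function(n_participants = 20, tasks_each = 5,
                             beta = c(A = 1, B = 0.5), noise = 0.3,
                             seed = 101) {
  set.seed(seed)
  pid <- rep(sprintf("P%02d", seq_len(n_participants)), each = tasks_each)
  n <- length(pid)
  A <- rnorm(n); B <- rnorm(n); C <- rnorm(n); D <- rnorm(n)
  y <- beta["A"] * A + beta["B"] * B + noise * rnorm(n)
  data.frame(participant_id = pid, A = A, B = B, C = C, D = D,
             adjusted_time = y, stringsAsFactors = FALSE)
}

test_that("the cohort split is subject-disjoint and near 80/20 on both counts", {
  tab <- make_model_table(10, 5)
  plan <- split_cohort(tab, seed = 4)
  expect_length(intersect(plan$train, plan$test), 0L)
  expect_equal(length(plan$test), 2L)
  expect_equal(plan$task_fraction, 0.2, tolerance = 0.031)
  expect_identical(plan, split_cohort(tab, seed = 4))
  # unequal task counts still admit a dual 80/20 split
  tab2 <- make_model_table(20, 4)
  tab2 <- tab2[-(1:6), ]
  plan2 <- split_cohort(tab2, seed = 5)
  expect_lt(abs(plan2$task_fraction - 0.2), 0.031)
})

test_that("the MI estimator ranks dependence correctly", {
  set.seed(42)
  n <- 2000
  target <- rnorm(n)
  indep <- rnorm(n)
  copy <- target
  related <- target + 0.5 * rnorm(n)
  mi_indep <- mutual_information(indep, target)
  mi_copy <- mutual_information(copy, target)
  mi_related <- mutual_information(related, target)
  expect_lt(mi_indep, 0.05)          # within noise of zero
  expect_gt(mi_copy, mi_related)
  expect_gt(mi_related, mi_indep)
  tab <- data.frame(participant_id = "x", copy = copy, indep = indep,
                    related = related, adjusted_time = target)
  sel <- select_features_mi(tab, c("indep", "related", "copy"), k = 2)
  expect_equal(sel$feature[1], "copy")
  expect_equal(nrow(sel), 2L)
})

test_that("grouped tuning is deterministic and respects fold grouping", {
  tab <- make_model_table(12, 5)
  m1 <- tune_model(tab, c("A", "B", "C"), kind = "rf",
                   grid = list(num_trees = c(15L, 30L),
                               max_depth = c(2L, 4L), min_node = 3L),
                   seed = 9)
  m2 <- tune_model(tab, c("A", "B", "C"), kind = "rf",
                   grid = list(num_trees = c(15L, 30L),
                               max_depth = c(2L, 4L), min_node = 3L),
                   seed = 9)
  expect_identical(m1$params, m2$params)
  expect_identical(predict(m1, tab), predict(m2, tab))
})

test_that("a heavily penalized lasso collapses to the constant prediction", {
  tab <- make_model_table(15, 5, beta = c(A = 0.05, B = 0), noise = 1)
  m <- tune_model(tab, c("A", "B", "C", "D"), kind = "lasso",
                  grid = list(lambda = 50))
  pr <- predict(m, tab)
  expect_lt(diff(range(pr)), 1e-10)
  expect_equal(unname(pr[1]), mean(tab$adjusted_time), tolerance = 1e-6)
})

test_that("a forest can interpolate a noise-free target below the noise floor", {
  tab <- make_model_table(15, 6, beta = c(A = 2, B = 0), noise = 0)
  m <- tune_model(tab, c("A", "B"), kind = "rf",
                  grid = list(num_trees = 200L, max_depth = 0L,
                              min_node = 1L), seed = 2)
  pr <- predict(m, tab)
  eta <- 0.5
  expect_lt(sqrt(mean((tab$adjusted_time - pr)^2)), eta)
})

test_that("metrics follow their definitions", {
  expect_equal(evaluate_predictions(c(1, 2, 3), c(1, 2, 3)),
               list(rmse = 0, mae = 0, explained_variance = 1, r2 = 1))
  m <- evaluate_predictions(c(1, 2), c(0, 0))
  expect_equal(m$rmse, sqrt(2.5))
  expect_equal(m$mae, 1.5)
  # the mean predictor has R^2 = 0 on its own training rows
  tab <- make_model_table(8, 4)
  base <- tune_model(tab, c("A"), kind = "baseline_mean")
  ev <- evaluate_model(base, tab)
  expect_equal(ev$metrics$r2, 0, tolerance = 1e-12)
  expect_error(evaluate_predictions(numeric(0), numeric(0)), "empty")
})

test_that("attributions are additive and rank planted effects", {
  tab <- make_model_table(12, 5, beta = c(A = 5, B = 0.3), noise = 0.05)
  # constant model: all attributions zero
  base <- tune_model(tab, c("A", "B"), kind = "baseline_mean")
  at0 <- shapley_attribution(base, tab[1:10, ], tab)
  expect_equal(max(abs(at0$phi)), 0)
  # single-feature linear model: that feature carries all attribution
  lin <- tune_model(tab, c("A", "B"), kind = "lasso",
                    grid = list(lambda = 1e-4))
  at1 <- shapley_attribution(lin, tab[1:20, ], tab, seed = 3)
  expect_equal(rowSums(at1$phi), at1$prediction - at1$base_value,
               tolerance = 1e-8)
  expect_equal(at1$ranking$feature[1], "A")
  share <- at1$ranking$mean_abs_phi[1] / sum(at1$ranking$mean_abs_phi)
  expect_gt(share, 0.9)
  # forest model with a dominant feature ranks it first
  rf <- tune_model(tab, c("A", "B", "C"), kind = "rf",
                   grid = list(num_trees = 50L, max_depth = 4L,
                               min_node = 3L), seed = 5)
  at2 <- shapley_attribution(rf, tab[1:15, ], tab, seed = 4)
  expect_equal(at2$ranking$feature[1], "A")
  expect_equal(rowSums(at2$phi), at2$prediction - at2$base_value,
               tolerance = 1e-8)
})

test_that("the paired sign-flip test behaves at both extremes", {
  set.seed(19)
  r <- rnorm(100)
  same <- permutation_test_residuals(r, r, n_perm = 500)
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  # planted uniform improvement of 1 SD over 200 pairs
  a <- rnorm(200, 0, 1) + 2
  b <- a - 1
  better <- permutation_test_residuals(a, b, n_perm = 999, seed = 8)
  expect_lt(better$p_value, 0.01)
  expect_warning(permutation_test_residuals(r, r, n_perm = 50), "100")
})

test_that("the PHQ augmentation is a controlled no-op without signal", {
  co <- small_cohort()
  ft <- build_feature_table(co$keystrokes, co$accel, co$tasks, seed = 6)
  tab <- ft$table[complete.cases(ft$table[c("typingSpeed_gm",
                                            "backspaceRate_gm",
                                            "adjusted_time")]), ]
  pids <- unique(tab$participant_id)
  train <- tab[tab$participant_id %in% pids[-1], ]
  test <- tab[tab$participant_id == pids[1], ]
  grid <- list(num_trees = 15L, max_depth = 4L, min_node = 5L)
  exp1 <- phq_experiment(train, test,
                         c("typingSpeed_gm", "backspaceRate_gm"),
                         co$phq, grid = grid, seed = 11)
  # base model inside the experiment equals a separately tuned base model
  sep <- tune_model(train, c("typingSpeed_gm", "backspaceRate_gm"),
                    kind = "rf", grid = grid, seed = 11)
  expect_equal(exp1$base$metrics, evaluate_model(sep, test)$metrics,
               tolerance = 1e-12)
  expect_true(all(c("rmse", "mae") %in% names(exp1$augmented$metrics)))
  expect_equal(exp1$phq_feature, "phq_mean")
  exp2 <- phq_experiment(train, test,
                         c("typingSpeed_gm", "backspaceRate_gm"),
                         co$phq, grid = grid, seed = 11,
                         items = "first_two")
  expect_equal(exp2$phq_feature, "phq_first2_mean")
})
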