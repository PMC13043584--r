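# Predictive modeling of practice-adjusted task times: subject-wise 80/20
# split, mutual-information filter selection (top 10 of 36), and four
# model families tuned by grid search under participant-grouped 3-fold
# cross-validation, compared against a training-mean baseline.

#' Subject-wise train/test split
#'
#' Draws random participant partitions (seeded) until both the participant
#' fraction and the task fraction of the test side are within `tol` of
#' `fraction`; returns the best draw found if none is admissible within
#' `max_draws`.  Train and test participant sets are disjoint by
#' construction.
#'
#' @param table feature table (one row per task) with `participant_id`.
#' @param fraction target test fraction (default 0.2).
#' @param seed RNG seed.
#' @param tol admissible deviation of either fraction (default 0.03).
#' @param max_draws bound on random draws (default 1000).
#' @return list of class `split_plan`: `train`, `test` (participant ids),
#'   `participant_fraction`, `task_fraction`, `admissible`.
#' @export
split_cohort <- function(table, fraction = 0.2, seed = 1L, tol = 0.03,
                         max_draws = 1000L) {
  pids <- sort(unique(table$participant_id))
  n <- length(pids)
  if (n < 5L) stop("need at least 5 participants to split", call. = FALSE)
  n_test <- max(1L, round(fraction * n))
  counts <- table(table$participant_id)
  .with_seed(seed, {
    best <- NULL; best_err <- Inf
    for (d in seq_len(max_draws)) {
      test <- sample(pids, n_test)
      pf <- n_test / n
      tf <- sum(counts[test]) / nrow(table)
      err <- max(abs(pf - fraction), abs(tf - fraction))
      if (err < best_err) {
        best_err <- err
        best <- list(test = sort(test), pf = pf, tf = tf)
      }
      if (err <= tol) break
    }
    if (best_err > tol)
      warning(sprintf("no admissible split after %d draws; best deviation %.3f",
                      max_draws, best_err), call. = FALSE)
    structure(list(train = setdiff(pids, best$test), test = best$test,
                   participant_fraction = best$pf,
                   task_fraction = best$tf,
                   admissible = best_err <= tol),
              class = "split_plan")
  })
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan: %d train / %d test participants; task fraction %.3f>\n",
              length(x$train), length(x$test), x$task_fraction))
  invisible(x)
}

#' Nearest-neighbour mutual information between two continuous variables
#'
#' The Kraskov-Stoegbauer-Grassberger (type 1) estimator with Chebyshev
#' distances: for each point, the distance to its `k`-th neighbour in the
#' joint space sets a box whose marginal neighbour counts enter a digamma
#' average.  A seeded, vanishingly small jitter breaks ties so the
#' estimator is well defined on discrete-valued columns.  Estimates are
#' clamped at zero.
#'
#' @param x,y numeric vectors of equal length.
#' @param k neighbour count (default 3).
#' @param seed seed for the tie-breaking jitter.
#' @return estimated mutual information in nats (nonnegative).
#' @export
mutual_information <- function(x, y, k = 3L, seed = 1L) {
  n <- length(x)
  stopifnot(length(y) == n)
  if (n <= k + 1L) return(0)
  .with_seed(seed, {
    x <- x + rnorm(n, 0, (sd(x) + 1e-12) * 1e-10)
    y <- y + rnorm(n, 0, (sd(y) + 1e-12) * 1e-10)
  })
  dx <- abs(outer(x, x, "-"))
  dy <- abs(outer(y, y, "-"))
  dz <- pmax(dx, dy)
  diag(dz) <- Inf
  eps <- apply(dz, 1L, function(r) sort(r)[k])
  diag(dx) <- Inf; diag(dy) <- Inf
  nx <- rowSums(dx < eps)
  ny <- rowSums(dy < eps)
  mi <- digamma(k) + digamma(n) - mean(digamma(nx + 1L) + digamma(ny + 1L))
  max(mi, 0)
}

#' Mutual-information filter feature selection
#'
#' Estimates the MI between every candidate column and the target on the
#' supplied (training) rows only and returns the top `k` by MI, ties
#' broken by column order.
#'
#' @param table training data frame.
#' @param features candidate column names.
#' @param target target column name (default `"adjusted_time"`).
#' @param k number of features to retain (default 10).
#' @param neighbors,seed passed to [mutual_information()].
#' @return data frame `feature`, `mi`, ranked; the top `k` rows.
#' @export
select_features_mi <- function(table, features,
                               target = "adjusted_time", k = 10L,
                               neighbors = 3L, seed = 1L) {
  keep <- features[features %in% names(table)]
  cc <- complete.cases(table[c(keep, target)])
  dat <- table[cc, , drop = FALSE]
  mi <- vapply(seq_along(keep), function(i)
    mutual_information(dat[[keep[i]]], dat[[target]], k = neighbors,
                       seed = seed + i), numeric(1L))
  ord <- order(-mi, seq_along(keep))
  out <- data.frame(feature = keep[ord], mi = mi[ord],
                    stringsAsFactors = FALSE)
  if (k > nrow(out)) {
    warning("fewer candidates than requested; returning all",
            call. = FALSE)
    k <- nrow(out)
  }
  head(out, k)
}

#' Default hyperparameter grids
#'
#' Config-defined grids for each model family; each grid contains the
#' optima the package's documentation discusses (lasso penalty 0.5,
#' polynomial-kernel SVR with cost 0.5, 30-neighbour KNN, and random
#' forests of 15 trees / depth 4 / leaf 5 and 30 trees / depth 5 / leaf
#' 4).
#'
#' @param kind model family.
#' @return named list of parameter vectors.
#' @export
default_grid <- function(kind = c("lasso", "svr", "knn", "rf",
                                  "baseline_mean")) {
  kind <- match.arg(kind)
  switch(kind,
    lasso = list(lambda = c(0.01, 0.1, 0.5, 1)),
    svr = list(kernel = c("polynomial", "radial"),
               cost = c(0.1, 0.5, 1, 10)),
    knn = list(k = c(5L, 10L, 15L, 30L)),
    rf = list(num_trees = c(15L, 30L), max_depth = c(3L, 4L, 5L),
              min_node = c(3L, 4L, 5L)),
    baseline_mean = list())
}

# Participant-grouped fold assignment balancing row counts.
.group_folds <- function(groups, n_folds = 3L, seed = 1L) {
  counts <- sort(table(groups), decreasing = TRUE)
  pids <- .with_seed(seed, {
    # shuffle within equal counts, then greedy-fill the lightest fold
    names(counts)[order(-as.vector(counts), runif(length(counts)))]
  })
  fold_of <- setNames(integer(length(pids)), pids)
  load <- numeric(n_folds)
  for (p in pids) {
    f <- which.min(load)
    fold_of[p] <- f
    load[f] <- load[f] + counts[[p]]
  }
  fold_of[as.character(groups)]
}

.fit_one <- function(kind, X, y, params, seed = 1L) {
  if (kind == "baseline_mean") {
    return(list(kind = kind, mean = mean(y)))
  }
  scale_it <- kind %in% c("lasso", "svr", "knn")
  ctr <- if (scale_it) colMeans(X) else NULL
  scl <- if (scale_it) {
    s <- apply(X, 2L, sd); s[s == 0 | is.na(s)] <- 1; s
  } else NULL
  Xs <- if (scale_it) scale(X, center = ctr, scale = scl) else X
  model <- switch(kind,
    lasso = glmnet::glmnet(Xs, y, alpha = 1, lambda = params$lambda,
                           standardize = FALSE),
    svr = e1071::svm(Xs, y, type = "eps-regression",
                     kernel = params$kernel, cost = params$cost,
                     scale = FALSE),
    knn = caret::knnreg(as.data.frame(Xs), y,
                        k = min(params$k, nrow(Xs))),
    rf = ranger::ranger(
      x = as.data.frame(X), y = y, num.trees = params$num_trees,
      max.depth = params$max_depth, min.node.size = params$min_node,
      seed = seed, num.threads = 1L))
  list(kind = kind, model = model, center = ctr, scale = scl,
       params = params)
}

.predict_one <- function(fit, X) {
  if (fit$kind == "baseline_mean") return(rep(fit$mean, nrow(X)))
  Xs <- if (!is.null(fit$center))
    scale(X, center = fit$center, scale = fit$scale) else X
  switch(fit$kind,
    lasso = as.vector(predict(fit$model, newx = as.matrix(Xs))),
    svr = as.vector(predict(fit$model, as.matrix(Xs))),
    knn = as.vector(predict(fit$model, as.data.frame(Xs))),
    rf = predict(fit$model, data = as.data.frame(X),
                 num.threads = 1L)$predictions)
}

#' Tune and fit a model under grouped cross-validation
#'
#' Grid search minimizing cross-validated RMSE over participant-grouped
#' 3-fold splits of the training rows (no participant ever spans folds),
#' then a refit on all training rows at the best setting.  Features are
#' standardized with training statistics for lasso, SVR, and KNN; the
#' tree model sees unscaled features.
#'
#' @param train training data frame.
#' @param features predictor column names.
#' @param target target column (default `"adjusted_time"`).
#' @param kind model family.
#' @param grid named list of parameter vectors (default
#'   [default_grid()]).
#' @param n_folds folds (default 3).
#' @param seed RNG seed for fold assignment and tree fitting.
#' @return object of class `tuned_model`.
#' @export
tune_model <- function(train, features, target = "adjusted_time",
                       kind = c("rf", "lasso", "svr", "knn",
                                "baseline_mean"),
                       grid = NULL, n_folds = 3L, seed = 1L) {
  kind <- match.arg(kind)
  if (is.null(grid)) grid <- default_grid(kind)
  cc <- complete.cases(train[c(features, target)])
  train <- train[cc, , drop = FALSE]
  X <- as.matrix(train[features])
  y <- train[[target]]
  settings <- if (length(grid)) expand.grid(grid, stringsAsFactors = FALSE)
              else data.frame(row.names = "1")
  cv <- rep(NA_real_, nrow(settings))
  if (nrow(settings) > 1L) {
    folds <- .group_folds(train$participant_id, n_folds, seed)
    if (any(tapply(folds, train$participant_id,
                   function(f) length(unique(f))) != 1L))
      stop("internal error: participant spans CV folds", call. = FALSE)
    for (s in seq_len(nrow(settings))) {
      params <- as.list(settings[s, , drop = FALSE])
      sq <- vapply(seq_len(n_folds), function(f) {
        tr <- folds != f
        if (!any(tr) || all(tr)) return(NA_real_)
        fit <- .fit_one(kind, X[tr, , drop = FALSE], y[tr], params,
                        seed = seed)
        pr <- .predict_one(fit, X[!tr, , drop = FALSE])
        sqrt(mean((y[!tr] - pr)^2))
      }, numeric(1L))
      cv[s] <- mean(sq, na.rm = TRUE)
    }
    best <- which.min(cv)
  } else best <- 1L
  params <- as.list(settings[best, , drop = FALSE])
  fit <- .fit_one(kind, X, y, params, seed = seed)
  structure(list(kind = kind, fit = fit, params = params,
                 cv_results = cbind(settings, cv_rmse = cv),
                 features = features, target = target,
                 n_train = nrow(train), seed = seed),
            class = "tuned_model")
}

#' @export
print.tuned_model <- function(x, ...) {
  ps <- if (length(x$params))
    paste(names(x$params), unlist(x$params), sep = "=", collapse = ", ")
  else "none"
  cat(sprintf("<tuned_model %s (n=%d): %s>\n", x$kind, x$n_train, ps))
  invisible(x)
}

#' @export
predict.tuned_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata[object$features])
  .predict_one(object$fit, X)
}

#' Regression metrics
#'
#' @param truth,pred numeric vectors.
#' @return named list: `rmse`, `mae`, `explained_variance`
#'   (`1 - var(residual)/var(truth)`), `r2` (`1 - SS_res/SS_tot`).
#' @export
evaluate_predictions <- function(truth, pred) {
  if (!length(truth)) stop("evaluation error: empty test set",
                           call. = FALSE)
  res <- truth - pred
  list(rmse = sqrt(mean(res^2)),
       mae = mean(abs(res)),
       explained_variance = 1 - var(res) / var(truth),
       r2 = 1 - sum(res^2) / sum((truth - mean(truth))^2))
}

#' Evaluate a tuned model on held-out rows
#'
#' @param model a [tune_model()] fit.
#' @param test test data frame (participants disjoint from training).
#' @return list of class `model_report`: `kind`, `params`, `metrics`,
#'   `predictions` (data frame with per-row truth, prediction, residual).
#' @export
evaluate_model <- function(model, test) {
  cc <- complete.cases(test[c(model$features, model$target)])
  test <- test[cc, , drop = FALSE]
  pred <- predict(model, test)
  truth <- test[[model$target]]
  structure(list(kind = model$kind, params = model$params,
                 metrics = evaluate_predictions(truth, pred),
                 predictions = data.frame(
                   participant_id = test$participant_id,
                   truth = truth, prediction = pred,
                   residual = truth - pred)),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<model_report %s: RMSE %.3f, MAE %.3f, expl.var %.3f, R2 %.3f (n=%d)>\n",
              x$kind, m$rmse, m$mae, m$explained_variance, m$r2,
              nrow(x$predictions)))
  invisible(x)
}
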