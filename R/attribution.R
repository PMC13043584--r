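# Additive per-prediction feature attributions (Shapley values).  The
# value of a coalition S is the model's prediction with the features in S
# taken from the explained row and the rest replaced, feature-wise, by a
# background sample of training rows (interventional expectation).  With
# exact enumeration over coalitions the attributions satisfy the
# efficiency property: for each row they sum to the prediction minus the
# base value (the mean prediction over the background).

#' Shapley attributions for a tuned model
#'
#' Exact enumeration over all `2^p` feature coalitions (the selected
#' feature count is 10 in the standard pipeline, so 1024 coalition
#' evaluations).  Additivity is verified per prediction to `tol`.
#'
#' @param model a [tune_model()] fit.
#' @param newdata rows to explain (complete cases on the model features).
#' @param background background rows (training data); at most
#'   `n_background` rows are used, sampled with `seed`.
#' @param n_background background sample size (default 25).
#' @param seed seed for the background subsample.
#' @param tol additivity tolerance (default 1e-6).
#' @return list of class `attribution`: `phi` (rows x features matrix),
#'   `base_value`, `prediction`, `ranking` (data frame, by mean |phi|),
#'   and `long` (row, feature, value, attribution) for directionality
#'   plots.
#' @export
shapley_attribution <- function(model, newdata, background,
                                n_background = 25L, seed = 1L,
                                tol = 1e-6) {
  feats <- model$features
  p <- length(feats)
  if (p > 16L) stop("exact enumeration limited to 16 features",
                    call. = FALSE)
  newdata <- newdata[complete.cases(newdata[feats]), , drop = FALSE]
  background <- background[complete.cases(background[feats]), ,
                           drop = FALSE]
  bg <- .with_seed(seed, {
    background[sample(nrow(background),
                      min(n_background, nrow(background))), feats,
               drop = FALSE]
  })
  Xn <- as.matrix(newdata[feats]); Xb <- as.matrix(bg)
  n <- nrow(Xn); m <- nrow(Xb)
  n_coal <- 2^p
  # v[i, c]: mean prediction for row i under coalition c
  v <- matrix(NA_real_, n, n_coal)
  # stacked design: for each coalition, n*m rows (row i repeated over bg)
  base_stack <- Xb[rep(seq_len(m), times = n), , drop = FALSE]
  row_ix <- rep(seq_len(n), each = m)
  for (cidx in seq_len(n_coal)) {
    bits <- as.logical(bitwAnd(cidx - 1L, 2^(seq_len(p) - 1L)))
    Xc <- base_stack
    if (any(bits)) Xc[, bits] <- Xn[row_ix, bits, drop = FALSE]
    pr <- .predict_one(model$fit, Xc)
    v[, cidx] <- rowsum(pr, row_ix)[, 1L] / m
  }
  # Shapley weights over coalition sizes
  phi <- matrix(0, n, p, dimnames = list(NULL, feats))
  sizes <- vapply(seq_len(n_coal) - 1L, function(cc)
    sum(as.logical(bitwAnd(cc, 2^(seq_len(p) - 1L)))), integer(1L))
  fact <- factorial(0:p)
  for (j in seq_len(p)) {
    bit <- 2^(j - 1L)
    without <- which(bitwAnd(seq_len(n_coal) - 1L, bit) == 0L)
    s <- sizes[without]
    wgt <- fact[s + 1L] * fact[p - s] / fact[p + 1L]
    with_j <- without + bit
    phi[, j] <- (v[, with_j, drop = FALSE] -
                   v[, without, drop = FALSE]) %*% wgt
  }
  base <- v[, 1L]
  pred <- v[, n_coal]
  gap <- abs(rowSums(phi) - (pred - base))
  if (any(gap > tol))
    stop(sprintf("internal error: additivity violated (max gap %.2e)",
                 max(gap)), call. = FALSE)
  imp <- colMeans(abs(phi))
  ranking <- data.frame(feature = feats, mean_abs_phi = imp,
                        stringsAsFactors = FALSE)
  ranking <- ranking[order(-ranking$mean_abs_phi), ]
  rownames(ranking) <- NULL
  long <- data.frame(row = rep(seq_len(n), times = p),
                     feature = rep(feats, each = n),
                     value = as.vector(Xn),
                     attribution = as.vector(phi),
                     stringsAsFactors = FALSE)
  structure(list(phi = phi, base_value = base, prediction = pred,
                 ranking = ranking, long = long),
            class = "attribution")
}

#' @export
print.attribution <- function(x, ...) {
  cat(sprintf("<attribution: %d prediction(s), top feature %s (mean |phi| %.3g)>\n",
              nrow(x$phi), x$ranking$feature[1L],
              x$ranking$mean_abs_phi[1L]))
  invisible(x)
}

#' Paired sign-flip permutation test on absolute residuals
#'
#' Tests whether two models differ in absolute residual on the same test
#' rows.  The statistic is the mean difference of paired absolute
#' residuals; the null is built by independently flipping the sign of
#' each pair's difference.  Two-sided p-value with the add-one
#' correction.
#'
#' @param resid_a,resid_b residual vectors on identical rows.
#' @param n_perm permutation draws (default 2000; below 100 warns).
#' @param seed RNG seed.
#' @return list: `statistic` (mean |resid_a| - |resid_b|), `p_value`,
#'   `n_perm`.
#' @export
permutation_test_residuals <- function(resid_a, resid_b, n_perm = 2000L,
                                       seed = 1L) {
  stopifnot(length(resid_a) == length(resid_b))
  if (n_perm < 100L) warning("fewer than 100 permutations", call. = FALSE)
  d <- abs(resid_a) - abs(resid_b)
  obs <- mean(d)
  n <- length(d)
  perm <- .with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      mean(d * sample(c(-1, 1), n, replace = TRUE)), numeric(1L))
  })
  p <- (1 + sum(abs(perm) >= abs(obs) - 1e-15)) / (n_perm + 1)
  list(statistic = obs, p_value = min(p, 1), n_perm = n_perm)
}

#' Mood-augmentation experiment
#'
#' Re-tunes the best model after adding the participant's average PHQ
#' total (or the average of the first two items, anhedonia and depressed
#' mood) as an extra predictor, on the same split, and reports both
#' models side by side.
#'
#' @param train,test feature-table rows (subject-disjoint).
#' @param features selected predictor names for the base model.
#' @param phq validated PHQ record stream.
#' @param kind model family (default `"rf"`).
#' @param grid,seed passed to [tune_model()].
#' @param items `"all"` (mean total) or `"first_two"` (mean of items 1-2).
#' @return list: `base`, `augmented` (both [evaluate_model()] reports),
#'   `phq_feature`, `tuned_base`, `tuned_augmented`.
#' @export
phq_experiment <- function(train, test, features, phq, kind = "rf",
                           grid = NULL, seed = 1L, items = c("all",
                                                             "first_two")) {
  items <- match.arg(items)
  col <- if (items == "all") "phq_mean" else "phq_first2_mean"
  val <- if (items == "all") phq$total else (phq$item1 + phq$item2) / 2
  means <- tapply(val, phq$participant_id, mean)
  add_col <- function(df) {
    df[[col]] <- as.vector(means[df$participant_id])
    miss <- is.na(df[[col]])
    if (any(miss)) {
      warning(sprintf("%d row(s) without PHQ reports; cohort mean imputed",
                      sum(miss)), call. = FALSE)
      df[[col]][miss] <- mean(means, na.rm = TRUE)
    }
    df
  }
  train2 <- add_col(train); test2 <- add_col(test)
  base <- tune_model(train, features, kind = kind, grid = grid,
                     seed = seed)
  aug <- tune_model(train2, c(features, col), kind = kind, grid = grid,
                    seed = seed)
  list(base = evaluate_model(base, test),
       augmented = evaluate_model(aug, test2),
       phq_feature = col, tuned_base = base, tuned_augmented = aug)
}
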