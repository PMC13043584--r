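# Graph-regularized SVD.  Solves
#     min_{H, W} ||X - H W||_F^2 + alpha Tr(W B W^T)   s.t.  H^T H = I_r
# by the Cholesky route: with D the (lower) Cholesky factor of I + alpha B,
# the SVD of X D^{-T} = E S F^T yields H* = E_r and W* = S_r F_r^T D^{-1}.
# For fixed H the optimal W is H^T X (I + alpha B)^{-1}; substituting shows
# H* consists of the top-r left singular vectors of X D^{-T}, so the
# returned pair attains the global minimum.

#' Solve the graph-regularized SVD
#'
#' @param X numeric matrix of size `features x n` (features are rows; the
#'   columns follow the observation-graph node order).
#' @param B symmetric positive-semidefinite regularizer (see
#'   [build_regularizer()]).
#' @param alpha regularization scale, `>= 0` (default 100).
#' @param rank factorization rank, 1 or 2 (default 1).
#' @return list with `H` (`features x rank`, orthonormal columns), `W`
#'   (`rank x n`), `d` (retained singular values of `X D^{-T}`),
#'   `objective`, and `roughness` (`Tr(W B W^T)`).  The sign fix is
#'   applied: if every entry of `W` is negative, both factors are negated.
#' @export
graph_svd <- function(X, B, alpha = 100, rank = 1L) {
  X <- as.matrix(X)
  if (!(rank %in% 1:2)) stop("config error: rank must be 1 or 2",
                             call. = FALSE)
  if (alpha < 0) stop("config error: alpha must be >= 0", call. = FALSE)
  n <- ncol(X)
  if (!all(dim(B) == c(n, n)))
    stop("dimension mismatch between X and B", call. = FALSE)
  A <- diag(n) + alpha * B
  R <- tryCatch(chol(A), error = function(e)
    stop("numerical error: Cholesky factorization of I + alpha*B failed: ",
         conditionMessage(e), call. = FALSE))
  # A = R'R with R upper triangular; D = R' is the lower Cholesky factor.
  Y <- t(backsolve(R, t(X), transpose = TRUE))   # X D^{-T}
  sv <- svd(Y)
  r <- min(rank, length(sv$d))
  H <- sv$u[, seq_len(r), drop = FALSE]
  Z <- diag(sv$d[seq_len(r)], r, r) %*% t(sv$v[, seq_len(r), drop = FALSE])
  W <- t(backsolve(R, t(Z)))                     # Z D^{-1}
  # Sign fix: the SVD's sign is arbitrary; the trajectory is reported
  # nonnegative.  Structural zeros (cells disconnected from all activity)
  # survive smoothing only up to rounding noise, so "all negative" is
  # tested up to a relative tolerance: negate when no entry is genuinely
  # positive but some are negative.
  tol <- 1e-12 * max(abs(W), 1e-300)
  if (!any(W > tol) && any(W < -tol)) {
    H <- -H; W <- -W
  }
  resid <- X - H %*% W
  roughness <- sum(diag(W %*% B %*% t(W)))
  list(H = H, W = W, d = sv$d[seq_len(r)],
       objective = sum(resid^2) + alpha * roughness,
       roughness = roughness)
}

#' Toroidal temporal smoothing of typing activity
#'
#' Fits the graph-regularized SVD to the two hourly typing features --
#' normalized keystroke counts and typing speed -- of one participant,
#' using the toroidal observation graph built from the raw counts.  The
#' rank-1 right factor, reshaped to days x 24, is the smoothed activity
#' trajectory `W*` from which typing-regularity features and sleep labels
#' are derived.
#'
#' @param counts filtered, unnormalized count [activity_matrix()]; edge
#'   weights are computed from it, and its normalization (see
#'   [normalize_counts()]) supplies the first data row.
#' @param speed matching speed [activity_matrix()].
#' @param alpha regularization scale (default 100).
#' @param rank factorization rank (default 1).
#' @param regularizer `"laplacian"` (default) or `"adjacency"`.
#' @param standardize_rows scale each data row to unit variance before
#'   factorization (off by default; the two rows are used as produced).
#' @param zero_tol entries of `|W*|` at or below this are treated as exact
#'   zeros downstream; default `1e-9 * max(|W*|)`.
#' @return object of class `torus_svd` with components `Wstar` (days x 24
#'   smoothed trajectory, sign-fixed and clamped at zero), `Wraw` (the
#'   unclamped right factor), `H` (loadings), `d` (singular values),
#'   `objective`, `roughness`, `zero_tol`, `dates`, and the inputs' flattened
#'   data matrix `X`.
#' @export
torus_svd <- function(counts, speed, alpha = 100, rank = 1L,
                      regularizer = c("laplacian", "adjacency"),
                      standardize_rows = FALSE, zero_tol = NULL) {
  stopifnot(inherits(counts, "activity_matrix"),
            inherits(speed, "activity_matrix"),
            identical(counts$dates, speed$dates))
  regularizer <- match.arg(regularizer)
  norm <- normalize_counts(counts)
  # day-major flattening: row-wise across the days x 24 grid
  X <- rbind(as.vector(t(norm$values)), as.vector(t(speed$values)))
  if (standardize_rows) {
    s <- apply(X, 1L, sd)
    s[s == 0] <- 1
    X <- X / s
  }
  g <- activity_graph(counts)
  B <- build_regularizer(g, regularizer)
  fit <- graph_svd(X, B, alpha = alpha, rank = rank)
  W1 <- fit$W[1L, ]
  if (is.null(zero_tol)) zero_tol <- 1e-9 * max(abs(W1), 1e-300)
  Wstar <- matrix(pmax(W1, 0), nrow = nrow(counts$values), ncol = 24L,
                  byrow = TRUE,
                  dimnames = dimnames(counts$values))
  Wstar[Wstar <= zero_tol] <- 0
  structure(list(Wstar = Wstar, Wraw = fit$W, H = fit$H, d = fit$d,
                 objective = fit$objective, roughness = fit$roughness,
                 alpha = alpha, rank = rank, regularizer = regularizer,
                 zero_tol = zero_tol, dates = counts$dates,
                 participant_id = counts$participant_id, X = X),
            class = "torus_svd")
}

#' @export
print.torus_svd <- function(x, ...) {
  cat(sprintf("Toroidal graph-regularized SVD (rank %d, alpha %g)\n",
              x$rank, x$alpha))
  cat(sprintf("  participant: %s, %d days x 24 hours\n",
              x$participant_id, nrow(x$Wstar)))
  cat(sprintf("  singular value(s): %s\n",
              paste(signif(x$d, 4L), collapse = ", ")))
  cat(sprintf("  objective %.5g, roughness Tr(WBW') %.5g\n",
              x$objective, x$roughness))
  invisible(x)
}

#' @export
summary.torus_svd <- function(object, ...) {
  res <- residuals(object)
  out <- list(participant_id = object$participant_id,
              n_days = nrow(object$Wstar), alpha = object$alpha,
              rank = object$rank, d = object$d,
              objective = object$objective, roughness = object$roughness,
              frac_zero = mean(object$Wstar == 0),
              loadings = object$H,
              resid_fnorm = sqrt(sum(res^2)))
  class(out) <- "summary.torus_svd"
  out
}

#' @export
print.summary.torus_svd <- function(x, ...) {
  cat(sprintf("torus_svd fit: %s (%d days), rank %d, alpha %g\n",
              x$participant_id, x$n_days, x$rank, x$alpha))
  cat(sprintf("  singular values: %s\n",
              paste(signif(x$d, 4L), collapse = ", ")))
  cat(sprintf("  loadings (counts, speed): %s\n",
              paste(signif(x$loadings[, 1L], 4L), collapse = ", ")))
  cat(sprintf("  objective %.5g  roughness %.5g  residual F-norm %.5g\n",
              x$objective, x$roughness, x$resid_fnorm))
  cat(sprintf("  share of W* cells at zero: %.1f%%\n", 100 * x$frac_zero))
  invisible(x)
}

#' @export
fitted.torus_svd <- function(object, ...) object$H %*% object$Wraw

#' @export
residuals.torus_svd <- function(object, ...) object$X - fitted(object)

#' @export
coef.torus_svd <- function(object, ...) {
  list(H = object$H, d = object$d)
}

#' Image plot of the smoothed trajectory
#'
#' @param x a `torus_svd` fit.
#' @param ... passed to [graphics::image()].
#' @export
plot.torus_svd <- function(x, ...) {
  image(x = 0:23, y = seq_len(nrow(x$Wstar)), z = t(x$Wstar),
        col = hcl.colors(64, "YlGnBu", rev = TRUE),
        xlab = "hour of day", ylab = "day",
        main = sprintf("smoothed typing activity W* (%s)",
                       x$participant_id), ...)
  invisible(x)
}
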