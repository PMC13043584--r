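# Sleep estimation from the smoothed trajectory W*.  The pipeline is:
# binarize (any activity -> 1), flood-fill the dominant block of zero
# cells, extend sleep backwards across midnight, clean small gaps with an
# 8 h sliding window advancing by 2 h over the flattened hour sequence,
# and finally enforce one contiguous sleep block per relative 24 h period.
# "Sleep" here is a behavioural proxy: a prolonged contiguous absence of
# typing, not measured sleep.

#' Binarize a smoothed trajectory
#'
#' @param Wstar days x 24 matrix, sign-fixed and clamped at zero.
#' @param zero_tol values at or below this count as zero (no typing).
#' @return integer matrix of 0/1.
#' @export
binarize_activity <- function(Wstar, zero_tol = 0) {
  if (any(Wstar < 0)) stop("W* must be clamped at zero before binarization",
                           call. = FALSE)
  b <- (Wstar > zero_tol) + 0L
  if (all(b == 1L))
    warning("no zero-activity cells: no candidate sleep", call. = FALSE)
  b
}

#' Flood-fill the dominant inactive block
#'
#' Seeds at the zero cell in the hour column whose mean binarized activity
#' is minimal (taking the earliest day carrying a zero in that column) and
#' grows the 4-connected component of zero cells, treating the matrix as a
#' 2-D image (rows are days, columns are hours; no wraparound inside this
#' step).
#'
#' @param binary 0/1 matrix from [binarize_activity()].
#' @return logical mask of the component (`TRUE` = candidate sleep).
#' @export
flood_fill_inactive <- function(binary) {
  nd <- nrow(binary); nh <- ncol(binary)
  if (!any(binary == 0L)) {
    warning("no zero cell: empty sleep mask", call. = FALSE)
    return(matrix(FALSE, nd, nh))
  }
  col_mean <- colMeans(binary)
  # minimum-activity hour among columns that actually contain a zero
  has_zero <- apply(binary == 0L, 2L, any)
  cand <- which(has_zero)
  seed_col <- cand[which.min(col_mean[cand])]
  seed_row <- which(binary[, seed_col] == 0L)[1L]
  mask <- matrix(FALSE, nd, nh)
  queue <- matrix(c(seed_row, seed_col), ncol = 2L)
  mask[seed_row, seed_col] <- TRUE
  while (nrow(queue)) {
    cur <- queue[nrow(queue), , drop = FALSE]
    queue <- queue[-nrow(queue), , drop = FALSE]
    r <- cur[1L]; cl <- cur[2L]
    nb <- rbind(c(r - 1L, cl), c(r + 1L, cl), c(r, cl - 1L), c(r, cl + 1L))
    ok <- nb[, 1L] >= 1L & nb[, 1L] <= nd & nb[, 2L] >= 1L & nb[, 2L] <= nh
    nb <- nb[ok, , drop = FALSE]
    for (k in seq_len(nrow(nb))) {
      if (!mask[nb[k, 1L], nb[k, 2L]] && binary[nb[k, 1L], nb[k, 2L]] == 0L) {
        mask[nb[k, 1L], nb[k, 2L]] <- TRUE
        queue <- rbind(queue, nb[k, , drop = FALSE])
      }
    }
  }
  mask
}

#' Extend masked sleep backwards across midnight
#'
#' For every day whose 00:00 cell is in the mask, walks hours 23, 22, ...
#' of the previous row while those cells are zero in the binarized matrix
#' and adds them to the mask, stopping at the first active hour.
#'
#' @param mask logical mask from [flood_fill_inactive()].
#' @param binary the binarized matrix.
#' @return extended mask.
#' @export
extend_pre_midnight <- function(mask, binary) {
  nd <- nrow(mask)
  for (d in seq_len(nd)[-1L]) {
    if (!mask[d, 1L]) next
    for (h in 24:1) {
      if (binary[d - 1L, h] == 0L) mask[d - 1L, h] <- TRUE else break
    }
  }
  mask
}

#' Remove small gaps in a flattened label sequence
#'
#' Slides a window of `window` hours (default 8) advancing by `stride`
#' hours (default 2) over the labels flattened in chronological order.
#' Within each window, a maximal run of one label of length at most `gap`
#' (default 2) flanked on both sides, within the window, by the opposite
#' label is flipped to the flanking label; flips are applied left to right
#' on the running result until the window is stable, then the window
#' advances.
#'
#' @param labels integer vector of 0 (wake) / 1 (sleep).
#' @param window,stride,gap window length, advance, and maximal flipped
#'   run length, all in hours.
#' @return cleaned label vector.
#' @export
smooth_labels <- function(labels, window = 8L, stride = 2L, gap = 2L) {
  n <- length(labels)
  if (n < 3L) return(labels)
  for (s in seq(1L, max(1L, n - window + 1L), by = stride)) {
    e <- min(s + window - 1L, n)
    repeat {
      seg <- labels[s:e]
      r <- rle(seg)
      if (length(r$lengths) < 3L) break
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      # interior runs only: flanked on both sides within the window
      cand <- which(r$lengths <= gap)
      cand <- cand[cand > 1L & cand < length(r$lengths)]
      if (!length(cand)) break
      k <- cand[1L]
      seg[starts[k]:ends[k]] <- 1L - r$values[k]
      labels[s:e] <- seg
    }
  }
  labels
}

#' Enforce one sleep block per relative 24 h period
#'
#' Partitions the flattened label sequence into relative 24 h periods
#' anchored at the participant's modal sleep-onset hour (so a block
#' spanning midnight is counted once).  Within each period, if several
#' sleep runs remain only the longest (earliest on ties) is kept; the
#' others are relabelled wake.  Daily sleep hours are emitted per period.
#'
#' @param labels 0/1 vector flattened in chronological order (day-major).
#' @param n_days number of day rows the labels came from.
#' @param dates optional `Date` vector for the rows.
#' @param participant_id optional id carried through.
#' @return object of class `sleep_labels`: `labels` (days x 24 matrix),
#'   `daily_sleep_hours` (one per full relative period), `anchor_hour`,
#'   `periods` (data frame of period start offsets and sleep hours).
#' @export
enforce_single_blocks <- function(labels, n_days, dates = NULL,
                                  participant_id = NULL) {
  n <- length(labels)
  stopifnot(n == n_days * 24L)
  r <- rle(labels)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  onset_idx <- starts[r$values == 1L]
  anchor <- if (length(onset_idx)) {
    tab <- table((onset_idx - 1L) %% 24L)
    as.integer(names(tab)[which.max(tab)])
  } else 0L
  # period p covers [first_anchor + 24(p-1), +24); leading cells before the
  # first anchor form a partial leading period.
  first_anchor <- anchor + 1L
  period <- ((seq_len(n) - first_anchor) %/% 24L)
  out <- labels
  sleep_per_period <- integer(0)
  period_ids <- sort(unique(period))
  for (p in period_ids) {
    ix <- which(period == p)
    seg <- out[ix]
    rr <- rle(seg)
    sleep_runs <- which(rr$values == 1L)
    if (length(sleep_runs) > 1L) {
      keep <- sleep_runs[which.max(rr$lengths[sleep_runs])]
      re <- cumsum(rr$lengths); rs <- re - rr$lengths + 1L
      for (k in setdiff(sleep_runs, keep)) seg[rs[k]:re[k]] <- 0L
      out[ix] <- seg
    }
    sleep_per_period <- c(sleep_per_period, sum(seg))
  }
  full <- vapply(period_ids, function(p) sum(period == p) == 24L,
                 logical(1L))
  if (any(sleep_per_period[full] == 0L))
    warning("period(s) with no sleep run: daily sleep 0", call. = FALSE)
  mat <- matrix(out, nrow = n_days, ncol = 24L, byrow = TRUE)
  if (!is.null(dates)) rownames(mat) <- as.character(dates)
  # date of the day row each period starts in (for look-back windows)
  start_cell <- vapply(period_ids, function(p) which(period == p)[1L],
                       integer(1L))
  start_day <- (start_cell - 1L) %/% 24L + 1L
  periods <- data.frame(period = period_ids,
                        start_day = start_day,
                        full = full,
                        sleep_hours = sleep_per_period)
  if (!is.null(dates)) periods$date <- dates[start_day]
  structure(list(labels = mat,
                 daily_sleep_hours = sleep_per_period[full],
                 periods = periods,
                 anchor_hour = anchor,
                 participant_id = participant_id,
                 dates = dates),
            class = "sleep_labels")
}

#' @export
print.sleep_labels <- function(x, ...) {
  cat(sprintf("<sleep_labels%s: %d days, anchor %02d:00, median %g h sleep/period>\n",
              if (is.null(x$participant_id)) "" else
                paste0(" ", x$participant_id),
              nrow(x$labels), x$anchor_hour,
              median(x$daily_sleep_hours)))
  invisible(x)
}

#' Estimate sleep labels from a smoothed trajectory
#'
#' Runs the full labelling chain: [binarize_activity()],
#' [flood_fill_inactive()], [extend_pre_midnight()], [smooth_labels()],
#' [enforce_single_blocks()].
#'
#' @param fit a [torus_svd()] fit, or a days x 24 nonnegative matrix.
#' @param zero_tol zero tolerance for binarization; defaults to the fit's.
#' @param window,stride,gap see [smooth_labels()].
#' @return a `sleep_labels` object.
#' @export
estimate_sleep <- function(fit, zero_tol = NULL, window = 8L, stride = 2L,
                           gap = 2L) {
  if (inherits(fit, "torus_svd")) {
    W <- fit$Wstar
    if (is.null(zero_tol)) zero_tol <- fit$zero_tol
    dates <- fit$dates; pid <- fit$participant_id
  } else {
    W <- as.matrix(fit)
    if (is.null(zero_tol)) zero_tol <- 1e-9 * max(abs(W), 1e-300)
    dates <- NULL; pid <- NULL
  }
  b <- binarize_activity(W, zero_tol)
  mask <- flood_fill_inactive(b)
  mask <- extend_pre_midnight(mask, b)
  lab <- as.integer(t(mask))          # day-major flatten, 1 = sleep
  lab <- smooth_labels(lab, window = window, stride = stride, gap = gap)
  enforce_single_blocks(lab, n_days = nrow(W), dates = dates,
                        participant_id = pid)
}
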