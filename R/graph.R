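# Observation graph over the (hour, day) cells of a filtered activity
# matrix.  Nodes are all days x 24 cells in day-major order (day 1 hours
# 00..23, day 2 hours 00..23, ...).  Hour edges join neighbouring hours
# within a day plus the 23:00 -> 00:00 wrap into the next retained day;
# day edges join the same hour on retained days up to three rows apart.
# Time thus wraps like a flow on a torus: around the day, and along the
# day-to-day axis.

#' Hour-edge weight
#'
#' The weight between two neighbouring hours is the average of their
#' keystroke counts; the midnight boundary pair (23:00 on day j, 00:00 on
#' day j+1) uses the same formula.
#'
#' @param k_cur,k_next keystroke counts of the two cells.
#' @return numeric weight.
#' @export
hour_edge_weight <- function(k_cur, k_next) (k_cur + k_next) / 2

#' Day-edge centre weight
#'
#' The typical typing activity at hour `i` around day `j`: the median of
#' the counts at that hour over the seven-day window `j-3 .. j+3`,
#' truncated to available days at the boundary of the series.  The weight
#' actually placed on an undirected edge (i, j)-(i, j') is the mean of the
#' medians centred at `j` and at `j'` (symmetrization).
#'
#' @param column keystroke counts at one hour across the retained days.
#' @param j centre day (row rank).
#' @return numeric weight.
#' @export
day_edge_weight <- function(column, j) {
  lo <- max(1L, j - 3L); hi <- min(length(column), j + 3L)
  median(column[lo:hi])
}

#' Build the toroidal observation graph of an activity matrix
#'
#' Edge weights are computed from the (by default raw, unnormalized)
#' keystroke counts; see [hour_edge_weight()] and [day_edge_weight()].
#' Day adjacency is by chronological rank among the retained rows, so
#' matrices with filtered-out days remain well defined.
#'
#' @param counts count [activity_matrix()] used for the edge weights.
#' @param day_reach how many rows apart day edges reach (default 3).
#' @return list of class `observation_graph` with `n`, `edges` (data frame
#'   `from`, `to`, `weight`, `type`), and the matrix dimensions.
#' @export
activity_graph <- function(counts, day_reach = 3L) {
  stopifnot(inherits(counts, "activity_matrix"))
  v <- counts$values
  nd <- nrow(v)
  node <- function(day, hour) (day - 1L) * 24L + hour + 1L  # hour in 0..23
  from <- integer(0); to <- integer(0); w <- numeric(0); ty <- character(0)
  # hour edges within each day
  for (i in 0:22) {
    from <- c(from, node(seq_len(nd), i))
    to <- c(to, node(seq_len(nd), i + 1L))
    w <- c(w, hour_edge_weight(v[, i + 1L], v[, i + 2L]))
    ty <- c(ty, rep("hour", nd))
  }
  # midnight wrap between consecutive retained rows
  if (nd > 1L) {
    from <- c(from, node(seq_len(nd - 1L), 23L))
    to <- c(to, node(2:nd, 0L))
    w <- c(w, hour_edge_weight(v[-nd, 24L], v[-1L, 1L]))
    ty <- c(ty, rep("hour", nd - 1L))
  }
  # day edges: same hour, rows 1..day_reach apart, symmetrized medians
  med <- vapply(seq_len(nd), function(j)
    apply(v, 2L, function(col) day_edge_weight(col, j)),
    numeric(24L))                      # 24 x nd
  for (gap in seq_len(min(day_reach, nd - 1L))) {
    j <- seq_len(nd - gap)
    for (i in 0:23) {
      from <- c(from, node(j, i))
      to <- c(to, node(j + gap, i))
      w <- c(w, (med[i + 1L, j] + med[i + 1L, j + gap]) / 2)
      ty <- c(ty, rep("day", length(j)))
    }
  }
  structure(list(n = nd * 24L, n_days = nd,
                 edges = data.frame(from = from, to = to, weight = w,
                                    type = ty)),
            class = "observation_graph")
}

#' Build the graph regularizer B
#'
#' By default B is the combinatorial graph Laplacian (degree minus
#' weighted adjacency) of the observation graph, which is symmetric
#' positive-semidefinite so that `I + alpha B` is positive-definite and
#' Cholesky-factorizable for any `alpha >= 0`.  The raw weighted adjacency
#' is retained as an alternative for comparison.
#'
#' @param graph an [activity_graph()].
#' @param type `"laplacian"` (default) or `"adjacency"`.
#' @return dense symmetric `n x n` matrix.
#' @export
build_regularizer <- function(graph, type = c("laplacian", "adjacency")) {
  type <- match.arg(type)
  n <- graph$n
  A <- matrix(0, n, n)
  e <- graph$edges
  A[cbind(e$from, e$to)] <- A[cbind(e$from, e$to)] + e$weight
  A[cbind(e$to, e$from)] <- A[cbind(e$to, e$from)] + e$weight
  if (type == "adjacency") return(A)
  diag(rowSums(A)) - A
}
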