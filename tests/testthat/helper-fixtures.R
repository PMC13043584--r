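# Shared fixtures and independent oracles, built in code at test time.

# Keystroke rows at given second offsets from a fixed origin.
make_keystrokes <- function(offsets, participant_id = "P1",
                            key_category = "alphanumeric",
                            session_id = NA_character_,
                            hand_mode = "two",
                            origin = as.POSIXct("2023-03-06 00:00:00",
                                                tz = "UTC")) {
  n <- length(offsets)
  data.frame(participant_id = participant_id,
             timestamp = origin + offsets,
             key_category = rep_len(key_category, n),
             press_duration = rep_len(0.08, n),
             session_id = rep_len(session_id, n),
             hand_mode = rep_len(hand_mode, n),
             stringsAsFactors = FALSE)
}

# A small cohort shared by several test files (memoized).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_config(n_participants = 6,
                                              n_days = 16, seed = 401))
    cache
  }
})

# Independent brute-force oracle for the rank-1 graph-regularized SVD
# objective: H is parameterized on an angle grid, W(theta) solved in
# closed form, and the objective evaluated explicitly from the residual.
angle_grid_oracle <- function(X, B, alpha, n_grid = 1e5) {
  n <- ncol(X)
  Ainv <- solve(diag(n) + alpha * B)
  XA <- X %*% Ainv
  theta <- seq(0, pi, length.out = n_grid)
  Hg <- cbind(cos(theta), sin(theta))          # grid x 2
  Wg <- Hg %*% XA                              # grid x n
  HX <- Hg %*% X
  obj <- sum(X^2) - 2 * rowSums(HX * Wg) + rowSums(Wg^2) +
    alpha * rowSums((Wg %*% B) * Wg)
  min(obj)
}

# Random connected-ish Laplacian for solver tests.
random_laplacian <- function(n, n_edges = 2L * n) {
  A <- matrix(0, n, n)
  ij <- which(upper.tri(A))
  pick <- sample(ij, min(n_edges, length(ij)))
  A[pick] <- runif(length(pick), 0, 3)
  A <- A + t(A)
  diag(rowSums(A)) - A
}

# Independent connected-component oracle for the flood fill, via igraph:
# the 4-connected component of zero cells containing (seed_row, seed_col).
flood_fill_oracle <- function(binary, seed_row, seed_col) {
  nd <- nrow(binary); nh <- ncol(binary)
  id <- function(r, c) (c - 1L) * nd + r
  zeros <- which(binary == 0L, arr.ind = TRUE)
  edges <- integer(0)
  for (k in seq_len(nrow(zeros))) {
    r <- zeros[k, 1L]; c <- zeros[k, 2L]
    if (r < nd && binary[r + 1L, c] == 0L)
      edges <- c(edges, id(r, c), id(r + 1L, c))
    if (c < nh && binary[r, c + 1L] == 0L)
      edges <- c(edges, id(r, c), id(r, c + 1L))
  }
  g <- igraph::make_empty_graph(n = nd * nh, directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  comp <- igraph::components(g)$membership
  mask <- matrix(FALSE, nd, nh)
  target <- comp[id(seed_row, seed_col)]
  in_comp <- which(comp == target)
  # restrict to zero cells (isolated nonzero vertices have their own comp)
  mask[in_comp] <- TRUE
  mask & (binary == 0L)
}
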