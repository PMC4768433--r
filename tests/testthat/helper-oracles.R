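# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: plain loops and textbook formulas only.

# full N-linear contraction of the atom-level tensor for one atom, by
# explicit loops over all index tuples (any index equal to `atom` qualifies)
brute_contract_atom <- function(values, props, atom) {
  n <- dim(values)[1]
  order <- length(dim(values))
  idx <- rep(1L, order)
  total <- 0
  repeat {
    if (any(idx == atom)) {
      w <- values[matrix(idx, 1)]
      for (p in seq_len(order)) w <- w * props[[p]][idx[p]]
      total <- total + w
    }
    p <- 1L
    while (p <= order) {
      idx[p] <- idx[p] + 1L
      if (idx[p] <= n) break
      idx[p] <- 1L
      p <- p + 1L
    }
    if (p > order) break
  }
  total
}

# any-index atom-level split by brute-force loop
brute_split <- function(values, atom) {
  out <- array(0, dim(values))
  n <- dim(values)[1]
  order <- length(dim(values))
  grid <- as.matrix(expand.grid(rep(list(seq_len(n)), order)))
  for (r in seq_len(nrow(grid))) {
    if (any(grid[r, ] == atom))
      out[matrix(grid[r, ], 1)] <- values[matrix(grid[r, ], 1)]
  }
  out
}

# leave-one-out PRESS by n explicit refits with lm()
brute_press <- function(X, y) {
  n <- nrow(X)
  press <- 0
  df <- data.frame(y = y, X)
  for (i in seq_len(n)) {
    fit <- stats::lm(y ~ ., data = df[-i, , drop = FALSE])
    pred <- stats::predict(fit, newdata = df[i, , drop = FALSE])
    press <- press + (y[i] - pred)^2
  }
  unname(press)
}

# bond angle at vertex v from the three Euclidean side lengths
law_of_cosines_angle <- function(pv, pb, pc) {
  dvb <- sqrt(sum((pv - pb)^2))
  dvc <- sqrt(sum((pv - pc)^2))
  dbc <- sqrt(sum((pb - pc)^2))
  acos((dvb^2 + dvc^2 - dbc^2) / (2 * dvb * dvc))
}

# random rigid motion (proper rotation + translation)
rigid_motion <- function(coords, seed) {
  set.seed(seed)
  M <- matrix(stats::rnorm(9), 3)
  qrM <- qr(M)
  R <- qr.Q(qrM)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  sweep(coords %*% R, 2, stats::runif(3, -5, 5), "+")
}

# tuple_matrix wrapper around a bare (reference) matrix
as_tm <- function(m, order = 2L, state = "ns") {
  tensormol:::new_tuple_matrix(as.matrix(m), order, state = state)
}

we_fixture <- worked_example()
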