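# Independent oracles and small data builders used across test files.

# Constrained least-squares oracle for the round-robin decomposition:
# minimize sum over defined cells of (X_ij - mu - a_i - b_j)^2 subject to
# sum(a) = sum(b) = 0, via an explicit design matrix with the last level
# expressed as minus the sum of the others.
ls_round_robin_oracle <- function(v) {
  n <- nrow(v)
  idx <- which(row(v) != col(v), arr.ind = TRUE)
  y <- v[idx]
  X <- matrix(0, nrow(idx), 1 + 2 * (n - 1))
  X[, 1] <- 1
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]
    if (i < n) X[r, 1 + i] <- X[r, 1 + i] + 1
    else X[r, 2:n] <- X[r, 2:n] - 1
    if (j < n) X[r, n + j] <- X[r, n + j] + 1
    else X[r, (n + 1):(2 * n - 1)] <- X[r, (n + 1):(2 * n - 1)] - 1
  }
  cf <- qr.coef(qr(X), y)
  a <- c(cf[2:n], -sum(cf[2:n]))
  b <- c(cf[(n + 1):(2 * n - 1)], -sum(cf[(n + 1):(2 * n - 1)]))
  gamma <- v - cf[1] - outer(a, rep(1, n)) - outer(rep(1, n), b)
  diag(gamma) <- NA_real_
  list(mu = unname(cf[1]), alpha = unname(a), beta = unname(b),
       gamma = unname(gamma))
}

random_rr <- function(n, seed, group_id = "g1", variable = "v") {
  set.seed(seed)
  v <- matrix(rnorm(n * n, mean = 4), n, n)
  diag(v) <- NA_real_
  round_robin_table(v, group_id = group_id, variable = variable)
}

# small simulated dataset for fit tests
sim_datasets <- function(seed = 1, ...) {
  pipeline_datasets(simulate_srm_arrma(sim_config(seed = seed, ...)))
}

expect_rr_invariants <- function(eff, table, tol = 1e-9) {
  expect_lt(abs(sum(eff$actor)), tol)
  expect_lt(abs(sum(eff$partner)), tol)
  rec <- eff$mu + outer(eff$actor, rep(1, length(eff$actor))) +
    outer(rep(1, length(eff$partner)), eff$partner) + eff$relationship
  expect_lt(max(abs(rec - table$values), na.rm = TRUE), tol)
  expect_lt(max(abs(rowSums(eff$relationship, na.rm = TRUE))), tol)
  expect_lt(max(abs(colSums(eff$relationship, na.rm = TRUE))), tol)
}
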