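# Shared fixtures: everything is generated in code, nothing read from disk.

# Small random regression problem on the normalized feature scale.
make_problem <- function(n, d = 2L, seed = 1L) {
  set.seed(seed)
  x <- matrix(runif(n * d, -1, 1), n, d)
  y <- sin(2 * x[, 1]) + if (d > 1) 0.5 * x[, 2] else 0
  list(x = x, y = y + rnorm(n, sd = 0.05))
}

# Tiny breakthrough table written to a temp CSV.
write_toy_csv <- function(df = data.frame(c0 = c(24, 24, 8),
                                          h0 = c(7, 7, 11),
                                          u = c(160, 160, 80),
                                          t = c(0, 30, 60),
                                          ratio = c(0.01, 0.44, 0.93))) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE)
  path
}

# Brute-force RBF kernel: explicit double loop, independent of the
# vectorized implementation.
rbf_bruteforce <- function(A, B, sigma2) {
  K <- matrix(NA_real_, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    for (j in seq_len(nrow(B)))
      K[i, j] <- exp(-sum((A[i, ] - B[j, ])^2) / sigma2)
  K
}

# Independent LSSVM oracle: assembles the bordered KKT system with loops and
# solves it with a generic least-squares routine (QR), then predicts by a
# plain loop over the expansion f(x) = sum_k a_k K(x, x_k) + b.
lssvm_oracle <- function(x, y, gamma, sigma2, newx) {
  n <- nrow(x)
  K <- rbf_bruteforce(x, x, sigma2)
  M <- matrix(0, n + 1, n + 1)
  for (j in 2:(n + 1)) { M[1, j] <- 1; M[j, 1] <- 1 }
  for (i in 1:n) for (j in 1:n)
    M[i + 1, j + 1] <- K[i, j] + (i == j) / gamma
  sol <- qr.solve(qr(M), c(0, y))
  b <- sol[1]; a <- sol[-1]
  preds <- numeric(nrow(newx))
  for (i in seq_len(nrow(newx))) {
    acc <- b
    for (k in 1:n)
      acc <- acc + a[k] * exp(-sum((newx[i, ] - x[k, ])^2) / sigma2)
    preds[i] <- acc
  }
  list(alphas = a, bias = b, pred = preds)
}
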