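# Fixture builders and independent brute-force oracles used across tests.
# The oracles deliberately use a different computational route than the
# package (explicit refits, normal equations, auxiliary regressions).

rand_problem <- function(n, k, seed, beta = NULL, intercept = 1, noise = 0.5) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("d", seq_len(k))))
  if (is.null(beta)) beta <- rnorm(k)
  y <- intercept + as.vector(X %*% beta) + rnorm(n, sd = noise)
  list(X = X, y = y, beta = beta, intercept = intercept)
}

# OLS via explicit normal equations (independent of qr-based fit_ols).
ols_oracle <- function(X, y) {
  Xa <- cbind(1, X)
  unname(solve(t(Xa) %*% Xa, t(Xa) %*% y)[, 1])
}

# Leave-one-out Q2 by n explicit refits.
q2_loo_oracle <- function(X, y) {
  n <- length(y)
  press <- 0
  for (i in seq_len(n)) {
    b <- ols_oracle(X[-i, , drop = FALSE], y[-i])
    press <- press + (y[i] - b[1] - sum(X[i, ] * b[-1]))^2
  }
  1 - press / sum((y - mean(y))^2)
}

# Hat-matrix diagonal by explicit matrix products.
leverage_oracle <- function(X) {
  Xa <- cbind(1, X)
  diag(Xa %*% solve(t(Xa) %*% Xa) %*% t(Xa))
}

# VIFs by auxiliary regressions of each column on the others.
vif_oracle <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    fit <- lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    1 / (1 - r2)
  }, numeric(1))
}

# Small dataset wrapper around a random problem.
rand_dataset <- function(n, k, seed, ...) {
  pr <- rand_problem(n, k, seed, ...)
  qsar_dataset(pr$X, pr$y)
}
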