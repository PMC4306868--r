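# Build a one-row-per-twin table from per-pair vectors: `y` is an n x 2
# matrix of outcomes, `covs` a named list of n x 2 matrices.
twin_table <- function(zygosity, y, covs = list()) {
  n <- length(zygosity)
  y <- matrix(y, nrow = n)
  out <- data.frame(
    pair_id = rep(seq_len(n), each = 2L),
    twin_index = rep(1:2, n),
    zygosity = rep(zygosity, each = 2L),
    outcome = as.vector(t(y)),
    stringsAsFactors = FALSE
  )
  for (nm in names(covs)) out[[nm]] <- as.vector(t(matrix(covs[[nm]], nrow = n)))
  out
}

# Population value of the ENVDIF coefficient in the double-entered EQ3
# projection when a covariate with variance `v` and per-unit effect `beta`
# enters both twins' latent outcomes independently.  Derived from the
# population second moments (Frisch-Waugh on the relatedness-specific
# co-twin slopes); exact regardless of the covariate's marginal shape.
envdif_estimand <- function(beta, v, h2, c2, w_mz = 0.5) {
  rbar <- w_mz * (h2 + c2) + (1 - w_mz) * (0.5 * h2 + c2)
  beta * (1 + beta^2 * v + rbar) / (2 + beta^2 * v)
}

# Brute-force loop-over-clusters sandwich covariance (independent oracle).
brute_cluster_cov <- function(X, u, cl, correct = FALSE) {
  B <- solve(t(X) %*% X)
  M <- matrix(0, ncol(X), ncol(X))
  for (g in unique(cl)) {
    Xg <- X[cl == g, , drop = FALSE]
    s <- t(Xg) %*% u[cl == g]
    M <- M + s %*% t(s)
  }
  V <- B %*% M %*% B
  if (correct) {
    G <- length(unique(cl)); n <- nrow(X); k <- ncol(X)
    V <- V * G / (G - 1) * (n - 1) / (n - k)
  }
  V
}
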