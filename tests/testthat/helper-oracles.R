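# Independent oracles shared across test files. These deliberately use
# different algorithms from the package implementations they check.

# SIMPLS (de Jong 1993) regression coefficients for univariate-response PLS;
# predictions must agree with the NIPALS implementation.
simpls_coef <- function(X, y, k) {
  S <- crossprod(X, y)
  R <- matrix(0, ncol(X), k); V <- matrix(0, ncol(X), k)
  Q <- numeric(k)
  for (a in seq_len(k)) {
    r <- S
    t_ <- X %*% r
    nt <- sqrt(sum(t_^2))
    t_ <- t_ / nt; r <- r / nt
    p <- crossprod(X, t_)
    Q[a] <- as.numeric(crossprod(y, t_))
    v <- p
    if (a > 1) v <- v - V[, 1:(a - 1), drop = FALSE] %*%
        crossprod(V[, 1:(a - 1), drop = FALSE], p)
    v <- v / sqrt(sum(v^2))
    S <- S - v %*% crossprod(v, S)
    R[, a] <- r; V[, a] <- v
  }
  R %*% Q
}

# Brute-force weighted running-sum enrichment score by direct loop.
es_brute <- function(scores, hit, w = 1) {
  n <- length(scores)
  m <- sum(hit)
  wts <- abs(scores)^w
  run <- numeric(n); cur <- 0
  denom_hit <- sum(wts[hit])
  for (i in seq_len(n)) {
    cur <- cur + if (hit[i]) wts[i] / denom_hit else -1 / (n - m)
    run[i] <- cur
  }
  run[which.max(abs(run))]
}
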