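# independent oracles, written against the definitions (plain loops, no code
# shared with the package implementation)

# exhaustive permutation-FDR q-values by brute-force enumeration of all
# distinct label assignments
brute_force_fdr <- function(X, labels) {
  n <- nrow(X); m <- ncol(X)
  idx1 <- which(labels == "tumor"); n1 <- length(idx1); n2 <- n - n1
  tstat <- function(g1) {
    vapply(seq_len(m), function(j) {
      a <- X[g1, j]; b <- X[setdiff(seq_len(n), g1), j]
      sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
      d <- mean(a) - mean(b)
      if (sp2 == 0) return(if (d == 0) 0 else sign(d) * Inf)
      d / sqrt(sp2 * (1 / n1 + 1 / n2))
    }, numeric(1))
  }
  obs <- abs(tstat(idx1))
  assigns <- combn(n, n1)
  null_abs <- apply(assigns, 2, function(g1) abs(tstat(g1)))
  K <- ncol(assigns)
  thr <- sort(unique(obs))
  fdr <- vapply(thr, function(c) {
    (sum(null_abs >= c) / K) / max(1, sum(obs >= c))
  }, numeric(1))
  q_at <- vapply(seq_along(thr), function(k) min(pmin(fdr[1:k], 1)), numeric(1))
  q_at[match(obs, thr)]
}

# unpenalized logistic regression by plain Newton-Raphson
newton_logistic <- function(X, y, maxit = 200, tol = 1e-12) {
  Xd <- cbind(1, X)
  beta <- rep(0, ncol(Xd))
  for (i in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    p <- 1 / (1 + exp(-eta))
    W <- p * (1 - p)
    step <- solve(t(Xd) %*% (Xd * W), t(Xd) %*% (y - p))
    beta <- beta + drop(step)
    if (max(abs(step)) < tol) break
  }
  beta
}
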