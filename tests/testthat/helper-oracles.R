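# Independent oracles used to cross-check the package's linear algebra.
# Each one deliberately takes the slow, direct route so that agreement is
# informative.

# Brute-force tip covariance: intersect the root-to-tip edge sets of each
# tip pair and sum the lengths of the shared edges.
vcv_oracle <- function(tree) {
  ntip <- ape::Ntip(tree)
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  elen <- numeric(ntip + tree$Nnode)
  elen[tree$edge[, 2L]] <- tree$edge.length
  root <- ntip + 1L
  path_edges <- lapply(seq_len(ntip), function(v) {
    e <- integer(0)
    while (v != root) {
      e <- c(e, v)  # edge identified by its child node
      v <- parent[v]
    }
    e
  })
  V <- matrix(0, ntip, ntip, dimnames = list(tree$tip.label, tree$tip.label))
  for (i in seq_len(ntip))
    for (j in seq_len(i))
      V[i, j] <- V[j, i] <- sum(elen[intersect(path_edges[[i]], path_edges[[j]])])
  V
}

# Dense multivariate-normal log-likelihood with GLS coefficients and the
# ML variance plugged in, written with explicit inverses and determinants.
mvn_loglik_oracle <- function(y, X, V) {
  n <- length(y)
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  sigma2 <- drop(t(r) %*% Vi %*% r) / n
  -0.5 * (n * log(2 * pi * sigma2) + as.numeric(determinant(V)$modulus) + n)
}

# Ordinary logistic regression by hand-rolled IRLS (the PQL tau2 = 0
# reference point).
logistic_irls_oracle <- function(X, y, tol = 1e-10, max_iter = 50L) {
  beta <- rep(0, ncol(X))
  for (i in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    new <- drop(solve(t(X) %*% (w * X), t(X) %*% (w * z)))
    if (max(abs(new - beta)) < tol) break
    beta <- new
  }
  unname(beta)
}

random_tree <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n)
  tr$edge.length <- tr$edge.length + 0.1  # keep branches clearly positive
  tr
}

skip_if_no <- function(pkg) testthat::skip_if_not_installed(pkg)
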