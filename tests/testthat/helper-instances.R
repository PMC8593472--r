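# Small random test instances and dense oracles, built in code.

# binomial genotype matrix with no monomorphic column
rand_genotypes <- function(n, L, maf = 0.05) {
  G <- matrix(stats::rbinom(n * L, 2L, maf), n, L)
  for (j in seq_len(L)) {
    while (diff(range(G[, j])) == 0)
      G[, j] <- stats::rbinom(n, 2L, maf)
  }
  G
}

# full small instance: genotypes, design (intercept + 1 covariate + E), trait
make_instance <- function(n, L, tau = 1, sigma = 1, nu = 0, seed = NULL,
                          maf = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  G <- rand_genotypes(n, L, maf)
  X <- matrix(stats::rnorm(n), n, 1)
  E <- stats::rnorm(n)
  des <- null_design(E, X)
  ss <- snp_set(G)
  y <- simulate_random_effects(ss, des, tau = tau, sigma = sigma, nu = nu)
  list(G = G, X = X, E = E, des = des, ss = ss, y = y)
}

dense_V <- function(G, tau, sigma) {
  V <- tau * tcrossprod(G)
  diag(V) <- diag(V) + sigma
  V
}

dense_P <- function(X, V) {
  Vi <- solve(V)
  ViX <- Vi %*% X
  Pm <- Vi - ViX %*% solve(crossprod(X, ViX), t(ViX))
  (Pm + t(Pm)) / 2
}

# explicit orthonormal basis of range(X)^perp, via the dense projector
dense_perp_basis <- function(X) {
  n <- nrow(X)
  Pi <- diag(n) - X %*% solve(crossprod(X), t(X))
  e <- eigen((Pi + t(Pi)) / 2, symmetric = TRUE)
  e$vectors[, e$values > 0.5, drop = FALSE]
}

# dense restricted log-likelihood of the projected model (up to a constant)
dense_reml_loglik <- function(tau, sigma, u, AtG) {
  R <- tau * tcrossprod(AtG)
  diag(R) <- diag(R) + sigma
  -0.5 * (determinant(R, logarithm = TRUE)$modulus +
            sum(u * solve(R, u)))
}
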