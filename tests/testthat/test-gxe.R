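test_that("interaction design equals the dense diagonal product", {
  set.seed(141)
  G <- matrix(rnorm(30), 10, 3)
  E <- rnorm(10)
  expect_equal(gxe_design(G, E), diag(E) %*% G, ignore_attr = TRUE)
  expect_identical(gxe_design(G, rep(1, 10)), G)
  expect_true(all(gxe_design(G, rep(0, 10)) == 0))
})

test_that("apply_p annihilates the design and matches the dense projection", {
  set.seed(151)
  inst <- make_instance(100, 6)
  op <- woodbury_op(inst$ss$G, 0.9, 1.1)
  pop <- p_operator(inst$des, op)
  # range(X_tilde) is annihilated
  expect_equal(max(abs(apply_p(pop, inst$des$X_tilde))), 0,
               tolerance = 1e-9)
  # dense oracle
  Pd <- dense_P(inst$des$X_tilde, dense_V(inst$ss$G, 0.9, 1.1))
  W <- matrix(rnorm(300), 100, 3)
  expect_equal(apply_p(pop, W), Pd %*% W, tolerance = 1e-9)
})

test_that("tau = 0 with an intercept-only design centers and rescales", {
  set.seed(161)
  n <- 40
  G <- rand_genotypes(n, 3)
  des <- structure(list(X_tilde = matrix(1, n, 1), E = rnorm(n),
                        n = n, P = 1L), class = "null_design")
  sigma <- 2.5
  op <- woodbury_op(G, 0, sigma)
  pop <- p_operator(des, op)
  y <- rnorm(n)
  expect_equal(apply_p(pop, y), (y - mean(y)) / sigma, tolerance = 1e-10)
})

test_that("score statistic vanishes on fitted null data and has the closed form", {
  set.seed(171)
  inst <- make_instance(80, 5)
  vc <- list(tau_hat = 0.7, sigma_hat = 1.2)
  y_in <- drop(inst$des$X_tilde %*% c(2, -1, 0.3))
  st <- score_statistic(y_in, inst$des, inst$ss, vc)
  expect_equal(st$T, 0, tolerance = 1e-9)

  # tau = 0, sigma = 1, intercept-only: T = ||Gtilde'(y - ybar)||^2 / 2
  n <- 30
  des1 <- structure(list(X_tilde = matrix(1, n, 1), E = rnorm(n),
                         n = n, P = 1L), class = "null_design")
  G <- rand_genotypes(n, 4)
  y <- rnorm(n)
  st1 <- score_statistic(y, des1, suppressWarnings(snp_set(G)),
                         list(tau_hat = 0, sigma_hat = 1))
  Gt <- gxe_design(G, des1$E)
  expect_equal(st1$T, 0.5 * sum(crossprod(Gt, y - mean(y))^2),
               tolerance = 1e-10)
})

test_that("null spectrum reduces the dense kernel exactly", {
  set.seed(181)
  inst <- make_instance(150, 6)
  vc <- list(tau_hat = 0.8, sigma_hat = 1.3)
  lam <- null_spectrum(inst$des, inst$ss, vc)

  # single-locus case by hand
  ss1 <- suppressWarnings(snp_set(inst$ss$G[, 1, drop = FALSE]))
  lam1 <- null_spectrum(inst$des, ss1, vc)
  Pd <- dense_P(inst$des$X_tilde, dense_V(ss1$G, 0.8, 1.3))
  g <- gxe_design(ss1$G, inst$des$E)
  expect_equal(lam1, 0.5 * drop(crossprod(g, Pd %*% g)), tolerance = 1e-9)

  # dense n x n kernel (V^{1/2} P Gtilde form) has the same nonzero spectrum
  V <- dense_V(inst$ss$G, 0.8, 1.3)
  Pd <- dense_P(inst$des$X_tilde, V)
  eV <- eigen(V, symmetric = TRUE)
  Vh <- eV$vectors %*% (sqrt(eV$values) * t(eV$vectors))
  C1 <- Vh %*% Pd %*% gxe_design(inst$ss$G, inst$des$E) / sqrt(2)
  evC <- eigen(tcrossprod(C1), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(lam, evC[seq_along(lam)], tolerance = 1e-8)
})

test_that("degenerate exposures and shifts behave as the model implies", {
  set.seed(191)
  inst <- make_instance(100, 5)
  # E identically zero: no interaction direction, p = 1
  expect_warning(
    r0 <- gxe_test(inst$y, rep(0, 100), inst$ss,
                   X = cbind(inst$X, rnorm(100))),
    "identically zero")
  expect_equal(r0$T, 0)
  expect_equal(r0$p_value, 1)
  expect_error(gxe_test(inst$y, rep(2, 100), inst$ss, X = inst$X),
               "constant")

  # adding a constant to y leaves the statistic unchanged (intercept present)
  r1 <- gxe_test(inst$y, inst$E, inst$ss, X = inst$X)
  r2 <- gxe_test(inst$y + 7.5, inst$E, inst$ss, X = inst$X)
  expect_equal(r1$T, r2$T, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-9)
})

test_that("truth mode skips estimation and uses the supplied components", {
  set.seed(201)
  inst <- make_instance(90, 4)
  r <- gxe_test(inst$y, inst$E, inst$ss, X = inst$X, vc = c(1, 1))
  expect_equal(r$vc$tau_hat, 1)
  expect_equal(r$vc$n_iter, 0L)
  # matches an explicit score_statistic call at the same components
  st <- score_statistic(inst$y, inst$des, inst$ss,
                        list(tau_hat = 1, sigma_hat = 1))
  expect_equal(r$T, st$T, tolerance = 1e-12)
})

test_that("dense engine enforces its size cap and matches otherwise", {
  set.seed(211)
  inst <- make_instance(60, 3)
  expect_error(gxe_test_dense(inst$y, inst$des, inst$ss, n_cap = 50),
               "cap")
  r1 <- gxe_test(inst$y, inst$E, inst$ss, X = inst$X)
  r2 <- gxe_test(inst$y, inst$E, inst$ss, X = inst$X, engine = "dense")
  expect_equal(r1$T, r2$T, tolerance = 1e-9)
  expect_equal(r1$p_value, r2$p_value, tolerance = 1e-8)
  # dense P satisfies its defining identities
  V <- dense_V(inst$ss$G, r2$vc$tau_hat, r2$vc$sigma_hat)
  Pd <- dense_P(inst$des$X_tilde, V)
  expect_equal(Pd %*% V %*% Pd, Pd, tolerance = 1e-9)
  expect_equal(Pd, t(Pd), tolerance = 1e-12)
  expect_equal(max(abs(Pd %*% inst$des$X_tilde)), 0, tolerance = 1e-9)
})
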