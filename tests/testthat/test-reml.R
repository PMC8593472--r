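test_that("em_prepare projects out the fixed-effect space", {
  set.seed(61)
  inst <- make_instance(120, 6)
  # response inside range(X_tilde): u = 0
  y_in <- drop(inst$des$X_tilde %*% c(1, -2, 0.5))
  ws <- em_prepare(y_in, inst$des, inst$ss)
  expect_equal(max(abs(ws$u)), 0, tolerance = 1e-9)

  # a genotype column collinear with a covariate is annihilated
  G2 <- cbind(inst$ss$G[, 1:3], inst$des$X_tilde[, 2])
  ws2 <- em_prepare(inst$y, inst$des, suppressWarnings(snp_set(G2)))
  expect_equal(max(abs(ws2$AtG[, 4])), 0, tolerance = 1e-9)

  # invariants against the dense projector
  Pi <- diag(120) - inst$des$X_tilde %*%
    solve(crossprod(inst$des$X_tilde), t(inst$des$X_tilde))
  ws3 <- em_prepare(inst$y, inst$des, inst$ss)
  expect_equal(sum(ws3$u^2), drop(inst$y %*% Pi %*% inst$y),
               tolerance = 1e-9)
  expect_equal(drop(crossprod(ws3$AtG, ws3$u)),
               drop(crossprod(inst$ss$G, Pi %*% inst$y)),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("em_update has the boundary fixed point and matches a dense EM step", {
  set.seed(71)
  inst <- make_instance(60, 4)
  ws <- em_prepare(inst$y, inst$des, inst$ss)
  m <- ws$m

  # tau = 0 is absorbing; sigma jumps to ||u||^2 / (n - P)
  upd0 <- em_update(0, 2.5, ws)
  expect_identical(upd0[["tau"]], 0)
  expect_equal(upd0[["sigma"]], sum(ws$u^2) / m, tolerance = 1e-12)

  # u = 0: tau contracts, sigma shrinks
  ws0 <- em_prepare(drop(inst$des$X_tilde %*% c(1, 1, 1)), inst$des, inst$ss)
  upd <- em_update(0.8, 1.2, ws0)
  expect_lte(upd[["tau"]], 0.8)
  expect_lt(upd[["sigma"]], 1.2)

  # dense one-step oracle with an explicit basis and explicit solve
  A <- dense_perp_basis(inst$des$X_tilde)
  u <- drop(crossprod(A, inst$y))
  AtG <- crossprod(A, inst$ss$G)
  for (ts in list(c(0.5, 1), c(2, 0.3), c(1, 1))) {
    R <- ts[1] * tcrossprod(AtG); diag(R) <- diag(R) + ts[2]
    Rinv <- solve(R)
    GARu <- drop(crossprod(AtG, Rinv %*% u))
    trM <- sum(diag(crossprod(AtG, Rinv %*% AtG)))
    tau_d <- (ts[1] / 4) * (ts[1] * sum(GARu^2) + 4 - ts[1] * trM)
    sig_d <- (ts[2] / nrow(AtG)) *
      (ts[2] * sum((Rinv %*% u)^2) + ts[1] * trM)
    upd <- em_update(ts[1], ts[2], ws)
    expect_equal(unname(upd), c(tau_d, sig_d), tolerance = 1e-10)
  }
})

test_that("scalable and dense REML-EM trajectories coincide", {
  set.seed(81)
  inst <- make_instance(150, 8)
  vc1 <- reml_em(inst$y, inst$des, inst$ss)
  vc2 <- reml_em_dense(inst$y, inst$des, inst$ss)
  expect_equal(vc1$n_iter, vc2$n_iter)
  expect_equal(vc1$trace, vc2$trace, tolerance = 1e-8)
  expect_equal(c(vc1$tau_hat, vc1$sigma_hat),
               c(vc2$tau_hat, vc2$sigma_hat), tolerance = 1e-8)
})

test_that("EM iterates stay admissible and ascend the restricted likelihood", {
  set.seed(91)
  for (k in 1:3) {
    inst <- make_instance(100, 5, tau = runif(1, 0, 2))
    vc <- reml_em(inst$y, inst$des, inst$ss)
    expect_true(all(vc$trace[, "tau"] >= 0))
    expect_true(all(vc$trace[, "sigma"] > 0))
    A <- dense_perp_basis(inst$des$X_tilde)
    u <- drop(crossprod(A, inst$y))
    AtG <- crossprod(A, inst$ss$G)
    ll <- apply(vc$trace, 1, function(r)
      dense_reml_loglik(r[1], r[2], u, AtG))
    expect_true(all(diff(ll) > -1e-9))
  }
})

test_that("variance components are recovered from simulated data", {
  # no genetic effect: tau_hat near the boundary, sigma_hat near truth
  set.seed(101)
  inst <- make_instance(500, 10, tau = 0, sigma = 1)
  # approach to the tau = 0 boundary is slow; max_iter is a flag, not an error
  vc <- suppressWarnings(reml_em(inst$y, inst$des, inst$ss))
  expect_lt(vc$tau_hat, 0.05)
  expect_lt(abs(vc$sigma_hat - 1), 0.2)

  # pure fixed-effect model with sigma = 4: sigma_hat within 3 SE
  set.seed(102)
  n <- 2000
  X <- matrix(rnorm(n), n, 1); E <- rnorm(n)
  des <- null_design(E, X)
  y <- drop(des$X_tilde %*% c(1, 1, 1)) + rnorm(n, 0, 2)
  ss <- snp_set(rand_genotypes(n, 10))
  # true tau is 0: the slow boundary approach may exhaust max_iter (flagged)
  vc <- suppressWarnings(reml_em(y, des, ss))
  se <- sqrt(2 * 16 / (n - 3))
  expect_lt(abs(vc$sigma_hat - 4), 3 * se)
})

test_that("non-convergence warns and flags rather than fails", {
  set.seed(111)
  inst <- make_instance(80, 4)
  expect_warning(vc <- reml_em(inst$y, inst$des, inst$ss, max_iter = 2L),
                 "did not converge")
  expect_false(vc$converged)
  expect_equal(vc$n_iter, 2L)
})
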