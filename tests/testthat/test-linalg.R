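test_that("Woodbury operator factors the capacitance matrix correctly", {
  # zero update: M = I
  G <- matrix(rnorm(12), 4, 3)
  op <- woodbury_op(G, tau = 0, sigma = 2)
  expect_equal(op$chol_M, diag(3), ignore_attr = TRUE)

  # hand example: G = ones (3 x 1), tau = sigma = 1 -> M = [[4]], chol = [[2]]
  op1 <- woodbury_op(matrix(1, 3, 1), 1, 1)
  expect_equal(drop(op1$chol_M), 2)

  # random instance: chol'chol = I + (tau/sigma) G'G
  set.seed(11)
  G <- matrix(rnorm(250), 50, 5)
  op <- woodbury_op(G, 0.7, 2)
  expect_equal(crossprod(op$chol_M),
               diag(5) + (0.7 / 2) * crossprod(G),
               tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(woodbury_op(G, 1, 0), "sigma")
  expect_error(woodbury_op(G, -1, 1), "tau")
})

test_that("apply_vinv matches a dense solve and is symmetric and cached", {
  set.seed(21)
  G <- rand_genotypes(200, 10)
  op <- woodbury_op(G, 1.3, 0.8)
  V <- dense_V(G, 1.3, 0.8)

  # inverse identity on one column
  e1 <- c(1, rep(0, 199))
  expect_equal(apply_vinv(op, drop(V %*% e1)), e1, tolerance = 1e-10)

  # dense linear-solve oracle, matrix right-hand side
  W <- matrix(rnorm(600), 200, 3)
  expect_equal(apply_vinv(op, W), solve(V, W), tolerance = 1e-10)

  # tau = 0: V = sigma I exactly
  op0 <- woodbury_op(G, 0, 0.8)
  expect_identical(apply_vinv(op0, W), W / 0.8)

  # symmetry of V^{-1}
  v <- rnorm(200); w <- rnorm(200)
  expect_equal(sum(w * apply_vinv(op, v)), sum(v * apply_vinv(op, w)),
               tolerance = 1e-10)

  # cache coherence: repeated application is bitwise identical
  expect_identical(apply_vinv(op, W), apply_vinv(op, W))

  expect_error(apply_vinv(op, matrix(0, 5, 2)), "dimension")
})

test_that("Woodbury inversion is exact across (tau, sigma) settings", {
  set.seed(31)
  for (k in 1:6) {
    m <- sample(50:300, 1); L <- sample(2:20, 1)
    tau <- runif(1, 0, 3); sigma <- runif(1, 0.2, 3)
    G <- matrix(rnorm(m * L), m, L)
    op <- woodbury_op(G, tau, sigma)
    W <- matrix(rnorm(m * 2), m, 2)
    VW <- dense_V(G, tau, sigma) %*% W
    expect_equal(apply_vinv(op, VW), W, tolerance = 1e-9)
  }
})

test_that("perpendicular projector annihilates the design space", {
  # intercept-only design: constants project to zero
  pr <- perp_projector(matrix(1, 4, 1))
  expect_equal(project_perp(pr, rep(1, 4)), rep(0, 3), tolerance = 1e-12)

  # degenerate n = P: empty complement
  pr0 <- perp_projector(diag(3))
  expect_identical(dim(project_perp(pr0, matrix(rnorm(6), 3, 2))),
                   c(0L, 2L))

  # leverage of an intercept-only design: ||A'e1||^2 = 1 - 1/n
  pr5 <- perp_projector(matrix(1, 5, 1))
  expect_equal(sum(project_perp(pr5, c(1, 0, 0, 0, 0))^2), 0.8,
               tolerance = 1e-12)

  # range annihilation and Pythagoras on a random design
  set.seed(41)
  X <- cbind(1, matrix(rnorm(200), 100, 2))
  pr <- perp_projector(X)
  expect_equal(max(abs(project_perp(pr, X))), 0, tolerance = 1e-10)
  for (k in 1:10) {
    w <- rnorm(100)
    q1 <- qr.qty(pr$qr, w)[1:3]
    expect_equal(sum(project_perp(pr, w)^2) + sum(q1^2), sum(w^2),
                 tolerance = 1e-10)
  }
})

test_that("implicit projection equals the materialized Q2 and dense projector", {
  set.seed(51)
  X <- cbind(1, matrix(rnorm(160), 80, 2))
  pr <- perp_projector(X)
  W <- matrix(rnorm(320), 80, 4)
  Q <- qr.Q(pr$qr, complete = TRUE)
  A <- Q[, -(1:3), drop = FALSE]
  expect_equal(project_perp(pr, W), crossprod(A, W), tolerance = 1e-10)

  # A A' is the dense orthogonal projector; idempotent
  AAt <- tcrossprod(A)
  Pi <- diag(80) - X %*% solve(crossprod(X), t(X))
  expect_equal(AAt, Pi, tolerance = 1e-9)
  expect_equal(AAt %*% AAt, AAt, tolerance = 1e-9)
})

test_that("rank-deficient designs are refused with the offending columns", {
  X <- cbind(1, 1:6, 2 * (1:6))
  expect_error(perp_projector(X), "rank deficient")
})
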