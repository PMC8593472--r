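#' Sherman-Morrison-Woodbury operator for V = tau * G G' + sigma * I
#'
#' Builds an implicit representation of the inverse of the low-rank-plus-
#' diagonal covariance `V = tau * G %*% t(G) + sigma * I`. Only the L x L
#' capacitance matrix `M = I_L + (tau/sigma) * G'G` is factored (Cholesky),
#' so `V^{-1}` can be applied to any conformable right-hand side without ever
#' forming an m x m matrix. The factor is computed once and reused by every
#' subsequent [apply_vinv()] call.
#'
#' @param G numeric matrix (m x L) defining the low-rank term. For the
#'   projected covariance used inside the REML-EM iterations this is `A'G`
#'   rather than `G` itself.
#' @param tau nonnegative scalar variance of the random effect.
#' @param sigma positive scalar residual variance.
#' @param gram optional precomputed `crossprod(G)`; pass it when the same
#'   Gram matrix is reused across operators with different `(tau, sigma)`
#'   (as in EM iterations) to avoid recomputing the O(m L^2) product.
#' @return an object of class `"woodbury_op"`: a list with elements `tau`,
#'   `sigma`, `G`, `gram`, `chol_M` (upper-triangular Cholesky factor of M),
#'   and `m` (the operator dimension).
#' @seealso [apply_vinv()]
#' @export
woodbury_op <- function(G, tau, sigma, gram = NULL) {
  G <- as.matrix(G)
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) || tau < 0)
    stop("'tau' must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("'sigma' must be a single positive number", call. = FALSE)
  if (!all(is.finite(G)))
    stop("'G' contains non-finite entries", call. = FALSE)
  L <- ncol(G)
  if (is.null(gram)) gram <- crossprod(G)
  M <- (tau / sigma) * gram
  diag(M) <- diag(M) + 1
  chol_M <- tryCatch(chol(M), error = function(e)
    stop("Cholesky factorization of the capacitance matrix failed: ",
         conditionMessage(e), call. = FALSE))
  structure(
    list(tau = tau, sigma = sigma, G = G, gram = gram,
         chol_M = chol_M, m = nrow(G), L = L),
    class = "woodbury_op"
  )
}

#' Apply V^{-1} to a matrix or vector via the Woodbury identity
#'
#' Computes `solve(V, W)` for `V = tau * G G' + sigma * I` using the cached
#' Cholesky factor of the L x L capacitance matrix:
#' \deqn{V^{-1}W = \frac{1}{\sigma}\left[W - \frac{\tau}{\sigma}
#'   G\,(I_L + \tfrac{\tau}{\sigma}G'G)^{-1} G'W\right].}
#' Cost is O(mLl + L^2 l) for an m x l right-hand side; no m x m
#' intermediate is formed and the capacitance matrix is never inverted
#' explicitly (two triangular solves).
#'
#' @param op a `"woodbury_op"` from [woodbury_op()].
#' @param W numeric vector of length m or matrix with m rows.
#' @return `V^{-1} W`, with the shape of `W` (vectors stay vectors).
#' @export
apply_vinv <- function(op, W) {
  stopifnot(inherits(op, "woodbury_op"))
  vec <- is.null(dim(W))
  W <- as.matrix(W)
  if (nrow(W) != op$m)
    stop("dimension mismatch: operator has dimension ", op$m,
         " but input has ", nrow(W), " rows", call. = FALSE)
  r <- op$tau / op$sigma
  if (r == 0) {
    out <- W / op$sigma
  } else {
    GtW <- crossprod(op$G, W)
    inner <- backsolve(op$chol_M, forwardsolve(op$chol_M, GtW,
                                               upper.tri = TRUE,
                                               transpose = TRUE))
    out <- (W - r * (op$G %*% inner)) / op$sigma
  }
  if (vec) drop(out) else out
}

#' Orthogonal-complement projector for a fixed-effect design
#'
#' Factors the n x P design `X` with a Householder QR decomposition and
#' represents the projector onto the orthogonal complement of `range(X)`
#' implicitly: the basis `A = Q2` (trailing n - P columns of Q) is never
#' materialized. Products `A'W` are formed by multiplying with `Q'` in
#' factored form and dropping the leading P rows.
#'
#' @param X numeric matrix, n x P, assumed full column rank.
#' @return an object of class `"perp_proj"`: list with the `qr` object,
#'   `n` and `P`.
#' @export
perp_projector <- function(X) {
  X <- as.matrix(X)
  n <- nrow(X); P <- ncol(X)
  if (P > n) stop("design has more columns than rows", call. = FALSE)
  qrx <- qr(X)
  tol <- .Machine$double.eps * max(n, P) * max(abs(qr.R(qrx)[1L, ]), 1)
  dR <- abs(diag(qr.R(qrx)))
  if (qrx$rank < P || any(dR < tol * max(dR))) {
    bad <- qrx$pivot[seq.int(qrx$rank + 1L, P)]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(qr = qrx, n = n, P = P), class = "perp_proj")
}

#' Project onto the orthogonal complement of the design space
#'
#' Returns `A'W`, the coordinates of `W` in an orthonormal basis of
#' `range(X)`'s orthogonal complement, computed as `Q'W` (implicit
#' Householder products) with the leading P rows discarded. Satisfies
#' `||A'w||^2 = ||w||^2 - ||Q1'w||^2` for any w.
#'
#' @param proj a `"perp_proj"` from [perp_projector()].
#' @param W numeric vector of length n or matrix with n rows.
#' @return an (n - P) x l matrix (or length n - P vector).
#' @export
project_perp <- function(proj, W) {
  stopifnot(inherits(proj, "perp_proj"))
  vec <- is.null(dim(W))
  W <- as.matrix(W)
  if (nrow(W) != proj$n)
    stop("dimension mismatch: projector expects ", proj$n, " rows, got ",
         nrow(W), call. = FALSE)
  qty <- qr.qty(proj$qr, W)
  out <- qty[-seq_len(proj$P), , drop = FALSE]
  if (vec) drop(out) else out
}
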