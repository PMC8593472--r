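#' Dense reference GxE variance-component test
#'
#' Reference implementation of the original dense-algebra GxE variance
#' component test: it explicitly forms `V`, `V^{-1}`, the n x n projection
#' `P`, the symmetric square root `V^{1/2}`, and the n x n kernel
#' `C = C1 C1'` with `C1 = V^{1/2} P Gtilde / sqrt(2)`, whose eigenvalues
#' give the null weights. Cost is O(n^3): it exists to certify the scalable
#' engine (their statistics and p-values agree to roundoff) and for small
#' data, so `n` is capped.
#'
#' Usually called through `gxe_test(..., engine = "dense")`.
#'
#' @param y numeric response vector.
#' @param design a [null_design()].
#' @param snpset a [snp_set()].
#' @param vc optional fixed variance components (skips the EM).
#' @param pvalue,tol,max_iter,acc,eig_threshold as in [gxe_test()].
#' @param n_cap refuse larger n (default 2000); raise explicitly if you
#'   really want an O(n^3) run.
#' @return a `"gxe_result"` with `engine = "dense"`.
#' @export
gxe_test_dense <- function(y, design, snpset, vc = NULL,
                           pvalue = c("davies", "liu"), tol = 1e-5,
                           max_iter = 500L, acc = 1e-9,
                           eig_threshold = 1e-10, n_cap = 2000L) {
  pvalue <- match.arg(pvalue)
  stopifnot(inherits(design, "null_design"), inherits(snpset, "snp_set"))
  n <- design$n
  if (n > n_cap)
    stop("n = ", n, " exceeds the dense-engine cap (", n_cap,
         "); use the scalable engine (gxe_test) or raise n_cap",
         call. = FALSE)
  if (is.null(vc))
    vc <- reml_em_dense(y, design, snpset, tol = tol, max_iter = max_iter)
  G <- snpset$G
  V <- vc$tau_hat * tcrossprod(G)
  diag(V) <- diag(V) + vc$sigma_hat
  Vi <- chol2inv(chol(V))
  X <- design$X_tilde
  ViX <- Vi %*% X
  P <- Vi - ViX %*% solve(crossprod(X, ViX), t(ViX))
  P <- (P + t(P)) / 2
  Gt <- gxe_design(G, design$E)
  t_vec <- drop(crossprod(Gt, P %*% as.numeric(y)))
  T_stat <- 0.5 * sum(t_vec^2)
  ## spectrum from the dense n x n kernel, via a symmetric square root of V
  eV <- eigen(V, symmetric = TRUE)
  Vhalf <- eV$vectors %*% (sqrt(pmax(eV$values, 0)) * t(eV$vectors))
  C1 <- Vhalf %*% (P %*% Gt) / sqrt(2)
  C <- tcrossprod(C1)
  ev <- eigen((C + t(C)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  lambda <- ev[ev > eig_threshold * max(ev, .Machine$double.xmin)]
  finish_gxe_result(T_stat, t_vec, lambda, vc, snpset, pvalue, acc,
                    engine = "dense")
}

#' Dense REML-EM for the nuisance variance components
#'
#' Reference EM on the explicitly projected model: the orthogonal projector
#' `I - X(X'X)^{-1}X'` is formed, an explicit orthonormal basis `A` of its
#' range is extracted by eigendecomposition, and each iteration solves the
#' dense (n-P) x (n-P) system `R = tau A'G G'A + sigma I` directly. Uses the
#' same initialization, convergence rule, and boundary guard as [reml_em()],
#' whose trajectory it must reproduce to roundoff.
#'
#' @inheritParams gxe_test_dense
#' @param init,tol,max_iter as in [reml_em()].
#' @return a `"vc_estimate"`.
#' @export
reml_em_dense <- function(y, design, snpset, init = NULL, tol = 1e-5,
                          max_iter = 500L, n_cap = 2000L) {
  stopifnot(inherits(design, "null_design"), inherits(snpset, "snp_set"))
  n <- design$n; P <- design$P
  if (n > n_cap)
    stop("n = ", n, " exceeds the dense-engine cap (", n_cap, ")",
         call. = FALSE)
  X <- design$X_tilde
  Pi <- diag(n) - X %*% solve(crossprod(X), t(X))
  ePi <- eigen((Pi + t(Pi)) / 2, symmetric = TRUE)
  A <- ePi$vectors[, ePi$values > 0.5, drop = FALSE]   # orthonormal basis
  m <- ncol(A)
  stopifnot(m == n - P)
  u <- drop(crossprod(A, as.numeric(y)))
  AtG <- crossprod(A, snpset$G)
  L <- ncol(AtG)
  GtA_AtG <- crossprod(AtG)
  if (is.null(init)) {
    s2 <- sum(u^2) / m
    init <- c(s2 / 2, s2 / 2)
  }
  tau <- init[[1L]]; sigma <- init[[2L]]
  trace <- matrix(NA_real_, max_iter + 1L, 2L,
                  dimnames = list(NULL, c("tau", "sigma")))
  trace[1L, ] <- c(tau, sigma)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    if (tau < 1e-12 * sigma) {
      tau <- 0
      sigma <- sum(u^2) / m
      iter <- iter + 1L
      trace[iter + 1L, ] <- c(tau, sigma)
      converged <- TRUE
      break
    }
    R <- tau * tcrossprod(AtG)
    diag(R) <- diag(R) + sigma
    Rinv <- chol2inv(chol(R))
    Rinv_u <- drop(Rinv %*% u)
    GARu <- drop(crossprod(AtG, Rinv_u))
    GAR_AG <- crossprod(AtG, Rinv %*% AtG)
    tr_GARAG <- sum(diag(GAR_AG))
    tau_next <- (tau / L) * (tau * sum(GARu^2) + L - tau * tr_GARAG)
    sigma_next <- (sigma / m) * (sigma * sum(Rinv_u^2) + tau * tr_GARAG)
    iter <- iter + 1L
    trace[iter + 1L, ] <- c(tau_next, sigma_next)
    rel <- max(abs(tau_next - tau) / max(tau, 1e-8),
               abs(sigma_next - sigma) / sigma)
    tau <- tau_next; sigma <- sigma_next
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("dense REML-EM did not converge in ", max_iter, " iterations",
            call. = FALSE)
  structure(list(tau_hat = tau, sigma_hat = sigma, n_iter = iter,
                 converged = converged,
                 trace = trace[seq_len(iter + 1L), , drop = FALSE]),
            class = "vc_estimate")
}
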