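#' Prepare the projected workspace for REML-EM
#'
#' The restricted likelihood of the null mixed model
#' `y = X_tilde beta + G b + e` depends on the data only through the
#' projection onto the orthogonal complement of `range(X_tilde)`:
#' `u = A'y` and `A'G`, where `A` spans that complement. Both are computed
#' once, via implicit QR products, before the iterations start; no n x n
#' object is ever formed. The Gram matrix `K = (A'G)'(A'G)` and `(A'G)'u`
#' are cached because every EM iteration reuses them.
#'
#' @param y numeric response vector of length n.
#' @param design a [null_design()].
#' @param snpset a [snp_set()] (or bare genotype matrix).
#' @return an `"em_workspace"`: list with `u`, `AtG`, `K`, `Gtu`, `u2`
#'   (= ||u||^2), `m` (= n - P), `L`.
#' @export
em_prepare <- function(y, design, snpset) {
  stopifnot(inherits(design, "null_design"))
  if (!inherits(snpset, "snp_set")) snpset <- snp_set(snpset)
  y <- as.numeric(y)
  if (length(y) != design$n || snpset$n != design$n)
    stop("'y', 'design' and 'snpset' disagree on n", call. = FALSE)
  proj <- perp_projector(design$X_tilde)
  u <- project_perp(proj, y)
  AtG <- project_perp(proj, snpset$G)
  structure(list(u = u, AtG = AtG, K = crossprod(AtG),
                 Gtu = drop(crossprod(AtG, u)), u2 = sum(u^2),
                 m = design$n - design$P, L = snpset$L),
            class = "em_workspace")
}

#' One EM update of the variance components (tau, sigma)
#'
#' Performs a single E+M step for the projected null model `u ~ N(0, R)`,
#' `R = tau * A'G G'A + sigma * I_{n-P}`:
#' \deqn{\tau_{t+1} = \frac{\tau_t}{L}\left[\tau_t\|G'A R^{-1}u\|^2 +
#'   \mathrm{tr}(I_L - \tau_t G'A R^{-1} A'G)\right]}
#' \deqn{\sigma_{t+1} = \frac{\sigma_t}{n-P}\left[\sigma_t\|R^{-1}u\|^2 +
#'   \tau_t\,\mathrm{tr}(G'A R^{-1} A'G)\right].}
#' `R^{-1}` is applied through a Woodbury operator built on `A'G`, whose
#' L x L Cholesky factor is computed once per iteration and reused for both
#' solves; the trace is accumulated in L-space so no (n-P) x (n-P)
#' intermediate appears.
#'
#' @param tau_t,sigma_t current iterates (`tau_t >= 0`, `sigma_t > 0`).
#' @param ws an `"em_workspace"` from [em_prepare()].
#' @return named numeric vector `c(tau = ., sigma = .)`.
#' @export
em_update <- function(tau_t, sigma_t, ws) {
  stopifnot(inherits(ws, "em_workspace"))
  if (tau_t < 0 || sigma_t <= 0)
    stop("require tau_t >= 0 and sigma_t > 0", call. = FALSE)
  L <- ws$L; m <- ws$m
  op <- woodbury_op(ws$AtG, tau_t, sigma_t, gram = ws$K)
  ## G'A R^{-1} u = (1/sigma) M^{-1} (A'G)'u   with M = I + (tau/sigma) K
  Minv_Gtu <- backsolve(op$chol_M,
                        forwardsolve(op$chol_M, ws$Gtu,
                                     upper.tri = TRUE, transpose = TRUE))
  GARu <- Minv_Gtu / sigma_t
  ## tr(G'A R^{-1} A'G) = (1/sigma) tr(M^{-1} K)
  MinvK <- backsolve(op$chol_M,
                     forwardsolve(op$chol_M, ws$K,
                                  upper.tri = TRUE, transpose = TRUE))
  tr_GARAG <- sum(diag(MinvK)) / sigma_t
  Rinv_u <- apply_vinv(op, ws$u)
  tau_next <- (tau_t / L) * (tau_t * sum(GARu^2) + L - tau_t * tr_GARAG)
  sigma_next <- (sigma_t / m) * (sigma_t * sum(Rinv_u^2) + tau_t * tr_GARAG)
  res <- c(tau = tau_next, sigma = sigma_next)
  if (!all(is.finite(res)))
    stop("non-finite EM update (tau_t = ", tau_t, ", sigma_t = ", sigma_t,
         ")", call. = FALSE)
  res
}

#' REML-EM estimation of the nuisance variance components
#'
#' Estimates `(tau, sigma)` of the null model `y = X_tilde beta + G b + e`
#' (`b ~ N(0, tau I_L)`, `e ~ N(0, sigma I_n)`) by EM on the restricted
#' (QR-projected) likelihood. Iterations stop when the relative change in
#' both components falls below `tol`. If `tau` collapses toward the boundary
#' (below `1e-12 * sigma`), it is frozen at zero and `sigma` is finished in
#' closed form (`||u||^2 / (n - P)`), avoiding the slow EM crawl near
#' `tau = 0`.
#'
#' @inheritParams em_prepare
#' @param init optional numeric `c(tau0, sigma0)`; default splits the
#'   projected phenotypic variance evenly between the two components.
#' @param tol relative-change convergence tolerance (default `1e-5`).
#' @param max_iter iteration cap (default `500`); hitting it yields a
#'   warning and `converged = FALSE`, not an error.
#' @return a `"vc_estimate"`: list with `tau_hat`, `sigma_hat`, `n_iter`,
#'   `converged`, and `trace` (an (n_iter + 1) x 2 matrix of iterates).
#' @export
reml_em <- function(y, design, snpset, init = NULL, tol = 1e-5,
                    max_iter = 500L) {
  if (tol <= 0) stop("'tol' must be positive", call. = FALSE)
  ws <- em_prepare(y, design, snpset)
  if (is.null(init)) {
    s2 <- ws$u2 / ws$m
    init <- c(s2 / 2, s2 / 2)
  }
  tau <- init[[1L]]; sigma <- init[[2L]]
  if (tau < 0 || sigma <= 0)
    stop("require init tau >= 0 and sigma > 0", call. = FALSE)
  trace <- matrix(NA_real_, max_iter + 1L, 2L,
                  dimnames = list(NULL, c("tau", "sigma")))
  trace[1L, ] <- c(tau, sigma)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    if (tau < 1e-12 * sigma) {      # boundary: closed-form finish
      tau <- 0
      sigma <- ws$u2 / ws$m
      iter <- iter + 1L
      trace[iter + 1L, ] <- c(tau, sigma)
      converged <- TRUE
      break
    }
    upd <- em_update(tau, sigma, ws)
    iter <- iter + 1L
    trace[iter + 1L, ] <- upd
    rel <- max(abs(upd[[1L]] - tau) / max(tau, 1e-8),
               abs(upd[[2L]] - sigma) / sigma)
    tau <- upd[[1L]]; sigma <- upd[[2L]]
    if (rel < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("REML-EM did not converge in ", max_iter, " iterations",
            call. = FALSE)
  structure(list(tau_hat = tau, sigma_hat = sigma, n_iter = iter,
                 converged = converged,
                 trace = trace[seq_len(iter + 1L), , drop = FALSE]),
            class = "vc_estimate")
}

#' Restricted log-likelihood of the projected null model
#'
#' Evaluates (up to an additive constant) the restricted log-likelihood
#' `-1/2 [log det R + u' R^{-1} u]` with `R = tau * A'G G'A + sigma * I`,
#' using the determinant identity `det R = sigma^{n-P} det M`. Used to
#' verify the EM ascent property.
#'
#' @param tau,sigma variance components (`tau >= 0`, `sigma > 0`).
#' @param ws an `"em_workspace"`.
#' @return scalar log-likelihood (constant omitted).
#' @export
reml_loglik <- function(tau, sigma, ws) {
  stopifnot(inherits(ws, "em_workspace"))
  op <- woodbury_op(ws$AtG, tau, sigma, gram = ws$K)
  logdet <- ws$m * log(sigma) + 2 * sum(log(diag(op$chol_M)))
  quad <- sum(ws$u * apply_vinv(op, ws$u))
  -0.5 * (logdet + quad)
}

#' @export
print.vc_estimate <- function(x, ...) {
  cat("Variance components (REML-EM):\n")
  cat("  tau_hat   =", format(x$tau_hat, digits = 6), "\n")
  cat("  sigma_hat =", format(x$sigma_hat, digits = 6), "\n")
  cat("  iterations:", x$n_iter,
      if (x$converged) "(converged)" else "(NOT converged)", "\n")
  invisible(x)
}
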