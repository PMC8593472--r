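#' Interaction design matrix diag(E) G
#'
#' Scales row i of the genotype matrix by the exposure `E[i]`. The diagonal
#' matrix is never formed; cost is O(nL).
#'
#' @param G numeric n x L matrix (or [snp_set()]).
#' @param E numeric exposure vector of length n.
#' @return numeric n x L matrix.
#' @export
gxe_design <- function(G, E) {
  if (inherits(G, "snp_set")) G <- G$G
  G <- as.matrix(G)
  if (nrow(G) != length(E))
    stop("'G' and 'E' disagree on n", call. = FALSE)
  G * as.numeric(E)      # E recycles down columns: row i scaled by E[i]
}

#' Null-model projection operator P
#'
#' Represents `P = V^{-1} - V^{-1} X (X'V^{-1}X)^{-1} X'V^{-1}` (with
#' `X = X_tilde`) implicitly: `V^{-1}` products go through the Woodbury
#' operator and only the P x P matrix `X'V^{-1}X` is factored, once, for
#' reuse across all right-hand sides. `P` annihilates `range(X_tilde)` and
#' satisfies `PVP = P`.
#'
#' @param design a [null_design()].
#' @param op a `"woodbury_op"` built from `(G, tau_hat, sigma_hat)`.
#' @return an object of class `"p_operator"`.
#' @export
p_operator <- function(design, op) {
  stopifnot(inherits(design, "null_design"), inherits(op, "woodbury_op"))
  if (op$m != design$n)
    stop("operator dimension does not match the design", call. = FALSE)
  ViX <- apply_vinv(op, design$X_tilde)
  XtViX <- crossprod(design$X_tilde, ViX)
  XtViX <- (XtViX + t(XtViX)) / 2
  chol_XtViX <- tryCatch(chol(XtViX), error = function(e)
    stop("X'V^{-1}X is singular (collinear covariates?)", call. = FALSE))
  structure(list(op = op, ViX = ViX, chol_XtViX = chol_XtViX,
                 n = design$n),
            class = "p_operator")
}

#' Apply the null-model projection P to a vector or matrix
#'
#' @param pop a `"p_operator"` from [p_operator()].
#' @param W numeric vector of length n or matrix with n rows.
#' @return `P %*% W`, same shape as `W`.
#' @export
apply_p <- function(pop, W) {
  stopifnot(inherits(pop, "p_operator"))
  vec <- is.null(dim(W))
  W <- as.matrix(W)
  if (nrow(W) != pop$n)
    stop("dimension mismatch in apply_p", call. = FALSE)
  ViW <- apply_vinv(pop$op, W)
  rhs <- crossprod(pop$ViX, W)          # X'V^{-1}W  (V^{-1} symmetric)
  coef <- backsolve(pop$chol_XtViX,
                    forwardsolve(pop$chol_XtViX, rhs,
                                 upper.tri = TRUE, transpose = TRUE))
  out <- ViW - pop$ViX %*% coef
  if (vec) drop(out) else out
}

#' Score-like statistic for the GxE variance component
#'
#' Computes `t = Gtilde' P y` and `T = t't / 2`, the score-like statistic
#' for H0: nu = 0 (no GxE variance). Pass externally fixed variance
#' components in `vc` to evaluate the statistic at the true values
#' ("truth mode").
#'
#' @param y numeric response vector.
#' @param design a [null_design()].
#' @param snpset a [snp_set()] or genotype matrix.
#' @param vc a `"vc_estimate"` or list with `tau_hat`, `sigma_hat`.
#' @param pop optional precomputed `"p_operator"` (shared with
#'   [null_spectrum()]).
#' @return list with `T`, `t`, and the `"p_operator"` used (`pop`).
#' @export
score_statistic <- function(y, design, snpset, vc, pop = NULL) {
  if (!inherits(snpset, "snp_set")) snpset <- snp_set(snpset)
  if (is.null(pop)) {
    op <- woodbury_op(snpset$G, vc$tau_hat, vc$sigma_hat)
    pop <- p_operator(design, op)
  }
  Gt <- gxe_design(snpset$G, design$E)
  t_vec <- drop(crossprod(Gt, apply_p(pop, as.numeric(y))))
  list(T = 0.5 * sum(t_vec^2), t = t_vec, pop = pop)
}

#' Null eigenvalue spectrum of the score statistic
#'
#' Under H0 the statistic is asymptotically a weighted sum of independent
#' 1-df chi-squares whose weights are the nonzero eigenvalues of the n x n
#' kernel matrix `C = C1 C1'` with `C1 = V^{1/2} P Gtilde / sqrt(2)`. Since
#' the nonzero eigenvalues of `C1 C1'` equal those of `C1'C1`, and
#' `PVP = P` gives `C1'C1 = Gtilde' P Gtilde / 2`, only the L x L matrix
#' is formed and decomposed: cost O(nL^2 + L^3), never O(n^3). Tiny
#' negative roundoff eigenvalues are clipped at zero and weights below
#' `threshold * max` are dropped.
#'
#' @inheritParams score_statistic
#' @param threshold relative negligibility threshold (default `1e-10`).
#' @return numeric vector of positive eigenvalue weights, descending
#'   (possibly empty when `Gtilde' P Gtilde` vanishes).
#' @export
null_spectrum <- function(design, snpset, vc, pop = NULL,
                          threshold = 1e-10) {
  if (!inherits(snpset, "snp_set")) snpset <- snp_set(snpset)
  if (is.null(pop)) {
    op <- woodbury_op(snpset$G, vc$tau_hat, vc$sigma_hat)
    pop <- p_operator(design, op)
  }
  Gt <- gxe_design(snpset$G, design$E)
  B <- 0.5 * crossprod(Gt, apply_p(pop, Gt))
  B <- (B + t(B)) / 2
  ev <- eigen(B, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  ev[ev > threshold * max(ev, .Machine$double.xmin)]
}

#' Set-based gene-environment interaction variance-component test
#'
#' Score test of H0: nu = 0 in the mixed model
#' `y = X beta_X + E beta_E + G b + diag(E) G c + eps`, with
#' `b ~ N(0, tau I_L)`, `c ~ N(0, nu I_L)`, `eps ~ N(0, sigma I_n)`.
#' The pipeline has three parts: (I) REML-EM estimation of the nuisance
#' variance components (tau, sigma) in the QR-projected space; (II) the
#' score-like statistic `T = ||Gtilde' P y||^2 / 2`; (III) the weighted
#' chi-square p-value from the L x L eigenvalue reduction of the null
#' kernel. One Woodbury operator and one `X'V^{-1}X` factorization are
#' shared across parts II-III, and no n x n matrix is ever formed
#' (`engine = "woodbury"`). `engine = "dense"` runs the O(n^3) reference
#' implementation instead (small n only; see [gxe_test_dense()]).
#'
#' @param y numeric response vector of length n (continuous trait).
#' @param E numeric exposure vector of length n.
#' @param G numeric n x L additive genotype matrix, or a [snp_set()].
#' @param X optional n x p covariate matrix (no intercept column).
#' @param vc optional fixed variance components (list with `tau_hat`,
#'   `sigma_hat`, or numeric `c(tau, sigma)`): skips EM ("truth mode").
#' @param engine `"woodbury"` (scalable, default) or `"dense"`.
#' @param pvalue `"davies"` (exact inversion, with moment-matching
#'   fallback) or `"liu"`.
#' @param tol,max_iter REML-EM convergence controls (see [reml_em()]).
#' @param acc absolute accuracy for the exact p-value integral.
#' @param eig_threshold relative threshold below which eigenvalue weights
#'   are dropped.
#' @param impute mean-impute missing genotypes (passed to [snp_set()]).
#' @return a `"gxe_result"`: list with `T`, `p_value`, `method` (p-value
#'   path actually used), `lambda` (weights), `vc` (variance-component
#'   estimate), `n`, `L`, `engine`, `t` (the L-vector score).
#' @examples
#' set.seed(1)
#' n <- 400; L <- 10
#' G <- matrix(rbinom(n * L, 2, 0.05), n, L)
#' E <- rnorm(n); X <- rnorm(n)
#' y <- 1 + X + E + rnorm(n)
#' gxe_test(y, E, G, X = X)
#' @export
gxe_test <- function(y, E, G, X = NULL, vc = NULL,
                     engine = c("woodbury", "dense"),
                     pvalue = c("davies", "liu"),
                     tol = 1e-5, max_iter = 500L, acc = 1e-9,
                     eig_threshold = 1e-10, impute = TRUE) {
  engine <- match.arg(engine)
  pvalue <- match.arg(pvalue)
  E <- as.numeric(E)
  if (length(E) > 0 && diff(range(E)) == 0) {
    if (E[1L] != 0)
      stop("exposure is constant: the interaction effect is confounded ",
           "and the test is undefined", call. = FALSE)
    ## E identically zero: no interaction direction exists; the statistic is
    ## identically 0 and the null spectrum empty. Fit the null model without
    ## the (all-zero, rank-deficient) exposure column.
    warning("exposure is identically zero; returning the degenerate result ",
            "T = 0, p = 1", call. = FALSE)
    design0 <- null_design(rep(0, length(E)), X)
    design0$X_tilde <- design0$X_tilde[, -design0$P, drop = FALSE]
    design0$P <- design0$P - 1L
    snpset <- if (inherits(G, "snp_set")) G else snp_set(G, impute = impute)
    vc0 <- if (is.null(vc))
      reml_em(y, design0, snpset, tol = tol, max_iter = max_iter)
    else structure(list(tau_hat = vc[[1L]], sigma_hat = vc[[2L]],
                        n_iter = 0L, converged = TRUE, trace = NULL),
                   class = "vc_estimate")
    return(finish_gxe_result(0, rep(0, snpset$L), numeric(0), vc0, snpset,
                             pvalue, acc, engine = engine))
  }
  design <- null_design(E, X)
  snpset <- if (inherits(G, "snp_set")) G else
    snp_set(G, impute = impute)
  y <- as.numeric(y)
  if (length(y) != design$n || snpset$n != design$n)
    stop("'y', 'E'/'X' and 'G' disagree on n", call. = FALSE)
  if (!all(is.finite(y)))
    stop("'y' contains non-finite values", call. = FALSE)
  if (!is.null(vc) && !inherits(vc, "vc_estimate")) {
    if (is.numeric(vc) && length(vc) == 2L)
      vc <- list(tau_hat = vc[[1L]], sigma_hat = vc[[2L]])
    vc <- structure(list(tau_hat = vc$tau_hat, sigma_hat = vc$sigma_hat,
                         n_iter = 0L, converged = TRUE, trace = NULL),
                    class = "vc_estimate")
  }
  if (engine == "dense")
    return(gxe_test_dense(y, design, snpset, vc = vc, pvalue = pvalue,
                          tol = tol, max_iter = max_iter, acc = acc,
                          eig_threshold = eig_threshold))
  ## Part I: nuisance variance components
  if (is.null(vc))
    vc <- reml_em(y, design, snpset, tol = tol, max_iter = max_iter)
  ## Part II: score statistic (operator shared with part III)
  op <- woodbury_op(snpset$G, vc$tau_hat, vc$sigma_hat)
  pop <- p_operator(design, op)
  st <- score_statistic(y, design, snpset, vc, pop = pop)
  ## Part III: spectrum and p-value
  lambda <- null_spectrum(design, snpset, vc, pop = pop,
                          threshold = eig_threshold)
  finish_gxe_result(st$T, st$t, lambda, vc, snpset, pvalue, acc,
                    engine = "woodbury")
}

finish_gxe_result <- function(T_stat, t_vec, lambda, vc, snpset, pvalue,
                              acc, engine) {
  if (length(lambda) == 0L) {
    pr <- tail_prob(1, "degenerate", 0L, 0)
  } else {
    pr <- wchisq_pvalue(T_stat, lambda, method = pvalue, acc = acc)
  }
  structure(
    list(T = T_stat, p_value = pr$p, method = pr$method,
         lambda = lambda, vc = vc, n = snpset$n, L = snpset$L,
         engine = engine, t = t_vec, ifault = pr$ifault),
    class = "gxe_result")
}

#' @export
print.gxe_result <- function(x, ...) {
  cat("Set-based GxE variance-component score test (", x$engine,
      " engine)\n", sep = "")
  cat("  n = ", x$n, ", L = ", x$L, " loci\n", sep = "")
  cat("  tau_hat = ", format(x$vc$tau_hat, digits = 5),
      ", sigma_hat = ", format(x$vc$sigma_hat, digits = 5),
      " (", x$vc$n_iter, " EM iterations",
      if (isTRUE(x$vc$converged)) "" else ", NOT converged", ")\n", sep = "")
  cat("  T = ", format(x$T, digits = 7), "\n", sep = "")
  cat("  p = ", format(x$p_value, digits = 5), "  [", x$method, "]\n",
      sep = "")
  invisible(x)
}
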