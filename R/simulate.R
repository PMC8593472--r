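#' Rare-variant haplotype pool
#'
#' Builds a pool of `H` binary haplotypes over `L` rare-variant sites from
#' which genotypes are drawn by haplotype resampling. Per-site minor allele
#' frequencies are drawn from a configurable site-frequency spectrum
#' truncated to `(1/H, maf_max)` and alleles are independent Bernoulli
#' draws; sites whose realized pool frequency is zero or at/above `maf_max`
#' are redrawn, so every retained site is polymorphic and rare in the pool.
#'
#' The default `"beta"` spectrum draws frequencies from Beta(0.3, 30)
#' truncated to the admissible interval, a right-skewed rare-variant
#' spectrum; `"neutral"` (density proportional to 1/f, the standing
#' -variation expectation of neutral coalescent theory) is more
#' singleton-heavy; `"uniform"` is flat.
#'
#' @param H number of haplotypes in the pool (default 10000).
#' @param L number of variant sites (default 100).
#' @param maf_max upper frequency bound, exclusive (default 0.01).
#' @param maf_dist `"neutral"`, `"beta"`, `"uniform"`, or a function
#'   `f(L)` returning `L` frequencies in `(1/H, maf_max)`.
#' @param seed optional integer seed (global RNG state restored on exit).
#' @return a `"haplotype_pool"`: list with `haplos` (H x L 0/1 integer
#'   matrix), `maf_pool` (realized frequencies), `H`, `L`, `maf_max`.
#' @export
haplotype_pool <- function(H = 10000L, L = 100L, maf_max = 0.01,
                           maf_dist = c("beta", "neutral", "uniform"),
                           seed = NULL) {
  if (H < 2L || L < 1L) stop("need H >= 2 and L >= 1", call. = FALSE)
  f_min <- 1 / H
  if (maf_max <= f_min)
    stop("'maf_max' must exceed 1/H (no feasible frequency)", call. = FALSE)
  if (!is.function(maf_dist)) {
    maf_dist <- match.arg(maf_dist)
    rfreq <- switch(maf_dist,
      neutral = function(k) f_min * (maf_max / f_min)^stats::runif(k),
      beta = function(k) {
        out <- numeric(0)
        while (length(out) < k) {
          cand <- stats::rbeta(2L * k, 0.3, 30)
          out <- c(out, cand[cand > f_min & cand < maf_max])
        }
        out[seq_len(k)]
      },
      uniform = function(k) stats::runif(k, f_min, maf_max))
  } else rfreq <- maf_dist
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  haplos <- matrix(0L, H, L)
  freq <- rfreq(L)
  todo <- seq_len(L)
  while (length(todo) > 0L) {
    for (j in todo)
      haplos[, j] <- stats::rbinom(H, 1L, freq[j])
    realized <- colMeans(haplos[, todo, drop = FALSE])
    bad <- realized == 0 | realized >= maf_max
    redo <- todo[bad]
    if (length(redo) > 0L) freq[redo] <- rfreq(length(redo))
    todo <- redo
  }
  structure(list(haplos = haplos, maf_pool = colMeans(haplos),
                 H = H, L = L, maf_max = maf_max),
            class = "haplotype_pool")
}

#' Draw unrelated genotypes from a haplotype pool
#'
#' Each individual's additive genotype is the sum of two haplotypes drawn
#' uniformly with replacement from the pool, so entries lie in {0, 1, 2}
#' and the expected sample allele frequency equals the pool frequency.
#'
#' @param pool a [haplotype_pool()].
#' @param n number of individuals.
#' @param seed optional integer seed (global RNG state restored on exit).
#' @return a [snp_set()] (monomorphic-in-sample loci are retained: they
#'   carry zero weight in the test and belong to the simulated design).
#' @export
draw_genotypes <- function(pool, n, seed = NULL) {
  stopifnot(inherits(pool, "haplotype_pool"), n >= 1L)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  i <- sample.int(pool$H, n, replace = TRUE)
  j <- sample.int(pool$H, n, replace = TRUE)
  G <- pool$haplos[i, , drop = FALSE] + pool$haplos[j, , drop = FALSE]
  suppressWarnings(snp_set(G, drop_monomorphic = FALSE))
}

#' Simulate covariate and exposure design
#'
#' One standard-normal confounder and one exposure (standard normal by
#' default, or Bernoulli for a binary exposure such as an activity status),
#' assembled into the consolidated design `[1 | X | E]`.
#'
#' @param n sample size.
#' @param p number of standard-normal covariates (default 1).
#' @param exposure `"normal"` (default) or `"binary"`.
#' @param prob carrier probability for a binary exposure.
#' @return a [null_design()].
#' @export
simulate_design <- function(n, p = 1L, exposure = c("normal", "binary"),
                            prob = 0.5) {
  exposure <- match.arg(exposure)
  X <- if (p > 0L) matrix(stats::rnorm(n * p), n, p) else NULL
  E <- switch(exposure,
              normal = stats::rnorm(n),
              binary = stats::rbinom(n, 1L, prob))
  null_design(E, X)
}

#' Simulate a trait from the random-effects GxE model
#'
#' Draws `y = X_tilde beta + G b + diag(E) G c + e` with
#' `b ~ N(0, tau I_L)`, `c ~ N(0, nu I_L)`, `e ~ N(0, sigma I_n)`, all
#' independent. `nu = 0` gives the null used for type-I-error and
#' estimator studies; `nu > 0` gives the alternative for power studies.
#'
#' @param snpset a [snp_set()] (or genotype matrix).
#' @param design a [null_design()].
#' @param tau,sigma,nu variance components (>= 0; `sigma` > 0 in any
#'   non-degenerate use).
#' @param beta fixed-effect coefficient vector of length P (default
#'   all ones).
#' @return numeric response vector of length n.
#' @export
simulate_random_effects <- function(snpset, design, tau = 1, sigma = 1,
                                    nu = 0, beta = NULL) {
  if (!inherits(snpset, "snp_set"))
    snpset <- suppressWarnings(snp_set(snpset, drop_monomorphic = FALSE))
  stopifnot(inherits(design, "null_design"),
            tau >= 0, sigma >= 0, nu >= 0)
  n <- design$n; L <- snpset$L
  if (snpset$n != n) stop("'snpset' and 'design' disagree on n", call. = FALSE)
  if (is.null(beta)) beta <- rep(1, design$P)
  y <- drop(design$X_tilde %*% beta)
  if (tau > 0)
    y <- y + drop(snpset$G %*% stats::rnorm(L, 0, sqrt(tau)))
  if (nu > 0)
    y <- y + drop(gxe_design(snpset$G, design$E) %*%
                    stats::rnorm(L, 0, sqrt(nu)))
  if (sigma > 0)
    y <- y + stats::rnorm(n, 0, sqrt(sigma))
  y
}

#' Simulate a trait from the fixed-effects GxE model
#'
#' Draws `y = X_tilde gamma_X + G gamma_G_vec + diag(E) G gamma_GE_vec + e`
#' where the first `ell` loci are causal: their entries of the coefficient
#' vectors equal the scalars `gamma_G` and `gamma_GE`, the rest are zero;
#' `e ~ N(0, sigma I_n)`. Used to study behaviour under model
#' misspecification (the test assumes random effects).
#'
#' @inheritParams simulate_random_effects
#' @param gamma_G,gamma_GE scalar effect sizes at the causal loci.
#' @param ell number of causal loci (first `ell` columns; `ell <= L`).
#' @param gamma_X fixed-effect coefficients (default all ones).
#' @return numeric response vector, with attributes `snr_G` and `snr_GE`
#'   (per-replicate variance ratios of each effect term to the noise).
#' @export
simulate_fixed_effects <- function(snpset, design, gamma_G = 0,
                                   gamma_GE = 0, ell, sigma = 1,
                                   gamma_X = NULL) {
  if (!inherits(snpset, "snp_set"))
    snpset <- suppressWarnings(snp_set(snpset, drop_monomorphic = FALSE))
  stopifnot(inherits(design, "null_design"), sigma >= 0)
  L <- snpset$L; n <- design$n
  if (ell > L || ell < 0) stop("'ell' must be in [0, L]", call. = FALSE)
  if (is.null(gamma_X)) gamma_X <- rep(1, design$P)
  gG <- c(rep(gamma_G, ell), rep(0, L - ell))
  gGE <- c(rep(gamma_GE, ell), rep(0, L - ell))
  eff_G <- drop(snpset$G %*% gG)
  eff_GE <- drop(gxe_design(snpset$G, design$E) %*% gGE)
  e <- stats::rnorm(n, 0, sqrt(sigma))
  y <- drop(design$X_tilde %*% gamma_X) + eff_G + eff_GE + e
  attr(y, "snr_G") <- if (stats::var(e) > 0) stats::var(eff_G) / stats::var(e) else NA_real_
  attr(y, "snr_GE") <- if (stats::var(e) > 0) stats::var(eff_GE) / stats::var(e) else NA_real_
  y
}

#' Signal-to-noise ratio of an effect term
#'
#' Sample-variance ratio `var(effect) / var(noise)`; the per-replicate
#' quantity whose median across replicates summarizes a fixed-effects
#' simulation scenario.
#'
#' @param effect numeric vector (an effect term, e.g. `G %*% gamma`).
#' @param noise numeric vector (the error term).
#' @return scalar ratio.
#' @export
snr <- function(effect, noise) {
  if (length(noise) < 2L || stats::var(noise) == 0)
    stop("noise variance is zero or undefined", call. = FALSE)
  stats::var(effect) / stats::var(noise)
}
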