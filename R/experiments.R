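#' @name experiments
#' @title Reproducible simulation-study harness
#'
#' @description
#' Drivers for the package's simulation studies: empirical type-I error,
#' power, variance-component estimator accuracy, and p-value accuracy
#' against the truth baseline (the statistic evaluated at the true
#' variance components). Every driver draws a fixed haplotype pool from the
#' master seed, then spawns one recorded sub-seed per replicate, so any
#' single replicate can be replayed. Summaries are recomputable from the
#' per-replicate records.
#'
#' @param n sample size per replicate.
#' @param L number of loci in the SNP set.
#' @param tau,sigma,nu true variance components of the random-effects
#'   generating model.
#' @param n_reps number of replicates.
#' @param seed master seed (integer).
#' @param alphas nominal significance level(s).
#' @param truth also compute, on the same data, the p-value with the true
#'   `(tau, sigma)` plugged in (skipping EM).
#' @param H,maf_max,maf_dist haplotype-pool settings (see
#'   [haplotype_pool()]).
#' @param tol,max_iter,pvalue forwarded to [gxe_test()].
#' @return an `"experiment_report"`: list with `config`, `records` (one row
#'   per replicate: `T`, `p`, and when applicable `p_true`, `tau_hat`,
#'   `sigma_hat`, `n_iter`, `converged`, `method`, `seed`), and `summary`
#'   (a data frame; see each driver).
NULL

exp_config <- function(...) {
  cfg <- list(...)
  cfg
}

replicate_seeds <- function(seed, n_reps) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_reps + 1L)
}

run_null_replicates <- function(n, L, tau, sigma, nu, n_reps, seed,
                                truth = FALSE, H = 10000L, maf_max = 0.01,
                                maf_dist = "beta", tol = 1e-5,
                                max_iter = 500L, pvalue = "davies") {
  seeds <- replicate_seeds(seed, n_reps)
  pool <- haplotype_pool(H = H, L = L, maf_max = maf_max,
                         maf_dist = maf_dist, seed = seeds[1L])
  rec <- data.frame(T = numeric(n_reps), p = numeric(n_reps),
                    p_true = NA_real_, tau_hat = numeric(n_reps),
                    sigma_hat = numeric(n_reps), n_iter = integer(n_reps),
                    converged = logical(n_reps),
                    method = character(n_reps), seed = seeds[-1L])
  for (k in seq_len(n_reps)) {
    set.seed(seeds[k + 1L])
    ss <- draw_genotypes(pool, n)
    des <- simulate_design(n)
    y <- simulate_random_effects(ss, des, tau = tau, sigma = sigma, nu = nu)
    X <- des$X_tilde[, -c(1L, des$P), drop = FALSE]
    fit <- gxe_test(y, des$E, ss, X = X, tol = tol, max_iter = max_iter,
                    pvalue = pvalue)
    rec$T[k] <- fit$T
    rec$p[k] <- fit$p_value
    rec$tau_hat[k] <- fit$vc$tau_hat
    rec$sigma_hat[k] <- fit$vc$sigma_hat
    rec$n_iter[k] <- fit$vc$n_iter
    rec$converged[k] <- fit$vc$converged
    rec$method[k] <- fit$method
    if (truth) {
      fit_t <- gxe_test(y, des$E, ss, X = X, vc = c(tau, sigma),
                        pvalue = pvalue)
      rec$p_true[k] <- fit_t$p_value
    }
  }
  rec
}

rejection_summary <- function(p, alphas) {
  do.call(rbind, lapply(alphas, function(a) {
    rate <- mean(p < a)
    se <- sqrt(rate * (1 - rate) / length(p))
    data.frame(alpha = a, rate = rate, se = se,
               ci_lo = max(0, rate - 1.96 * se),
               ci_hi = min(1, rate + 1.96 * se),
               n_reps = length(p))
  }))
}

#' Type-I-error experiment under the random-effects null
#'
#' Simulates `n_reps` null replicates (`nu = 0`) and reports the empirical
#' rejection rate of the test at each nominal level, with binomial standard
#' errors and 95% confidence intervals. With `truth = TRUE` the rejection
#' rates of the truth-baseline p-values are reported alongside.
#'
#' @rdname experiments
#' @export
type1_experiment <- function(n = 5000L, L = 100L, tau = 1, sigma = 1,
                             n_reps = 1000L, alphas = 0.05, seed = 1L,
                             truth = FALSE, H = 10000L, maf_max = 0.01,
                             maf_dist = "beta", tol = 1e-5,
                             max_iter = 500L, pvalue = "davies") {
  rec <- run_null_replicates(n, L, tau, sigma, nu = 0, n_reps, seed,
                             truth = truth, H = H, maf_max = maf_max,
                             maf_dist = maf_dist, tol = tol,
                             max_iter = max_iter, pvalue = pvalue)
  summ <- cbind(mode = "estimated", rejection_summary(rec$p, alphas))
  if (truth)
    summ <- rbind(summ,
                  cbind(mode = "truth", rejection_summary(rec$p_true, alphas)))
  experiment_report("type1",
                    exp_config(n = n, L = L, tau = tau, sigma = sigma,
                               nu = 0, n_reps = n_reps, alphas = alphas,
                               seed = seed, H = H, maf_max = maf_max,
                               maf_dist = maf_dist),
                    rec, summ)
}

#' Power experiment (random- or fixed-effects alternative)
#'
#' With `model = "random"`, draws replicates with GxE variance `nu > 0`;
#' with `model = "fixed"`, from the fixed-effects model with causal-locus
#' effects `gamma_G` / `gamma_GE` at the first `ell` loci (per-replicate
#' signal-to-noise ratios are recorded and summarized by their median).
#' Reports empirical power at `alpha`.
#'
#' @rdname experiments
#' @param model `"random"` or `"fixed"` generating model.
#' @param alpha nominal level for the power summary.
#' @param gamma_G,gamma_GE,ell fixed-effects scenario (see
#'   [simulate_fixed_effects()]).
#' @export
power_experiment <- function(n = 5000L, L = 100L, tau = 1, sigma = 1,
                             nu = 0.04, n_reps = 200L, alpha = 0.05,
                             seed = 1L, model = c("random", "fixed"),
                             gamma_G = 0, gamma_GE = 0, ell = 0L,
                             H = 10000L, maf_max = 0.01,
                             maf_dist = "beta", tol = 1e-5,
                             max_iter = 500L, pvalue = "davies") {
  model <- match.arg(model)
  if (model == "random") {
    seeds <- replicate_seeds(seed, n_reps)
    pool <- haplotype_pool(H = H, L = L, maf_max = maf_max,
                           maf_dist = maf_dist, seed = seeds[1L])
    rec <- data.frame(T = numeric(n_reps), p = numeric(n_reps),
                      snr_G = NA_real_, snr_GE = NA_real_,
                      seed = seeds[-1L])
    for (k in seq_len(n_reps)) {
      set.seed(seeds[k + 1L])
      ss <- draw_genotypes(pool, n)
      des <- simulate_design(n)
      y <- simulate_random_effects(ss, des, tau = tau, sigma = sigma,
                                   nu = nu)
      X <- des$X_tilde[, -c(1L, des$P), drop = FALSE]
      fit <- gxe_test(y, des$E, ss, X = X, tol = tol,
                      max_iter = max_iter, pvalue = pvalue)
      rec$T[k] <- fit$T; rec$p[k] <- fit$p_value
    }
    cfg <- exp_config(model = model, n = n, L = L, tau = tau,
                      sigma = sigma, nu = nu, n_reps = n_reps,
                      alpha = alpha, seed = seed)
  } else {
    seeds <- replicate_seeds(seed, n_reps)
    pool <- haplotype_pool(H = H, L = L, maf_max = maf_max,
                           maf_dist = maf_dist, seed = seeds[1L])
    rec <- data.frame(T = numeric(n_reps), p = numeric(n_reps),
                      snr_G = numeric(n_reps), snr_GE = numeric(n_reps),
                      seed = seeds[-1L])
    for (k in seq_len(n_reps)) {
      set.seed(seeds[k + 1L])
      ss <- draw_genotypes(pool, n)
      des <- simulate_design(n)
      y <- simulate_fixed_effects(ss, des, gamma_G = gamma_G,
                                  gamma_GE = gamma_GE, ell = ell,
                                  sigma = sigma)
      X <- des$X_tilde[, -c(1L, des$P), drop = FALSE]
      fit <- gxe_test(as.numeric(y), des$E, ss, X = X, tol = tol,
                      max_iter = max_iter, pvalue = pvalue)
      rec$T[k] <- fit$T; rec$p[k] <- fit$p_value
      rec$snr_G[k] <- attr(y, "snr_G"); rec$snr_GE[k] <- attr(y, "snr_GE")
    }
    cfg <- exp_config(model = model, n = n, L = L, sigma = sigma,
                      gamma_G = gamma_G, gamma_GE = gamma_GE, ell = ell,
                      n_reps = n_reps, alpha = alpha, seed = seed,
                      snr_G_median = stats::median(rec$snr_G),
                      snr_GE_median = stats::median(rec$snr_GE))
  }
  summ <- rejection_summary(rec$p, alpha)
  names(summ)[names(summ) == "rate"] <- "power"
  experiment_report("power", cfg, rec, summ)
}

#' Variance-component estimator accuracy experiment
#'
#' Null replicates with known `(tau, sigma)`; reports bias
#' (`mean(theta_hat) - theta`) and mean squared error of the REML-EM
#' estimates of both components.
#'
#' @rdname experiments
#' @export
estimator_mse_experiment <- function(n = 5000L, L = 100L, tau = 1,
                                     sigma = 1, n_reps = 200L, seed = 1L,
                                     H = 10000L, maf_max = 0.01,
                                     maf_dist = "beta", tol = 1e-5,
                                     max_iter = 500L) {
  rec <- run_null_replicates(n, L, tau, sigma, nu = 0, n_reps, seed,
                             truth = FALSE, H = H, maf_max = maf_max,
                             maf_dist = maf_dist, tol = tol,
                             max_iter = max_iter)
  summ <- data.frame(
    component = c("tau", "sigma"),
    truth = c(tau, sigma),
    bias = c(mean(rec$tau_hat) - tau, mean(rec$sigma_hat) - sigma),
    mse = c(mean((rec$tau_hat - tau)^2), mean((rec$sigma_hat - sigma)^2)),
    n_reps = n_reps)
  experiment_report("estimator_mse",
                    exp_config(n = n, L = L, tau = tau, sigma = sigma,
                               nu = 0, n_reps = n_reps, seed = seed),
                    rec, summ)
}

#' p-value accuracy against the truth baseline
#'
#' For each null replicate, two p-values are computed on identical data:
#' one with EM-estimated variance components and one with the true values
#' plugged in ("truth mode"). Reports the mean squared difference and
#' quantiles of the absolute relative error.
#'
#' @rdname experiments
#' @export
pvalue_mse_experiment <- function(n = 5000L, L = 100L, tau = 1, sigma = 1,
                                  n_reps = 200L, seed = 1L, H = 10000L,
                                  maf_max = 0.01, maf_dist = "beta",
                                  tol = 1e-5, max_iter = 500L) {
  rec <- run_null_replicates(n, L, tau, sigma, nu = 0, n_reps, seed,
                             truth = TRUE, H = H, maf_max = maf_max,
                             maf_dist = maf_dist, tol = tol,
                             max_iter = max_iter)
  are <- abs(rec$p - rec$p_true) / rec$p_true
  summ <- data.frame(
    mse_p = mean((rec$p - rec$p_true)^2),
    mse_tau = mean((rec$tau_hat - tau)^2),
    mse_sigma = mean((rec$sigma_hat - sigma)^2),
    bias_tau = mean(rec$tau_hat) - tau,
    bias_sigma = mean(rec$sigma_hat) - sigma,
    abs_rel_err_median = stats::median(are),
    abs_rel_err_q90 = stats::quantile(are, 0.9),
    n_reps = n_reps)
  rownames(summ) <- NULL
  experiment_report("pvalue_mse",
                    exp_config(n = n, L = L, tau = tau, sigma = sigma,
                               nu = 0, n_reps = n_reps, seed = seed),
                    rec, summ)
}

experiment_report <- function(kind, config, records, summary) {
  structure(list(kind = kind, config = config, records = records,
                 summary = summary),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Simulation experiment:", x$kind, "\n")
  cfg <- x$config[!vapply(x$config, is.null, logical(1L))]
  cat("  config:", paste(names(cfg), unlist(lapply(cfg, format)),
                         sep = "=", collapse = ", "), "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
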