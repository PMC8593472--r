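test_that("haplotype pool respects its frequency constraints and seed", {
  pool <- haplotype_pool(H = 500, L = 30, maf_max = 0.05, seed = 5)
  expect_identical(dim(pool$haplos), c(500L, 30L))
  expect_true(all(pool$maf_pool > 0 & pool$maf_pool < 0.05))
  pool2 <- haplotype_pool(H = 500, L = 30, maf_max = 0.05, seed = 5)
  expect_identical(pool$haplos, pool2$haplos)
  expect_error(haplotype_pool(H = 10, maf_max = 0.05), "1/H")
})

test_that("pairwise haplotype sharing matches the independent-site expectation", {
  pool <- haplotype_pool(H = 3000, L = 200, maf_max = 0.05,
                         maf_dist = "uniform", seed = 6)
  f <- pool$maf_pool
  set.seed(7)
  i <- sample(pool$H, 400, TRUE); j <- sample(pool$H, 400, TRUE)
  ok <- i != j
  sharing <- rowSums(pool$haplos[i[ok], ] * pool$haplos[j[ok], ])
  expect_lt(abs(mean(sharing) - sum(f^2)),
            3 * sd(sharing) / sqrt(sum(ok)) + 1e-9)
})

test_that("genotype draws are haplotype sums with matching frequencies", {
  pool <- haplotype_pool(H = 400, L = 25, maf_max = 0.08, seed = 8)
  ss <- draw_genotypes(pool, 5000, seed = 9)
  expect_true(all(ss$G %in% 0:2))
  # expected sample MAF equals pool frequency (3 SE, binomial on 2n draws)
  se <- sqrt(pool$maf_pool * (1 - pool$maf_pool) / (2 * 5000))
  expect_true(all(abs(ss$maf - pool$maf_pool) < 3 * se + 1e-3))
  # reproducibility
  ss2 <- draw_genotypes(pool, 5000, seed = 9)
  expect_identical(ss$G, ss2$G)
})

test_that("random-effects simulation honors its degenerate cases", {
  set.seed(221)
  inst <- make_instance(50, 4)
  y0 <- simulate_random_effects(inst$ss, inst$des, tau = 0, sigma = 0,
                                nu = 0)
  expect_equal(y0, drop(inst$des$X_tilde %*% rep(1, 3)))

  # marginal variance decomposition: Var(y_i | X) ~ tau * sum_j g_ij^2 + sigma
  set.seed(222)
  n <- 25
  G <- rand_genotypes(n, 10, maf = 0.3)
  des <- simulate_design(n)
  ss <- suppressWarnings(snp_set(G, drop_monomorphic = FALSE))
  reps <- replicate(3000, simulate_random_effects(ss, des, tau = 1,
                                                  sigma = 1, nu = 0))
  v_emp <- apply(reps, 1, var)
  v_the <- rowSums(G^2) + 1
  expect_lt(max(abs(v_emp / v_the - 1)), 0.25)
})

test_that("fixed-effects simulation sets causal loci and reports SNR", {
  set.seed(231)
  inst <- make_instance(200, 6)
  y0 <- simulate_fixed_effects(inst$ss, inst$des, gamma_G = 0,
                               gamma_GE = 0, ell = 0, sigma = 1)
  # null fixed-effects model: residual variance near sigma
  expect_lt(abs(var(y0 - drop(inst$des$X_tilde %*% rep(1, 3))) - 1), 0.35)
  expect_equal(attr(y0, "snr_G"), 0)

  y1 <- simulate_fixed_effects(inst$ss, inst$des, gamma_G = 1,
                               gamma_GE = 0.5, ell = 3, sigma = 1)
  expect_gt(attr(y1, "snr_G"), 0)
  expect_gt(attr(y1, "snr_GE"), 0)
  expect_error(simulate_fixed_effects(inst$ss, inst$des, ell = 99), "ell")
})

test_that("snr obeys its scale law", {
  set.seed(241)
  noise <- rnorm(100)
  expect_equal(snr(noise, noise), 1)
  expect_equal(snr(rep(0, 100), noise), 0)
  expect_equal(snr(2 * noise, noise), 4)
  expect_error(snr(noise, rep(1, 100)), "variance")
})
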