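---
title: "Set-based gene-environment interaction variance-component tests at biobank scale"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Set-based gene-environment interaction variance-component tests at biobank scale}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model and the hypothesis

`gxevc` tests whether an environmental exposure modifies the joint effect of
a *set* of genetic variants (a gene, a sliding window, a functional region)
on a continuous trait. For $n$ individuals with trait $y$, covariates $X$
(with intercept), exposure $E$, and an $n \times L$ additive genotype matrix
$G$, the mixed model is

$$
y = X\beta_X + E\beta_E + Gb + \tilde G c + \varepsilon,
\qquad \tilde G = \mathrm{diag}(E)\,G,
$$

with random effects $b \sim N(0, \tau I_L)$ (genetic main effects),
$c \sim N(0, \nu I_L)$ (interaction effects), and
$\varepsilon \sim N(0, \sigma I_n)$. Modelling the per-SNP coefficients as
random avoids the power loss and collinearity problems of estimating $2L$
fixed effects for rare, correlated variants. The interaction null is the
variance-component hypothesis $H_0\!: \nu = 0$, assessed with the
score-like statistic

$$
T = \tfrac12\, y^\top P \tilde G \tilde G^\top P y = \tfrac12\, t^\top t,
\qquad t = \tilde G^\top P y,
$$

where, writing $\tilde X = [\,1 \mid X \mid E\,]$ ($n \times P$) and
$V = \tau G G^\top + \sigma I_n$ for the null covariance,

$$
P = V^{-1} - V^{-1}\tilde X (\tilde X^\top V^{-1} \tilde X)^{-1}
    \tilde X^\top V^{-1}.
$$

Under $H_0$, $T$ is asymptotically a weighted sum of independent 1-df
chi-squares, $T \sim \sum_\ell \lambda_\ell \chi^2_{(1)}$, with weights the
nonzero eigenvalues of the kernel
$C = C_1 C_1^\top$, $C_1 = \tfrac{1}{\sqrt2} V^{1/2} P \tilde G$.

The nuisance components $(\tau, \sigma)$ are unknown and estimated under the
null model $y = \tilde X\beta + Gb + \varepsilon$ by restricted maximum
likelihood.

## Why naive computation fails at biobank scale, and what the package does instead

Every quantity above appears to involve $n \times n$ matrices: $V^{-1}$, $P$,
$V^{1/2}$, and the eigendecomposition of $C$. At $n \sim 10^5$ that is
$O(n^3)$ work and $O(n^2)$ memory per gene — infeasible for genome-wide
scans. The scalable engine computes the *same numbers exactly* (to roundoff)
through three devices, and the package ships a dense $O(n^3)$ reference
engine whose sole purpose is to certify that equality on small data (the
test suite compares statistics, p-values, eigenvalue spectra, and full EM
trajectories between the two engines).

**1. Low-rank inversion.** $V = \tau GG^\top + \sigma I_n$ is a rank-$L$
update of a scaled identity, so by the Sherman-Morrison-Woodbury identity

$$
V^{-1}W = \frac{1}{\sigma}\Big[W - \frac{\tau}{\sigma} G\,
  M^{-1} G^\top W\Big], \qquad
M = I_L + \frac{\tau}{\sigma} G^\top G .
$$

`woodbury_op()` factors the $L \times L$ capacitance matrix $M$ once
(Cholesky; two triangular solves per application, never an explicit
inverse), and `apply_vinv()` applies $V^{-1}$ in $O(nLl)$ for an
$n \times l$ right-hand side. The same factor is reused by the statistic and
the spectrum.

**2. Implicit projection for REML.** The restricted likelihood lives in the
orthogonal complement of $\mathrm{range}(\tilde X)$. With the full
Householder QR factorization $\tilde X = QR$, the trailing $n - P$ columns
$A = Q_2$ form an orthonormal basis of that complement, and products
$A^\top w$ are obtained from the factored form (`qr.qty`) by dropping the
leading $P$ rows — $A$ itself is never materialized (`perp_projector()`,
`project_perp()`).

**3. Spectrum reduction.** The nonzero eigenvalues of $C_1 C_1^\top$
($n \times n$) equal those of $C_1^\top C_1$ ($L \times L$), and because $P$
satisfies $PVP = P$,

$$
C_1^\top C_1 = \tfrac12 \tilde G^\top P V P \tilde G
             = \tfrac12 \tilde G^\top P \tilde G .
$$

So the null weights come from a symmetric $L \times L$ eigendecomposition,
$O(nL^2 + L^3)$ total, and $V^{1/2}$ is never needed. The identity is
verified both ways in the test suite against the explicitly formed dense
kernel.

## The REML-EM algorithm

With $u = A^\top y$ and $A^\top G$ computed once (`em_prepare()`), the
projected model is $u \sim N(0, \hat R)$,
$\hat R = \tau A^\top G G^\top A + \sigma I_{n-P}$, and the EM updates are

$$
\tau_{t+1} = \frac{\tau_t}{L}\Big[\tau_t \lVert G^\top A \hat R^{-1} u
  \rVert^2 + \mathrm{tr}\big(I_L - \tau_t\, G^\top A \hat R^{-1} A^\top G
  \big)\Big],
$$
$$
\sigma_{t+1} = \frac{\sigma_t}{n-P}\Big[\sigma_t \lVert \hat R^{-1} u
  \rVert^2 + \tau_t\, \mathrm{tr}\big(G^\top A \hat R^{-1} A^\top G\big)
  \Big].
$$

These are the exact E+M steps for the complete data $(u, b)$: the $\tau$
update is $E[\lVert b\rVert^2 \mid u]/L$ and the $\sigma$ update is
$E[\lVert u - A^\top G b\rVert^2 \mid u]/(n-P)$; both reduce algebraically
to the displayed forms, which is also why the restricted log-likelihood is
non-decreasing along the iterate sequence (asserted by the tests against a
dense evaluation of the objective). $\hat R^{-1}$ is applied with the same
Woodbury operator built on $A^\top G$; since $(\tau_t, \sigma_t)$ change
between iterations, one $L \times L$ Cholesky is computed per iteration and reused
for both solves, and the trace is accumulated in $L$-space
($\mathrm{tr}(G^\top A \hat R^{-1} A^\top G) = \mathrm{tr}(M^{-1}K)/\sigma$
with $K = (A^\top G)^\top A^\top G$ cached across iterations), so an
iteration costs $O(L^3 + nL)$ after the one-time $O(nL^2)$ setup.

Tunable parameters, with defaults and reasoning:

* **Initialization** `tau0 = sigma0 = var(u)/2`: the projected phenotypic
  variance split evenly between the two components — a neutral starting
  point that is positive whenever the data are non-degenerate.
* **Convergence** (`tol = 1e-5`, `max_iter = 500`): stop when the relative
  change of both components falls below `tol`,
  $\max\{|\Delta\tau|/\max(\tau, 10^{-8}),\ |\Delta\sigma|/\sigma\} <$
  `tol`. Hitting `max_iter` warns and flags `converged = FALSE` but still
  returns the estimate — standard EM practice, since the test statistic is
  well-defined at any admissible $(\tau, \sigma)$. Both are exposed to the
  user and on the command line (`--tol`, `--max-iter`).
* **Boundary guard**: EM approaches $\tau = 0$ geometrically slowly. When
  $\tau_t < 10^{-12}\sigma_t$ the iteration freezes $\tau$ at zero and
  finishes $\sigma$ in closed form ($\lVert u\rVert^2/(n-P)$, the exact
  restricted MLE when $\tau = 0$). Without the guard, sets with no genetic
  main effect dominate the run time of a scan.

EM preserves $\tau_t \ge 0$ and $\sigma_t > 0$ from positive starting
values, so no explicit constraint handling is needed.

## Tail probabilities of the weighted chi-square

Given weights $\lambda_1 \ge \dots \ge \lambda_r > 0$, the p-value
$\Pr(\sum_\ell \lambda_\ell \chi^2_{(1)} > T)$ is computed by direct
numerical inversion of the characteristic function,

$$
p = \frac12 + \frac{1}{\pi}\int_0^\infty
\frac{\sin\theta(u)}{u\,\rho(u)}\,du,
\qquad
\theta(u) = \tfrac12 \textstyle\sum_\ell \arctan(\lambda_\ell u)
  - \tfrac12 T u,
\quad
\rho(u) = \textstyle\prod_\ell (1 + \lambda_\ell^2 u^2)^{1/4},
$$

with adaptive quadrature at a requested absolute accuracy of `acc = 1e-9`
(`davies_pvalue()`). Numerical decisions:

* weights are rescaled by $\lambda_{\max}$ first (the probability is scale
  equivariant), which conditions the integrand;
* equal-weight spectra (including the single-weight case) dispatch to the
  closed-form chi-square tail;
* the quadrature's achieved error estimate — not its message string — decides
  the fault flag; on fault, or a result outside $(0, 1]$, the caller falls
  back to the four-cumulant moment-matching approximation (`liu_pvalue()`),
  and the result records which method produced it;
* reported p-values are floored at the smallest positive double; exact zero
  is never returned.

A chunked Monte Carlo sampler (`mc_pvalue()`) serves as an independent
oracle in the test suite (agreement within three binomial standard errors at
$10^6$ draws). The moment-matching approximation is exact for equal weights
and agrees with the inversion to $10^{-2}$ across the body of the
distribution for spectra of 10-50 uniform weights; for very small, highly
skewed spectra its error can exceed that, which is why it is the fallback
and not the default.

Spectrum hygiene: eigenvalues of $\tfrac12 \tilde G^\top P \tilde G$ that
are negative by roundoff are clipped to zero, and weights below
$10^{-10}\lambda_{\max}$ are dropped (`eig_threshold`, exposed). If the
whole spectrum vanishes — e.g. the exposure is identically zero — the
statistic is identically zero and the degenerate result $T = 0$, $p = 1$ is
returned rather than an error; a *constant nonzero* exposure, by contrast,
is an error, because the interaction is then confounded with the genetic
main effect and the null design loses rank.

## What the simulator emulates — and what it does not

The generator reproduces the rare-variant, unrelated-sample regime the
method targets:

* `haplotype_pool()` builds $H = 10{,}000$ binary haplotypes over $L$ sites
  whose frequencies are drawn from a site-frequency spectrum truncated to
  $(1/H,\ \texttt{maf\_max})$ with `maf_max = 0.01` — every site is a rare
  variant. The default spectrum is Beta(0.3, 30) (right-skewed toward rare
  sites); a neutral-coalescent $1/f$ spectrum and a uniform spectrum are
  selectable. Sites monomorphic in the pool (or at/above the bound) are
  redrawn.
* `draw_genotypes()` forms each individual as the sum of two haplotypes
  drawn with replacement — Hardy-Weinberg sampling from the pool. Loci that
  happen to be monomorphic *in the sample* are kept: they carry zero weight
  in the statistic and are part of the sampled design.
* `simulate_design()` draws one standard-normal covariate and a
  standard-normal (optionally Bernoulli) exposure; fresh covariates,
  exposure, and genotypes are drawn for every replicate, while the pool and
  site selection stay fixed within an experiment.
* `simulate_random_effects()` draws the trait from the mixed model above
  with $\beta$ the all-ones vector; `simulate_fixed_effects()` draws from a
  fixed-coefficient variant (first $\ell$ loci causal, scalar effects
  `gamma_G`, `gamma_GE`) used to study behaviour under model
  misspecification, reporting per-replicate signal-to-noise ratios
  (`snr()`).

Deliberately *not* modelled: linkage disequilibrium beyond what haplotype
sharing induces between independent sites, population structure and
relatedness, demography-driven frequency spectra, and genotyping error or
ascertainment. Consequently, passing the simulation-study tests demonstrates
correct behaviour of the statistic, the estimator, and the null
distribution under the stated sampling model — it does not certify
calibration on real cohort data with structure or strong LD. Power
constants in particular depend on the realized frequency spectrum, so power
is asserted only as an ordering property (power under an alternative
exceeds the nominal level), never as a number.

Default study conditions (the test suite and the acceptance script use
these): $n = 5000$, $L = 100$, $\tau = \sigma = 1$, $\nu = 0$, 2000
replicates for the type-I-error rate and 200 replicates for the
estimator-MSE and p-value-MSE studies; the null-uniformity check
(Kolmogorov-Smirnov at the 1% level, in both estimated- and true-component
modes) runs at $n = 2000$, $L = 50$ over 1000 replicates. These replicate
counts keep a full run on one CPU in the tens of minutes while leaving the
Monte Carlo error well below the tolerances being asserted; all drivers
accept larger `n_reps`.

## Degenerate inputs and other numerical choices

* Rank-deficient $\tilde X$ (collinear covariates) is detected at the QR
  step — singular values below $\varepsilon\,\max(n, P)\,s_{\max}$ count as
  zero — and reported with the offending column indices.
* Missing genotypes are mean-imputed per locus at ingestion; all-missing
  loci are dropped. Monomorphic loci are dropped (with a warning) when a
  user supplies a raw matrix to `gxe_test()`, since they contribute a
  confounded direction; an empty set after QC is an error, not $p = 1$.
* `n <= L` triggers a warning: the test path assumes more individuals than
  loci.
* The dense engine refuses $n > 2000$ by default (`n_cap`): its only role
  is verification, and an accidental $O(n^3)$ run on cohort data is a
  common foot-gun.
* Genotype coding is additive minor-allele counts, uncentered and
  unweighted — the linear kernel of the model. Per-variant weights can be
  applied by the caller by rescaling columns of $G$ before testing.

## Gene scans

`scan_genes()` maps SNPs to genes by physical position against a
gene-range list (four whitespace-delimited columns: chromosome, start, end,
symbol; 1-based, both ends inclusive; strand is irrelevant for additive
coding), tests every gene containing more than one SNP, and reports the
family-wise Bonferroni threshold $0.05 / (\text{genes tested})$ with the
per-gene table. Multiple-testing machinery beyond that threshold is out of
scope, as are VCF parsing, principal-component computation, kinship, and
Hardy-Weinberg QC — those belong to upstream tools.

## Known limitations

* Continuous traits only; no binary-trait score test.
* One environmental exposure at a time; no multi-exposure kernels.
* Unrelated samples; no kinship variance component.
* The EM is plain (no Newton or information-based acceleration); near
  $\tau = 0$ it relies on the boundary guard rather than speed.
* The exact tail inversion loses accuracy in extreme tails
  ($p \lesssim 10^{-10}$) of *small* spectra, where the integrand is slowly
  decaying and oscillatory; the fault flag and moment-matching fallback
  make this explicit in the output.
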