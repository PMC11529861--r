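---
title: "Sample-specific coexpression networks by empirical-Bayes shrinkage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-specific coexpression networks by empirical-Bayes shrinkage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bonobo)
```

## The model

Bulk expression studies usually summarise co-regulation with one
correlation matrix for the whole cohort. `bonobo` instead attributes a
full covariance/correlation network to every sample. The model treats the
centred log-expression of sample $i$ as multivariate normal,
$x_i - \bar{x} \sim N_g(0, V_i)$, and places a conjugate inverse-Wishart
prior on $V_i$ whose mean is $S_i$, the covariance of the *other* $N-1$
samples. Conjugacy gives a closed-form posterior, and its mean is a convex
combination

$$\Sigma_i \;=\; \delta_i\,(x_i-\bar{x})(x_i-\bar{x})^\top
  \;+\; (1-\delta_i)\, S_i, \qquad \delta_i = \frac{1}{\nu_i - g}.$$

Both terms are positive semidefinite, so every estimated covariance — and
every correlation derived from it by
$r_{jk} = v_{jk}/\sqrt{v_{jj}v_{kk}}$, a congruence transform — is a valid
PSD matrix. That is the structural advantage over interpolation-based and
z-score-product single-sample estimators, which the package also
implements as baselines and which demonstrably produce indefinite
matrices on heterogeneous data.

Assumptions worth keeping in mind: values must be roughly Gaussian (use
the built-in `log2(x+1)` transform for counts), there is no missing-data
mechanism (missing values are an error, never imputed), and constant
genes must be dropped (their variance terms break both calibration and
correlation conversion; `drop_zero_variance = TRUE` does this on load).

## Calibrating the mixing weight

$\delta_i$ is calibrated per sample by an empirical-Bayes argument. Under
the prior, the variance of a diagonal entry of $V_i$ is
$2 s_{kk}^2/(\nu_i - g - 3)$. Summing over genes and solving for $\nu_i$
gives

$$\nu_i = g + 3 + \frac{2\sum_k s_{kk}^2}{\sum_k \eta^{(k)}},$$

where $\eta^{(k)}$ estimates the variance of gene $k$'s variance: leave
out one sample at a time, recompute the gene's variance ($\eta_j^k$, with
the same $N-2$ divisor as $S_i$), and take the population variance
(divisor $N$) of the $N$ values. Consequences the test suite verifies:

- $\delta_i \in (0, 1/3]$ always, and $\nu_i \ge g+3$;
- duplicating the whole sample set shrinks every $\eta^{(k)}$ and hence
  every $\delta_i$: more homogeneous cohorts are shrunk harder toward the
  population network;
- for an $N$-sample homogeneous cohort $\delta_i$ scales like $1/N^2$, so
  at $N = 100$ the calibrated networks sit close to their leave-one-out
  covariances, and the edge tests below are correspondingly powerful.

Perfectly replicated data ($\sum_k \eta^{(k)} = 0$) are handled as the
$\delta \to 0$ limit with a warning: each network equals its leave-one-out
covariance. A fixed $\delta$ for all samples is available via
`bonobo(expr, delta = 0.1)`; values $\ge 1/3$ then preclude p-values
(the edge-variance formula needs $\nu - g > 3$).

Two conventions are deliberately exposed as flags rather than decided for
the user:

- `cov_divisor`: $S_i$ uses the unbiased divisor $N-2$ with the
  leave-one-out mean by default — the prior mean is then an unbiased
  covariance estimate — with `"ml"` ($N-1$) available; the choice only
  matters at small $N$.
- `edge_var`: the edge variance is evaluated at the prior parameters
  $(\nu, S_i)$ by default; `"posterior_params"` evaluates the same
  inverse-Wishart variance formula at the posterior parameters
  $(\nu+1, \Sigma_i)$, which some implementations prefer. The two agree
  as $\delta \to 0$.

Note one asymmetry inherited from the estimation procedure: the diagonal
sum $\sum_k s_{kk}^2$ is per-sample while $\sum_k \eta^{(k)}$ is a single
cohort-level quantity, so samples differ in $\delta_i$ only through their
leave-one-out diagonals.

## Edge significance and sparsification

Inverse-Wishart quantiles have no closed form, so credible regions use a
normal approximation: with $\psi_{jk}^2 =
[(\nu-g+1)s_{jk}^2 + (\nu-g-1)s_{jj}s_{kk}]/[(\nu-g)(\nu-g-3)]$, the edge
$(j,k)$ is retained at level $\alpha$ when
$2(1-\Phi(|\sigma_{jk}|/\psi_{jk})) \le \alpha$ (the absolute value makes
the test two-sided; the retention rule uses $\le$, so an edge exactly at
$\alpha$ is kept). `sparsify()` optionally applies Benjamini–Hochberg
across the $g(g-1)/2$ edges of one network — per network, not across
samples, because each sample's network is a separate inference. Diagonal
entries get a formal p-value but are flagged untestable (a null of zero
variance is not meaningful); `tidy()` drops them.

Numerical policies: correlation entries may exceed 1 by floating-point
error only — overshoot up to $10^{-12}$ is clipped, anything larger
raises an internal-consistency error rather than being hidden. Zero
$\psi_{jk}$ with a nonzero mean yields $p = 0$ with a warning; with a
zero mean, $p = 1$.

All leave-one-out quantities are computed by downdating two global
accumulators (the per-gene sum and the $g \times g$ sum of outer
products), one pass over the samples, so per-sample work is $O(g^2)$ and
peak memory is a couple of $g \times g$ matrices regardless of $N$.

## What the synthetic-data generator emulates

`generate_population()` builds cohorts in which every individual has a
distinct true covariance:

1. a population correlation matrix from a rank-5 factor model with
   uniform(0.3, 1) idiosyncratic variances, scaled to unit diagonal —
   chosen to give the block-structured, moderately dense correlations
   typical of coexpression modules rather than the near-diagonal matrices
   a plain random matrix would give at $g = 100$;
2. per-individual true covariances
   $V_i \sim \mathrm{InvWishart}((\nu_0-g-1)\Sigma_{\mathrm{pop}}, \nu_0)$
   with `population_spread` $\nu_0 = g + 40$, i.e. per-gene variances
   scatter around the population value with roughly 23% relative spread —
   realistic inter-individual heterogeneity without swamping the shared
   structure;
3. gene baseline means $N(6, 2^2)$ on the log2 scale, matching typical
   bulk microarray/log-RNA-seq magnitudes;
4. exactly one observed draw per individual; ground truth for individual
   $i$ is the *empirical* correlation of `truth_draws` (default 200)
   held-out replicate draws under $V_i$, so the truth itself carries
   sampling noise of about $1/\sqrt{200} \approx 0.07$ per entry, shared
   fairly by all methods (the analytic correlation of $V_i$ is available
   in tests for convergence checks);
5. scenario `mixture`: a configurable fraction of individuals come from a
   second population with its own factor-model correlation and per-gene
   mean offsets $N(0, 1)$;
6. scenario `gene_loss`: a configurable gene subset is silenced in a
   configurable sample subset — values replaced by noise of sd $10^{-6}$
   (loud jitter note: exact zeros would trip the zero-variance guard) in
   both the observed draw and the truth draws, so the silencing is part
   of the ground truth.

Replicate seeds are derived deterministically from the master seed
(distinct, collision-free, within 32-bit range), so benchmarks are exactly
reproducible.

What passing benchmarks do **not** show about real data: the generator's
individuals are exchangeable draws from one (or two) inverse-Wishart
populations — there is no batch structure, no count noise or
mean–variance relationship, no library-size variation, and the truth is
defined by replicate draws that real experiments never provide. The
benchmark orderings (shrinkage beats interpolation and z-score products;
errors grow with mixing; sparsification does not hurt recovery of
silenced genes) are claims about this generative family, at the problem
sizes stated below, not about any particular tissue or platform.

## Benchmark design and problem sizes

`run_benchmark()` scores each method's $N$ networks against the
per-individual truth by the squared Frobenius norm,
$\sum_{jk}(e_{jk}-t_{jk})^2$, averaged over individuals. The scaled
variant divides by the variance of the truth's upper-triangle entries —
the normalisation makes errors comparable across truths of different
overall correlation strength (the package defines the divisor this way;
other conventions exist).

The test suite exercises: homogeneous cohorts at $g = 100$,
$N \in \{10, 50, 100\}$ with 20 replicates (the shrinkage estimator's
mean error is below both baselines at every $N$ and decreases with $N$);
mixtures at fractions $\{0.05, 0.25, 0.5\}$ (error nondecreasing in the
mixing fraction); and gene-loss with 1% of genes silenced in 20% of
samples (sparse recovery at $\alpha = 0.05$ no worse than dense on the
silenced block in at least 16 of 20 replicates). These sizes keep the
whole suite to a few minutes while leaving the orderings far from their
decision boundaries; the one deliberately tight margin is the gene-loss
comparison, where the calibrated $\delta \sim 1/N^2$ makes the edge test
so powerful at $N = 100$ that sparse and dense estimates differ on only a
handful of block edges.

## Known limitations

- The Gaussian likelihood is an approximation for log-counts; heavy-tailed
  expression will inflate rank-one deviations and hence $\delta_i$.
- The normal-approximation p-values are marginal per edge; joint credible
  statements over the whole network are out of scope.
- No precision-matrix (partial-correlation) networks, no shrinkage targets
  other than the leave-one-out covariance, and no preprocessing beyond the
  log transform and the zero-variance guard.
- With $N$ just above the minimum of 3, the $N-2$ divisor makes $S_i$
  noisy; results at $N < 10$ should be treated as exploratory.
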