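---
title: "Multi-trait Bayesian variable selection: model, sampler and calibration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-trait Bayesian variable selection: model, sampler and calibration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtbvs)
```

## The model

`mtbvs` performs Bayesian variable selection over multi-SNP regression models
for one or several correlated quantitative traits measured on the same
individuals. Writing $Y$ for the $n \times q$ trait matrix and $X$ for the
$n \times p$ additive genotype matrix (both projected onto the orthogonal
complement of the intercept and any covariates), a model is a subset
$\gamma \subseteq \{1,\dots,p\}$ of SNP columns. Conditional on $\gamma$ the
traits follow a multivariate regression

$$Y = X_\gamma B_\gamma + E, \qquad E_i \sim N_q(0, \Sigma),$$

with a matrix-variate g-prior on the coefficients,
$B_\gamma \mid g, \Sigma \sim MN\!\left(0,\; g\,(X_\gamma^\top X_\gamma)^{-1},\; \Sigma\right)$,
which replicates the covariance structure of the likelihood, and a
Jeffreys-style prior $|\Sigma|^{-(q+1)/2}$ on the residual covariance. Both
$B_\gamma$ and $\Sigma$ integrate out analytically, leaving

$$\log p(Y \mid \gamma, g) = -\tfrac{kq}{2}\log(1+g)
  \;-\; \tfrac{n - c_{\mathrm{eff}}}{2}\,\log\det S(\gamma, g) + \text{const},$$

where $k = \operatorname{rank}(X_\gamma)$,
$S(\gamma,g) = Y^\top Y - \tfrac{g}{1+g}\, Y^\top H_\gamma Y$, $H_\gamma$ is
the orthogonal projector onto the span of $X_\gamma$, and $c_{\mathrm{eff}}$
counts the projected-out columns (intercept plus covariates). The reference
evaluator `log_marginal_likelihood()` computes $H_\gamma$ from a
column-pivoted QR factorization, which also determines $k$, so duplicated or
collinear SNP columns are harmless. The selection coefficient $g$ carries the
Zellner–Siow inverse-gamma(1/2, $n$/2) hyper-prior and is sampled rather than
fixed, giving the coefficients a heavy-tailed marginal prior.

Covariates are removed by projection before the search rather than carried as
always-included regressors. For this conjugate family the two formulations
are equivalent as long as the degrees of freedom use
$n - c_{\mathrm{eff}}$, which `data_bundle()` propagates.

### The sparsity prior

Users state the prior through natural quantities: the expected number of true
associations $E$, its standard deviation $S$, and a truncation multiplier
$F$. Each SNP enters independently with probability $\omega$, and
$\omega \sim \mathrm{Beta}(a, b)$ with $(a, b)$ moment-matched so the
beta-binomial model size has mean $E$ and standard deviation $S$
(the average per-SNP inclusion probability is then exactly $E/p$). A plain
binomial requires $S^2 = E(1 - E/p)$; any elicitation with more spread needs
the beta-binomial, which is why the constructor rejects underdispersed
requests and falls back to the binomial at the degenerate boundary. Models
larger than $T = \lfloor E + F S \rfloor$ get zero mass and the sampler
rejects proposals beyond $T$ outright; with $F = 7$ the discarded prior mass
is about $1 - \Phi(7) \approx 10^{-12}$, while the model space shrinks from
$2^p$ to $\sum_{k \le T}\binom{p}{k}$ (`model_space_size()` computes this
exactly in big-integer arithmetic). The reported "likely range" of the model
size is $[0, E + 3S]$.

## The sampler

`run_ess()` runs an evolutionary stochastic search: $L$ chains target
$\pi(\gamma, g \mid Y)^{1/t_\ell}$ along a geometric temperature ladder
$t_\ell = b^{\ell-1}$ with chain 1 pinned at $t_1 = 1$. Each sweep performs:

1. **Fast-scan Metropolis–Hastings** per chain: a pass over a Bernoulli
   subset of the panel (all SNPs for $p \le 10^4$, a quarter above)
   proposing single-SNP add/delete flips. The flip proposal is symmetric and
   in particular does not depend on the chain's temperature; heated chains
   would otherwise drift to bloated models that are almost always rejected.
2. **One global move**, crossover or exchange with equal probability:
   uniform crossover recombines the inclusion vectors of two random chains
   and accepts the offspring pair jointly under the tempered targets;
   exchange proposes swapping the full states $(\gamma, g)$ of an
   adjacent-temperature pair with the standard parallel-tempering ratio.
3. **A random-walk update of $\log g$** per chain, with the $g'/g$ Jacobian
   in the acceptance ratio.

The ladder base and the $g$ step size adapt only during burn-in (the ladder
toward an exchange acceptance rate in $[0.2, 0.6]$, the step toward 0.35
acceptance); both freeze afterwards so detailed balance holds over the
retained sweeps. Chains are initialized from the truncated size prior and the
$g$ hyper-prior. Every post-burn-in sweep of the non-heated chain is retained
without thinning, because the downstream estimators are defined as plain
frequencies over retained sweeps.

The per-sweep hot path is compiled (RcppArmadillo). Each chain maintains the
inverse Gram matrix of a full-rank basis of its model together with the
$q \times q$ quadratic form entering $S(\gamma, g)$, updated by rank-one
Schur-complement formulas on add/delete proposals; rows of $X^\top X$ are
cached lazily as SNPs are first touched. Columns numerically dependent on the
basis (Schur complement below $10^{-9}$ of the column's squared norm) stay in
the model for the size prior but do not change the likelihood — the same rank
convention as the pivoted-QR reference path, against which the recorded
log-posteriors re-evaluate to $10^{-9}$ in the test suite. States are rebuilt
from scratch every 2,000 sweeps to stop numerical drift, and $\det S$ uses a
symmetrized Cholesky with an eigenvalue-clipping fallback at
$10^{-12} \cdot \mathrm{tr}(S)/q$ for near-singular cases.

## Outputs and calibration

**Best models visited (BMV).** Unique models of the non-heated chain ranked
by model posterior probability — the log-posterior renormalized over the set
of unique visited models. A model visited at several $g$ values is scored by
its best recorded log-posterior: the probability is attached to the model,
not to a $(\gamma, g)$ pair. (Integrating over the visited $g$ values per
model would be the alternative; with $g$ well-mixed the two agree to within
sampling noise, and the maximum is reproducible without binning choices.)

**MPPI.** The marginal posterior probability of inclusion of SNP $j$ is the
fraction of retained sweeps whose model contains $j$ — the plain empirical
estimator, not a Rao-Blackwellized one. Its resolution is one over the number
of retained sweeps, which motivates the clipping constant
$\varepsilon = 1/(10 \cdot \text{retained})$ used when converting an MPPI of
exactly 0 or 1 to a finite Bayes factor.

**Bayes factors and RBF.** $\mathrm{BF} = \frac{m/(1-m)}{\pi/(1-\pi)}$ with
$m$ the MPPI and $\pi = E/p$. The empirical-FDR threshold $m^*$ maps through
the same transform to a group-specific BF threshold, and
$\mathrm{RBF} = \mathrm{BF}/\mathrm{BF}^*$ rescales each SNP's evidence by
its group's baseline. Within a group RBF preserves the BF ranking exactly;
across trait groups it is comparable because each group is standardized by
its own FDR baseline, so `rank_groups_by_rbf()` can order phenotype groups by
their strength of association with one SNP.

**Empirical FDR.** For each trait group the traits' rows are permuted $K$
times (jointly, preserving between-trait correlation) and the sampler re-run
with identical settings. The threshold is the smallest observed MPPI value at
which (pooled null exceedances divided by $K$) over observed exceedances is
at most $\alpha$. Dividing the pooled count by $K$ makes the numerator a
per-dataset expectation; the alternative (no division) makes the estimate
scale with the number of permutations. Null pools may be combined across
trait groups of equal cardinality, which is the default in tree analyses
where the tail of the null needs many draws. Two caveats found while
validating the procedure at desk scale are worth recording. First, the
threshold rule declares at least one SNP whenever the observed maximum MPPI
strictly exceeds every pooled null value — under a true global null with
effectively continuous MPPI values that event has probability about
$1/(K+1)$, so small panels with generous priors will occasionally declare a
single false positive; genome-scale sparsity (where most null MPPIs are
exactly zero) suppresses this through ties. Second, with real signal present
the permuted-null MPPI distribution understates the inclusion noise of
non-causal SNPs in the observed run (models carrying true signal also visit
their LD neighbors), so the realized false-positive share can exceed the
nominal level even though the estimated FDR at $m^*$ is below $\alpha$ by
construction.

## The synthetic study designs

The simulator reproduces the package's reference power-study designs at any
panel size. Genotypes are Hardy–Weinberg draws summed over two haplotypes;
within an LD block each haplotype copies its left neighbour's allele with
probability $\rho$ (sharing the block's allele frequency), giving genotype
correlations exactly $\rho^{|i-j|}$; blocks are independent and stand in for
chromosomes. Defaults for the preset scenarios: $n = 3{,}175$ individuals,
MAF uniform on $[0.05, 0.5]$, four blocks, adjacent correlation
$\rho = 0.6$ (squared correlation 0.36, a plausible level for a panel
already tagged at $r^2 > 0.8$), 20 replicates, and an expected
variance-explained cap of 5% per trait. The error SD of trait $t$ is set to
$\sigma_t^2 = \widehat{\mathrm{Var}}(X_c b_t)(1 - r^2_{\max})/r^2_{\max}$ so
the explained share equals the cap exactly. Scenario MT1 uses the fixed
$8 \times 3$ effect matrix with columns
$(0.2, 0.1, 0.2, 0.1, 0.075, 0.1, 0.075, 0.1)$,
$(0.1, 0.075, 0.1, 0.075, 0.1, 0.2, 0.1, 0.2)$ and
$(0.075, 0.1, 0.075, 0.1, 0.2, 0.1, 0.2, 0.1)$ and residual correlations
0.95/0.50/0.30; MT2 halves the correlations; ST1 is MT1's first trait; ST2
is a single trait with four primary/secondary effect pairs
$(4,1), (1,6), (1.5,3), (4,0.5)$, the secondary placed within 25 kb (five
map positions) of the primary in the same block.

What the generator does *not* emulate: real minor-allele-frequency spectra,
long-range LD and inter-block correlation, population structure,
genotyping error and missingness patterns, and non-normal trait residuals.
Passing recovery tests on these designs therefore demonstrates correctness
of the machinery and calibration under the stated model, not performance on
an arbitrary real cohort.

## Problem sizes used by the test suite

The suite exercises every claim at sizes a single CPU handles comfortably:
oracle-equivalence runs enumerate $p \le 7$ panels ($g$ integrated by
quadrature) against $1.5 \times 10^5$-sweep chains; the multi-trait recovery
study runs the MT1 design at $p = 500$, $n = 1{,}000$ with 55,000 sweeps and
5,000 burn-in over five replicates; the null FDR calibration uses 20
replicates of $p = 500$, $n = 400$ at 6,000 sweeps with $K = 3$
permutations. Full-scale defaults (110,000 sweeps, three chains) remain the
function defaults.

## Numerical and design choices, in brief

- Hardy–Weinberg QC uses the 1-df chi-square test on expected genotype
  counts without continuity correction; an exact test differs only for rare
  genotype classes near the MAF floor.
- Tagging is greedy maximum coverage at $r^2$ strictly above the threshold,
  ties to the lower column index; it is verified against exhaustive minimum
  covers on small panels but is not guaranteed minimal in general.
- The inverse-normal transform uses the $(r - 3/8)/(n + 1/4)$ offset with
  average ranks for ties.
- Missing genotypes are mean-imputed with a warning; model-based imputation
  is out of scope.
- Genotype columns are centered but not variance-scaled: scaling would
  change the g-prior geometry.
- All randomness in a run flows from the single configuration seed through
  R's generator (the compiled sampler consumes the same stream), so equal
  seeds give bit-identical histories.
- A proper inverse-Wishart prior on $\Sigma$ would add two tuning constants
  without changing desk-scale conclusions; the Jeffreys default keeps the
  marginal likelihood free of them.

## Known limitations

Exchange moves always swap $g$ together with $\gamma$; per-move windows are
the only ladder diagnostics. The FDR threshold behaves as discussed above on
small panels. MPPI-based ranking splits evidence across SNPs in strong LD —
interval-based matching (`evaluate_roc(window_bp = ...)`) is the appropriate
reading of power when proxies are acceptable. At genome scale ($p \sim 10^5$)
memory for the lazy $X^\top X$ row cache grows with the number of SNPs ever
visited, and a genome-scale run is a multi-hour computation on one
CPU.
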