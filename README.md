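# mtbvs — multi-trait Bayesian variable selection for GWAS

`mtbvs` searches for the small set of SNPs that jointly predict one or
several correlated quantitative traits, genome-wide. Instead of testing each
SNP marginally, it places a posterior distribution over multi-SNP regression
models and reports which variants — and which *groups of phenotypes* — the
data support. It is aimed at statistical geneticists analyzing cohorts with
multiple related traits (e.g. a lipid panel), and at methodologists who need
a transparent, testable reference implementation of evolutionary stochastic
search for variable selection.

## The model in brief

For traits $Y$ ($n \times q$) and additive genotypes $X$ ($n \times p$),
a model $\gamma$ selects columns of $X$:

$$Y = X_\gamma B_\gamma + E,\qquad
B_\gamma \mid g,\Sigma \sim MN\!\big(0,\, g (X_\gamma^\top X_\gamma)^{-1},\, \Sigma\big),
\qquad g \sim \mathrm{IG}(1/2,\, n/2),$$

with a Jeffreys prior on the residual covariance $\Sigma$. Coefficients and
$\Sigma$ integrate out to the closed-form marginal likelihood
$-\tfrac{kq}{2}\log(1+g) - \tfrac{n-c_{\mathrm{eff}}}{2}\log\det S(\gamma,g)$,
evaluated through a column-pivoted QR factorization. Sparsity comes from a
beta-binomial prior on the model size parameterized by its prior mean $E$ and
SD $S$, truncated at $T = \lfloor E + FS \rfloor$. A parallel-tempered
sampler (per-SNP add/delete scans, crossover and exchange moves, and updates
of $g$) explores the model space; the non-heated chain yields:

- **BMV** — best models visited, ranked by renormalized model posterior
  probability (MPP);
- **MPPI** — per-SNP marginal posterior probability of inclusion;
- **BF / RBF** — per-SNP Bayes factors, and Bayes factors rescaled by a
  group-specific significance baseline so the strength of association of a
  SNP can be *compared across trait groups*;
- **empirical FDR** — MPPI significance thresholds calibrated by rerunning
  the sampler on row-permuted traits.

A simulator for matrix-variate multi-trait phenotypes with LD-blocked
genotypes and variance-explained capping, plus ROC utilities, provides the
power-study harness.

## Worked example

Simulate one replicate of the three-trait reference design (8 causal SNPs on
4 LD blocks, residual trait correlations 0.95/0.50/0.30, 5% variance
explained per trait), then run the search:

```r
library(mtbvs)
scen <- scenario_presets()$MT1
rep1 <- simulate_replicate(scen, p = 200, n = 800, seed = 42)

bd  <- data_bundle(rep1$Y, rep1$G)
pr  <- model_size_prior(E = 8, S = 6, F = 7, p = 200)
fit <- run_ess(bd, pr, g_prior(bd$n),
               sampler_config(n_sweeps = 20000, burn_in = 2000,
                              n_chains = 3, seed = 7))
best_models(fit, max_models = 3)[, c("rank", "snp_ids", "model_size", "mpp")]
sort(compute_mppi(fit), decreasing = TRUE)[1:6]
```

Output (as printed by the code above):

```
  rank                         snp_ids model_size        mpp
1    1        snp1 snp88 snp126 snp192          4 0.79687708
2    2               snp1 snp88 snp126          3 0.06404165
3    3 snp1 snp88 snp125 snp126 snp192          5 0.02120019

  snp1  snp88 snp126 snp192 snp125 snp111
 1.000  1.000  1.000  0.897  0.021  0.018
```

The true causal set in this replicate is snp1, snp4, snp88, snp93, snp111,
snp126, snp177, snp192. The top model (posterior mass 0.80) contains exactly
the four causal SNPs with the largest effects; the four weak-effect SNPs
(0.075–0.1 against 5% total variance explained at n = 800) remain near the
noise floor, which is the expected behavior at this sample size. MPPI = 1.0
means the SNP appeared in every retained model.

Empirical FDR calibration and cross-group ranking follow the same pattern
(`empirical_fdr()`, `marginal_summary()`, `rank_groups_by_rbf()`); a
multi-branch trait-tree analysis with pooled null calibration is available
through `cmd_tree()`, and `inst/cli/mtbvs` exposes `run`, `tree`, `fdr`,
`simulate` and `roc` subcommands for shell use:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "mtbvs", package = "mtbvs"))')" \
    run --config config.yaml --out results/
```

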