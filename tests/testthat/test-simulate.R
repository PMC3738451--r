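test_that("simulated genotypes respect the MAF range, HWE and LD decay", {
  G <- simulate_genotypes(3175, 60, maf_range = c(0.1, 0.5),
                          blocks = rep(20, 3), rho = 0.9, seed = 71)
  X <- G$values
  f <- colMeans(X) / 2
  maf <- pmin(f, 1 - f)
  se <- sqrt(0.5 * 0.5 / (2 * 3175))
  expect_true(all(maf > 0.1 - 3 * se & maf <= 0.5))
  # adjacent correlation within a block recovers rho, decay is geometric
  r_adj <- sapply(c(1:19, 21:39, 41:59), function(j) cor(X[, j], X[, j + 1]))
  expect_equal(mean(r_adj), 0.9, tolerance = 0.02)
  r_lag4 <- sapply(c(1:16, 21:36), function(j) cor(X[, j], X[, j + 4]))
  expect_equal(mean(r_lag4), 0.9^4, tolerance = 0.05)
  # blocks are independent
  r_between <- abs(cor(X[, 1:20], X[, 21:40]))
  expect_lt(mean(r_between), 2 / sqrt(3175) + 0.02)
  # HWE holds per SNP (chi-square test well above the exclusion cutoff)
  qc <- qc_filter(G)
  expect_true(all(qc$report$kept))

  # zero decay gives independent SNPs
  G0 <- simulate_genotypes(2000, 30, blocks = rep(10, 3), rho = 0, seed = 72)
  r0 <- abs(cor(G0$values))
  expect_lt(mean(r0[upper.tri(r0)]), 2 / sqrt(2000))
  # map bookkeeping
  expect_identical(unique(G$map$chromosome), c("1", "2", "3"))
  expect_identical(G$map$position[1:3], as.integer(c(1, 5001, 10001)))
})

test_that("error-variance calibration hits the variance-explained cap exactly", {
  set.seed(73)
  n <- 20000
  G <- genotype_matrix(matrix(rbinom(n, 2, 0.5), n, 1))
  sig <- calibrate_error_variance(G, 1, matrix(0.2, 1, 1), max_r2 = 0.05)
  # Var(Xb) under HWE with f = 0.5: 2 f (1-f) b^2 = 0.02; sigma^2 = 0.02 * 0.95/0.05
  expect_equal(sig^2, 0.38, tolerance = 0.02)

  # empirical identity: explained share is exactly max_r2 by construction
  v <- var(as.numeric(G$values * 0.2))
  expect_equal(v / (v + sig^2), 0.05, tolerance = 1e-12)

  # zero effects get unit error SD; scaling effects scales sigma^2 by 4
  B <- cbind(c(0.2, 0.1), c(0, 0))
  G2 <- genotype_matrix(matrix(rbinom(400, 2, 0.3), 200, 2))
  s2 <- calibrate_error_variance(G2, 1:2, B, 0.05)
  expect_identical(s2[2], 1)
  s2x <- calibrate_error_variance(G2, 1:2, 2 * B, 0.05)
  expect_equal(s2x[1]^2, 4 * s2[1]^2, tolerance = 1e-12)

  expect_error(calibrate_error_variance(
    genotype_matrix(matrix(1, 50, 1)), 1, matrix(1, 1, 1), 0.05),
    "zero genetic variance")
})

test_that("matrix-variate traits reproduce the residual correlations and the cap", {
  scen <- scenario_presets()$MT1
  G <- simulate_genotypes(3175, 40, maf_range = scen$maf_range,
                          blocks = rep(10, 4), rho = scen$rho, seed = 74)
  causal <- c(3, 7, 13, 17, 23, 27, 33, 37)
  sigma <- calibrate_error_variance(G, causal, scen$B, scen$max_r2)
  Y <- simulate_traits(G, causal, scen$B, scen$R, sigma, seed = 75)
  E <- Y$values - G$values[, causal] %*% scen$B
  Rhat <- cor(E)
  expect_equal(Rhat[1, 2], 0.95, tolerance = 0.02)
  expect_equal(Rhat[2, 3], 0.50, tolerance = 0.04)
  expect_equal(Rhat[1, 3], 0.30, tolerance = 0.05)
  # per-trait variance explained by the causal SNPs (Monte-Carlo band)
  for (t in 1:3) {
    r2 <- summary(lm(Y$values[, t] ~ G$values[, causal]))$r.squared
    expect_lt(abs(r2 - 0.05), 0.02)
  }
  # null effects give null trait-SNP correlations
  Y0 <- simulate_traits(G, causal, matrix(0, 8, 3), scen$R, c(1, 1, 1), seed = 76)
  r <- abs(cor(Y0$values[, 1], G$values))
  expect_gte(mean(r <= 4 / sqrt(3175)), 0.95)
  expect_error(simulate_traits(G, causal, matrix(1, 8, 2),
                               matrix(c(1, 2, 2, 1), 2), c(1, 1)),
               "positive-definite")
})

test_that("the four scenario presets encode the reference power-study designs", {
  pres <- scenario_presets()
  expect_named(pres, c("MT1", "MT2", "ST1", "ST2"))
  mt1 <- pres$MT1
  expect_identical(dim(mt1$B), c(8L, 3L))
  expect_equal(mt1$B[, 1], c(0.2, 0.1, 0.2, 0.1, 0.075, 0.1, 0.075, 0.1),
               ignore_attr = TRUE)
  expect_equal(mt1$B[, 2], c(0.1, 0.075, 0.1, 0.075, 0.1, 0.2, 0.1, 0.2),
               ignore_attr = TRUE)
  expect_equal(mt1$B[, 3], c(0.075, 0.1, 0.075, 0.1, 0.2, 0.1, 0.2, 0.1),
               ignore_attr = TRUE)
  expect_equal(mt1$R[lower.tri(mt1$R)], c(0.95, 0.30, 0.50))
  expect_true(all(eigen(mt1$R)$values > 0))
  mt2 <- pres$MT2
  expect_equal(mt2$R[lower.tri(mt2$R)], c(0.475, 0.15, 0.25))
  expect_identical(mt1$max_r2, 0.05)
  expect_identical(mt1$n, 3175)
  expect_identical(mt1$n_replicates, 20)
  st1 <- pres$ST1
  expect_identical(st1$q, 1)
  expect_equal(st1$B[, 1], mt1$B[, 1], ignore_attr = TRUE)
  st2 <- pres$ST2
  expect_equal(st2$B[, 1], c(4, 1, 1, 6, 1.5, 3, 4, 0.5), ignore_attr = TRUE)
})

test_that("replicates place two causal SNPs per block, nearby for ST2", {
  rep1 <- simulate_replicate(scenario_presets()$MT1, p = 120, n = 200, seed = 77)
  expect_identical(length(rep1$causal), 8L)
  expect_identical(as.integer(table(rep1$truth$block)), rep(2L, 4))
  expect_identical(dim(rep1$Y$values), c(200L, 3L))

  rep2 <- simulate_replicate(scenario_presets()$ST2, p = 120, n = 200, seed = 78)
  expect_identical(length(rep2$causal), 8L)
  for (b in unique(rep2$truth$block)) {
    pair <- rep2$truth$index[rep2$truth$block == b]
    pos <- rep2$G$map$position[pair]
    expect_lte(abs(diff(pos)), 25000)
  }
  # replicate directories round-trip
  tmp <- withr::local_tempdir()
  write_replicate(rep1, tmp)
  expect_true(all(file.exists(file.path(tmp, c("genotypes.tsv", "traits.tsv",
                                               "truth.tsv", "genotypes.map")))))
  G2 <- read_genotypes(file.path(tmp, "genotypes.tsv"),
                       map_file = file.path(tmp, "genotypes.map"))
  expect_equal(G2$values, rep1$G$values, ignore_attr = TRUE)
})

test_that("ROC evaluation matches a hand-enumerated toy and its edge cases", {
  # 10 SNPs, truths at 3 and 7
  score <- c(0.1, 0.9, 0.8, 0.2, 0.05, 0.3, 0.7, 0.6, 0.02, 0.01)
  truth <- c(3, 7)
  roc <- evaluate_roc(score, truth)
  # thresholds descending: 0.9 declares {2}: 0 tp, 1 fp; 0.8 declares {2,3}: 1 tp;
  # 0.7 declares {2,3,7}: 2 tp, 1 fp; ...
  expect_equal(roc$power[roc$threshold == 0.9], 0)
  expect_equal(roc$power[roc$threshold == 0.8], 0.5)
  expect_equal(roc$power[roc$threshold == 0.7], 1)
  expect_equal(roc$fp[roc$threshold == 0.7], 1)
  expect_equal(roc$fp[roc$threshold == 0.01], 8)
  expect_equal(roc$fp_prop, roc$fp / 10)

  # perfect scores: full power at zero false positives
  sc2 <- rep(0, 10); sc2[truth] <- 1
  roc2 <- evaluate_roc(sc2, truth)
  expect_equal(roc2$power[1], 1)
  expect_equal(roc2$fp[1], 0)

  # windowed matching collapses a nearby hit into a true positive
  pos <- seq(0, by = 10000, length.out = 10)
  roc3 <- evaluate_roc(c(0, 0.9, 0, 0, 0, 0, 0, 0, 0, 0), truth = 3,
                       positions = pos, window_bp = 25000)
  expect_equal(roc3$power[roc3$threshold == 0.9], 1)
  expect_equal(roc3$fp[roc3$threshold == 0.9], 0)
  # and dedups clustered false positives into one interval
  roc4 <- evaluate_roc(c(0.9, 0.8, 0, 0, 0, 0, 0, 0, 0, 0), truth = 10,
                       positions = pos, window_bp = 25000)
  expect_equal(roc4$fp[roc4$threshold == 0.8], 1)

  # random scores track the diagonal
  set.seed(79)
  devs <- replicate(40, {
    sc <- runif(200)
    tr <- sample(200, 4)
    r <- evaluate_roc(sc, tr)
    i <- which.min(abs(r$n_declared - 50))
    r$power[i] - 50 / 200
  })
  expect_lt(abs(mean(devs)), 0.05)
})
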