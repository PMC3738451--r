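make_geno_from_counts <- function(counts) {
  # one column per element of `counts`, each a c(n0, n1, n2) genotype count
  n <- sum(counts[[1]])
  vals <- sapply(counts, function(ct) rep(c(0, 1, 2), times = ct))
  genotype_matrix(matrix(vals, nrow = n))
}

test_that("qc_filter applies the MAF, HWE and monomorphism rules", {
  G <- make_geno_from_counts(list(
    c(98, 2, 0),    # MAF exactly 0.01: kept (exclusion is strict <)
    c(0, 100, 0),   # all heterozygous: HWE chi-square = n = 100, p << 1e-4
    c(100, 0, 0),   # monomorphic
    c(50, 40, 10)   # ordinary SNP
  ))
  res <- qc_filter(G)
  expect_equal(res$report$kept, c(TRUE, FALSE, FALSE, TRUE))
  expect_equal(res$report$maf[1], 0.01)
  # hand-computed 1-df chi-square for (0,100,0): expected (25,50,25)
  chi2 <- (0 - 25)^2 / 25 + (100 - 50)^2 / 50 + (0 - 25)^2 / 25
  expect_equal(chi2, 100)
  expect_equal(res$report$hwe_p[2], pchisq(100, 1, lower.tail = FALSE))
  expect_identical(res$report$reason[3], "monomorphic")
  expect_identical(ncol(res$genotypes$values), 2L)
})

test_that("qc_filter is order-independent and errors on an empty panel", {
  set.seed(42)
  G <- genotype_matrix(matrix(rbinom(600, 2, rep(runif(12, 0.02, 0.5), each = 50)),
                              nrow = 50))
  perm <- sample(12)
  Gp <- genotype_matrix(G$values[, perm], snp_ids = G$snp_ids[perm])
  kept1 <- qc_filter(G)$report$kept
  kept2 <- qc_filter(Gp)$report$kept
  expect_identical(kept1[perm], kept2)

  mono <- genotype_matrix(matrix(0, 20, 3))
  expect_error(qc_filter(mono), "empty panel")
})

test_that("greedy tagging collapses duplicates and keeps independent SNPs", {
  set.seed(7)
  base <- rbinom(80, 2, 0.4)
  G <- genotype_matrix(sapply(1:5, function(i) base))
  res <- greedy_tag(G, r2 = 0.8)
  expect_identical(ncol(res$tags$values), 1L)
  expect_true(all(res$assignment == res$tags$snp_ids[1]))

  Gi <- genotype_matrix(sapply(1:6, function(i) rbinom(500, 2, 0.4)))
  resi <- greedy_tag(Gi, r2 = 0.8)
  expect_identical(ncol(resi$tags$values), 6L)
})

test_that("greedy tagging matches the brute-force minimum cover on a chain", {
  # construct a chain A~B strong, B~C strong, A~C weak via haplotype copies
  set.seed(11)
  n <- 4000
  b <- rbinom(n, 1, 0.5); b2 <- rbinom(n, 1, 0.5)
  copy <- function(h, rho) ifelse(runif(n) < rho, h, rbinom(n, 1, 0.5))
  a <- copy(b, 0.92); a2 <- copy(b2, 0.92)
  cc <- copy(b, 0.92); cc2 <- copy(b2, 0.92)
  G <- genotype_matrix(cbind(A = a + a2, B = b + b2, C = cc + cc2))
  r2 <- cor(G$values)^2
  expect_gt(r2["A", "B"], 0.8); expect_gt(r2["B", "C"], 0.8)
  expect_lt(r2["A", "C"], 0.8)

  res <- greedy_tag(G, r2 = 0.8)
  expect_identical(res$tags$snp_ids, "B")
  expect_identical(unname(res$assignment), rep("B", 3))

  # brute-force minimum cover over all non-empty tag subsets
  covers <- r2 > 0.8; diag(covers) <- TRUE
  subsets <- all_models(3)[-1]
  valid <- Filter(function(s) all(apply(covers[, s, drop = FALSE], 1, any)), subsets)
  best <- min(lengths(valid))
  expect_identical(length(res$tags$snp_ids), best)
})

test_that("every SNP is covered by its assigned tag above the threshold", {
  set.seed(3)
  G <- simulate_genotypes(600, 40, blocks = rep(8, 5), rho = 0.85)
  res <- greedy_tag(G, r2 = 0.5)
  r2 <- cor(impute_mean(G))^2
  for (i in seq_along(res$assignment)) {
    tag <- res$assignment[i]
    expect_true(tag %in% res$tags$snp_ids)
    if (G$snp_ids[i] != tag) {
      expect_gt(r2[G$snp_ids[i], tag], 0.5)
    }
  }
})

test_that("inverse-normal transform uses the rank-3/8 convention", {
  out <- inverse_normal_transform(c(5, 1, 3))
  expect_equal(out, qnorm((c(3, 1, 2) - 3 / 8) / 3.25), tolerance = 1e-12)
  expect_equal(out, c(0.870, -0.870, 0.000), tolerance = 1e-3)

  set.seed(1)
  y <- rlnorm(101)
  z <- inverse_normal_transform(y)
  expect_identical(order(z), order(y))
  # idempotent on an already-transformed symmetric vector
  expect_equal(inverse_normal_transform(out), out, tolerance = 1e-12)

  # ties share the average rank
  zt <- inverse_normal_transform(c(2, 2, 1))
  expect_equal(zt[1], zt[2])
  expect_error(inverse_normal_transform(rep(1, 5)), "constant")
  expect_error(inverse_normal_transform(c(1, NA, 3)), "missing")
})

test_that("covariate adjustment projects exactly and reports rank problems", {
  y <- matrix(c(1, 2, 3, 4), 4, 1)
  G <- matrix(rep(c(0, 1), 2), 4, 1)
  cov <- matrix(c(1, 1, 2, 2), 4, 1)
  adj <- adjust_for_covariates(y, G, cov)
  expect_equal(as.numeric(adj$Y), c(-0.5, 0.5, -0.5, 0.5), tolerance = 1e-12)
  expect_identical(adj$c_eff, 2L)

  # intercept-only: centering
  adj0 <- adjust_for_covariates(y, G, NULL)
  expect_equal(as.numeric(adj0$Y), as.numeric(y - mean(y)), tolerance = 1e-12)

  # idempotence and exact orthogonality on a larger problem
  set.seed(5)
  n <- 60
  Y <- matrix(rnorm(2 * n), n, 2)
  Gm <- matrix(rbinom(3 * n, 2, 0.3), n, 3)
  C <- cbind(age = rnorm(n), bmi = rnorm(n))
  a1 <- adjust_for_covariates(Y, Gm, C)
  a2 <- adjust_for_covariates(a1$Y, a1$X, C)
  expect_equal(a1$Y, a2$Y, tolerance = 1e-10)
  Z <- cbind(1, C)
  expect_lt(max(abs(crossprod(Z, a1$Y))), 1e-8 * norm(Y, "F"))
  expect_lt(max(abs(crossprod(Z, a1$X))), 1e-8 * norm(Gm, "F"))

  Cbad <- cbind(age = C[, 1], age2 = 2 * C[, 1])
  expect_error(adjust_for_covariates(Y, Gm, Cbad), "age2")
})

test_that("genotype and trait files round-trip in both dialects", {
  tmp <- withr::local_tempdir()
  set.seed(9)
  G <- simulate_genotypes(30, 5, seed = 2)
  G$values[3, 2] <- NA
  f <- file.path(tmp, "geno.tsv")
  write_genotypes(G, f)
  G2 <- read_genotypes(f)
  expect_equal(G2$values, G$values, ignore_attr = TRUE)
  expect_identical(G2$snp_ids, G$snp_ids)

  # PLINK RAW dialect
  raw <- file.path(tmp, "geno.raw")
  hdr <- c("FID IID PAT MAT SEX PHENOTYPE rs1_A rs2_C")
  rows <- apply(cbind(1:4, 1:4, 0, 0, 1, -9,
                      matrix(c(0, 1, 2, NA, 2, 2, 1, 0), 4, 2)), 1,
                paste, collapse = " ")
  writeLines(c(hdr, rows), raw)
  Gr <- read_genotypes(raw)
  expect_identical(Gr$snp_ids, c("rs1", "rs2"))
  expect_identical(dim(Gr$values), c(4L, 2L))
  expect_true(is.na(Gr$values[4, 1]))

  # map + id-checked trait table
  mapf <- file.path(tmp, "geno.map")
  writeLines(sprintf("%s\t%s\t%d", G$snp_ids, "1", seq(1, by = 100, length.out = 5)), mapf)
  G3 <- read_genotypes(f, map_file = mapf)
  expect_identical(G3$map$position, as.integer(seq(1, by = 100, length.out = 5)))

  tf <- file.path(tmp, "traits.tsv")
  writeLines(c("id\ttg\thdl", sprintf("ind%d\t%.2f\t%.2f", 1:3, rnorm(3), rnorm(3))), tf)
  Y <- read_trait_table(tf, id_col = "id", ids = paste0("ind", 1:3))
  expect_identical(colnames(Y), c("tg", "hdl"))
  expect_error(read_trait_table(tf, id_col = "id", ids = paste0("x", 1:3)),
               "row order")
})

test_that("mean imputation warns with the imputed fraction and fills columns means", {
  G <- genotype_matrix(matrix(c(0, 1, 2, NA, 1, 1, 1, 1), 4, 2))
  expect_warning(X <- impute_mean(G), "12.50%")
  expect_equal(as.numeric(X[4, 1]), 1)
})
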