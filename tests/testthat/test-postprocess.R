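# a tiny fitted object for postprocess tests without re-running the sampler
stub_fit <- function(models, logpost = NULL, g = NULL, p = 6,
                     E = 1.5, S = 1.5) {
  n_ret <- length(models)
  structure(list(
    models = models,
    history = data.frame(sweep = seq_len(n_ret),
                         model_size = lengths(models),
                         log_posterior = if (is.null(logpost)) rep(-10, n_ret) else logpost,
                         g = if (is.null(g)) rep(50, n_ret) else g),
    traces = list(model_size = matrix(lengths(models)),
                  log_posterior = matrix(if (is.null(logpost)) rep(-10, n_ret) else logpost),
                  g = matrix(if (is.null(g)) rep(50, n_ret) else g)),
    acceptance = list(), ladder = 1,
    data = list(n = 100, p = p, q = 1, c_eff = 1,
                snp_ids = paste0("snp", seq_len(p)), trait_names = "y"),
    size_prior = model_size_prior(E = E, S = S, F = 3, p = p),
    g_prior = g_prior(100),
    config = sampler_config(n_sweeps = n_ret, burn_in = 0, n_chains = 1)),
    class = "ess_fit")
}

test_that("model posterior probabilities renormalize over unique visited models", {
  fit <- stub_fit(list(1L, c(1L, 2L), 1L, 3L),
                  logpost = c(-5, -5, -5, -1e5))
  bm <- best_models(fit)
  expect_equal(sum(bm$mpp), 1, tolerance = 1e-10)
  # two models tie at the top with equal log-posterior -> 0.5 each
  expect_equal(bm$mpp[1:2], c(0.5, 0.5), tolerance = 1e-6)
  # lexicographic tie-break: model {1} before {1,2}
  expect_identical(bm$model[[1]], 1L)
  expect_identical(bm$model[[2]], c(1L, 2L))
  expect_equal(bm$n_visits[1], 2L)

  single <- best_models(stub_fit(list(2L), logpost = -3))
  expect_equal(single$mpp, 1)
})

test_that("a model visited at several g values is scored by its best log-posterior", {
  fit <- stub_fit(list(1L, 1L, 2L), logpost = c(-8, -4, -4), g = c(10, 90, 50))
  bm <- best_models(fit)
  expect_equal(bm$log_posterior[bm$snp_ids == "snp1"], -4)
  expect_equal(bm$mpp[1], 0.5, tolerance = 1e-10)
})

test_that("MPPI is the inclusion frequency over retained sweeps", {
  fit <- stub_fit(list(c(1L, 2L), 1L, c(1L, 3L), 1L))
  mppi <- compute_mppi(fit)
  expect_equal(unname(mppi), c(1, 0.25, 0.25, 0, 0, 0))
  expect_named(mppi, paste0("snp", 1:6))
})

test_that("Bayes factor transform matches direct odds arithmetic", {
  expect_equal(bayes_factor_from_mppi(0.5, 0.5)$bf, 1)
  pi0 <- 1e-4
  res <- bayes_factor_from_mppi(0.9, pi0)
  expect_equal(res$bf, 89991.0, tolerance = 1e-6)
  expect_equal(res$log10_bf, 4.954, tolerance = 1e-3)
  # m = pi -> posterior odds equal prior odds
  expect_equal(bayes_factor_from_mppi(pi0, pi0)$bf, 1, tolerance = 1e-8)
  # strictly increasing in m, strictly decreasing in pi
  ms <- seq(0.1, 0.9, by = 0.1)
  expect_true(all(diff(bayes_factor_from_mppi(ms, pi0)$bf) > 0))
  pis <- c(1e-5, 1e-4, 1e-3, 1e-2)
  bfs <- vapply(pis, function(x) bayes_factor_from_mppi(0.5, x)$bf, numeric(1))
  expect_true(all(diff(bfs) < 0))
  # clipping keeps extreme MPPIs finite
  expect_true(is.finite(bayes_factor_from_mppi(1, pi0, eps = 1e-5)$bf))
  expect_true(bayes_factor_from_mppi(0, pi0, eps = 1e-5)$bf > 0)
})

test_that("the group BF threshold is the same transform and is monotone", {
  expect_equal(bf_threshold(1e-4, 1e-4), 1)
  expect_equal(bf_threshold(0.9, 1e-4), 89991.0, tolerance = 1e-6)
  expect_lt(bf_threshold(0.5, 1e-4), bf_threshold(0.9, 1e-4))
})

test_that("RBF standardizes by the baseline and preserves within-group ranks", {
  expect_equal(rbf(50, 50), 1)
  # cross-group ordering can flip relative to raw BFs
  expect_equal(rbf(100, 50), 2)
  expect_equal(rbf(120, 80), 1.5)
  expect_gt(rbf(100, 50), rbf(120, 80))
  bfs <- c(5, 1, 40, 0.2)
  expect_identical(order(rbf(bfs, 7)), order(bfs))
})

test_that("groups are ranked by RBF with cardinality tie-breaks", {
  mk_summary <- function(rbf10, card, group) {
    s <- data.frame(snp_id = c("snpA", "snpB"), mppi = c(0.9, 0.1),
                    bf = c(10, 1), log10_bf = c(1, 0),
                    log10_rbf = c(rbf10, -1), significant = c(TRUE, FALSE),
                    in_top_bmv = c(TRUE, FALSE))
    attr(s, "cardinality") <- card
    s
  }
  sums <- list(g1 = mk_summary(log10(5), 1),
               g2 = mk_summary(log10(2), 2),
               g3 = mk_summary(log10(9), 3))
  ranked <- rank_groups_by_rbf("snpA", sums)
  expect_identical(ranked$group, c("g3", "g1", "g2"))

  # identical RBFs: larger cardinality first, then name
  ties <- list(a = mk_summary(0.5, 1), b = mk_summary(0.5, 3), c = mk_summary(0.5, 3))
  expect_identical(rank_groups_by_rbf("snpA", ties)$group, c("b", "c", "a"))

  expect_identical(rank_groups_by_rbf("snpA", sums["g2"])$group, "g2")
  sums$g1$snp_id <- c("other", "snpB")
  expect_warning(r2 <- rank_groups_by_rbf("snpA", sums), "absent")
  expect_identical(nrow(r2), 2L)
})

test_that("marginal summary assembles thresholds, flags and the top model", {
  fit <- stub_fit(list(c(1L, 2L), 1L, c(1L, 3L), 1L))
  s <- marginal_summary(fit, mppi_threshold = 0.25)
  expect_true(s$significant[1])
  expect_identical(sum(s$significant), 3L)
  expect_true(s$in_top_bmv[1])
  expect_equal(attr(s, "bf_threshold"),
               bf_threshold(0.25, fit$size_prior$pi_avg))
  # with an infinite threshold nothing is declared
  s2 <- marginal_summary(fit, mppi_threshold = Inf)
  expect_false(any(s2$significant))
})

test_that("diagnostics expose shrinkage, burn-in and first-visit sweeps", {
  bd <- toy_bundle(30, 5, 1, seed = 51, causal = 2, beta = 0.8)
  pr <- model_size_prior(E = 1.5, S = 1.5, F = 3, p = 5)
  fit <- run_ess(bd, pr, g_prior(bd$n),
                 sampler_config(n_sweeps = 800, burn_in = 100, n_chains = 2, seed = 3))
  d <- diagnostics(fit)
  expect_equal(d$shrinkage$shrinkage, d$shrinkage$g / (1 + d$shrinkage$g),
               tolerance = 1e-12)
  expect_identical(d$burn_in, 100L)
  expect_true(all(d$first_visits$first_visit_sweep <= 800))
  expect_true(all(d$first_visits$first_visit_sweep > 100))
  expect_identical(max(d$log_posterior$chain), 2L)
  # plotting works headlessly
  tmp <- withr::local_tempfile(fileext = ".png")
  grDevices::png(tmp); plot(d); grDevices::dev.off()
  expect_true(file.exists(tmp))
})
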