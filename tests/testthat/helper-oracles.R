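# Independent oracles and small fixtures used across the suite.

# Dense normal-equations log marginal likelihood: explicit projector through
# (Xg' Xg)^{-1}, no QR. Assumes the selected columns have full rank.
dense_logml <- function(Y, X, gamma, g, c_eff = 1) {
  n <- nrow(Y); q <- ncol(Y); neff <- n - c_eff
  YtY <- crossprod(Y)
  if (length(gamma) == 0) {
    return(-neff / 2 * as.numeric(determinant(YtY)$modulus))
  }
  Xg <- X[, gamma, drop = FALSE]
  k <- qr(Xg)$rank
  H <- Xg %*% solve(crossprod(Xg)) %*% t(Xg)
  S <- YtY - g / (1 + g) * crossprod(Y, H %*% Y)
  -(k * q / 2) * log1p(g) - neff / 2 * as.numeric(determinant(S)$modulus)
}

# All subsets of 1..p as a list of integer vectors.
all_models <- function(p) {
  out <- list(integer(0))
  for (j in seq_len(p)) {
    out <- c(out, lapply(out, function(m) c(m, j)))
  }
  out
}

# Exhaustive posterior over models with g integrated out by quadrature.
# Returns a data.frame with one row per model: key, log-evidence, posterior
# probability, and the implied per-SNP inclusion probabilities as an attr.
enumerate_posterior <- function(bundle, size_prior, gp, rel.tol = 1e-9) {
  models <- all_models(bundle$p)
  log_ev <- vapply(models, function(m) {
    lp_gamma <- log_prior_model(m, size_prior)
    if (!is.finite(lp_gamma)) return(-Inf)
    f <- function(g) {
      vapply(g, function(gi) {
        log_marginal_likelihood(bundle, m, gi) + log_prior_g(gi, gp)
      }, numeric(1))
    }
    # locate the mode on a log grid, then integrate exp(f - shift)
    grid <- exp(seq(log(1e-2), log(1e6), length.out = 60))
    shift <- max(f(grid))
    val <- stats::integrate(function(g) exp(f(g) - shift), 0, Inf,
                            rel.tol = rel.tol, subdivisions = 500L)$value
    lp_gamma + shift + log(val)
  }, numeric(1))
  post <- exp(log_ev - max(log_ev))
  post <- post / sum(post)
  mppi <- vapply(seq_len(bundle$p), function(j) {
    sum(post[vapply(models, function(m) j %in% m, logical(1))])
  }, numeric(1))
  out <- data.frame(key = vapply(models, paste, character(1), collapse = ","),
                    log_evidence = log_ev, posterior = post,
                    stringsAsFactors = FALSE)
  attr(out, "mppi") <- mppi
  attr(out, "models") <- models
  out
}

# Small genotype/trait fixture with a known signal.
make_toy <- function(n, p, q, causal = integer(0), beta = 0.5, seed = 1,
                     maf = 0.3) {
  set.seed(seed)
  G <- matrix(rbinom(n * p, 2, maf), n, p)
  # guard against monomorphic columns in tiny samples
  for (j in seq_len(p)) {
    if (length(unique(G[, j])) < 2) G[seq_len(2), j] <- c(0, 1)
  }
  B <- matrix(0, p, q)
  if (length(causal)) B[causal, ] <- beta
  Y <- G %*% B + matrix(rnorm(n * q), n, q)
  list(G = G, Y = Y, B = B)
}

# Bundle around make_toy for likelihood/sampler tests.
toy_bundle <- function(n = 30, p = 6, q = 2, seed = 1, causal = integer(0),
                       beta = 0.5) {
  toy <- make_toy(n, p, q, causal = causal, beta = beta, seed = seed)
  data_bundle(toy$Y, toy$G)
}

# Frequency table of visited models from an ess_fit, as named proportions.
model_freqs <- function(fit) {
  keys <- vapply(fit$models, paste, character(1), collapse = ",")
  tab <- table(keys)
  as.numeric(tab) / length(keys) -> pr
  stats::setNames(pr, names(tab))
}

# Total variation distance between a sampled frequency table and an
# enumerated posterior (both keyed by comma-separated model indices).
tv_distance <- function(freqs, enum) {
  keys <- union(names(freqs), enum$key)
  f <- stats::setNames(rep(0, length(keys)), keys)
  f[names(freqs)] <- freqs
  g <- stats::setNames(rep(0, length(keys)), keys)
  g[enum$key] <- enum$posterior
  sum(abs(f - g)) / 2
}
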