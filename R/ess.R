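#' Sampler configuration
#'
#' Settings of the evolutionary stochastic search sampler. Defaults mirror a
#' full genome-wide run (110,000 sweeps with 10,000 burn-in and three tempered
#' chains); scale them down for small panels.
#'
#' Every sweep performs one fast-scan Metropolis-Hastings pass per chain
#' (single-SNP add/delete flips over a random subset of the panel), one global
#' move (uniform crossover or an exchange of adjacent-temperature states,
#' chosen with probability `p_crossover`), and one random-walk update of the
#' selection coefficient g per chain. The geometric temperature ladder
#' `t_l = b^(l-1)` and the g proposal step are adapted during burn-in only:
#' the ladder toward an exchange acceptance rate inside
#' `[exchange_target[1], exchange_target[2]]`, the g step toward an acceptance
#' rate of `g_acc_target`.
#'
#' @param n_sweeps total sweeps (default 110000).
#' @param burn_in sweeps discarded as burn-in (default 10000).
#' @param n_chains number of tempered chains (default 3; chain 1 is the
#'   non-heated chain with temperature exactly 1).
#' @param seed integer seed; every source of randomness in the run flows from
#'   it.
#' @param scan_fraction expected fraction of SNPs visited per fast scan;
#'   `NULL` chooses 1 for panels up to 10,000 SNPs and 0.25 above.
#' @param p_crossover probability that the per-sweep global move is a
#'   crossover rather than an exchange (default 0.5).
#' @param ladder_base initial base of the geometric temperature ladder.
#' @param g_step initial random-walk standard deviation on log g.
#' @param exchange_target acceptance-rate band for ladder tuning.
#' @param g_acc_target target acceptance rate of the g update.
#' @param adapt_window sweeps between adaptation updates during burn-in.
#' @param refresh_every sweeps between full recomputations of the cached
#'   factorizations (guards against numerical drift).
#' @param record_all_chains record size/log-posterior/g traces for all chains
#'   (`TRUE`, default) or only the non-heated chain.
#' @return object of class `sampler_config`.
#' @export
sampler_config <- function(n_sweeps = 110000, burn_in = 10000, n_chains = 3,
                           seed = NULL, scan_fraction = NULL, p_crossover = 0.5,
                           ladder_base = 1.3, g_step = 1,
                           exchange_target = c(0.2, 0.6), g_acc_target = 0.35,
                           adapt_window = 100, refresh_every = 2000,
                           record_all_chains = TRUE) {
  stopifnot(burn_in < n_sweeps, n_chains >= 1, p_crossover >= 0, p_crossover <= 1,
            ladder_base > 1, g_step > 0, length(exchange_target) == 2)
  structure(list(n_sweeps = as.integer(n_sweeps), burn_in = as.integer(burn_in),
                 n_chains = as.integer(n_chains), seed = seed,
                 scan_fraction = scan_fraction, p_crossover = p_crossover,
                 ladder_base = ladder_base, g_step = g_step,
                 exchange_target = exchange_target, g_acc_target = g_acc_target,
                 adapt_window = as.integer(adapt_window),
                 refresh_every = as.integer(refresh_every),
                 record_all_chains = record_all_chains),
            class = "sampler_config")
}

#' Run the evolutionary stochastic search sampler
#'
#' Samples model indicators and the selection coefficient g from the joint
#' posterior with parallel tempered chains. Chains are initialized with
#' independent draws of the model from the truncated size prior and of g from
#' its hyper-prior. The retained history covers every post-burn-in sweep of
#' the non-heated chain; no thinning is applied, matching the definitions of
#' the model posterior probability and the marginal posterior probability of
#' inclusion downstream.
#'
#' @param data a [data_bundle()].
#' @param size_prior a [model_size_prior()] (its panel size must match the
#'   bundle).
#' @param gp a [g_prior()].
#' @param config a [sampler_config()].
#' @return object of class `ess_fit` with elements
#'   \describe{
#'     \item{models}{list of integer vectors, the visited model of each
#'       retained sweep of the non-heated chain (1-based SNP columns).}
#'     \item{history}{data.frame with `sweep`, `model_size`, `log_posterior`,
#'       `g` for the retained sweeps.}
#'     \item{traces}{matrices `model_size`, `log_posterior`, `g` over all
#'       sweeps (columns = chains).}
#'     \item{acceptance}{move counters.}
#'     \item{ladder}{final temperature ladder.}
#'     \item{data, size_prior, g_prior, config}{inputs (data stores
#'       dimensions and SNP ids only).}
#'   }
#' @export
run_ess <- function(data, size_prior, gp, config = sampler_config()) {
  stopifnot(inherits(data, "data_bundle"), inherits(size_prior, "model_size_prior"),
            inherits(gp, "g_prior"), inherits(config, "sampler_config"))
  if (size_prior$p != data$p) stop("panel size of the prior does not match the data")
  if (size_prior$T >= data$n - data$c_eff - data$q) {
    stop("truncation bound T = ", size_prior$T, " leaves no degrees of freedom: ",
         "need T < n - c_eff - q = ", data$n - data$c_eff - data$q)
  }
  if (!is.null(config$seed)) set.seed(config$seed)
  scan_frac <- config$scan_fraction
  if (is.null(scan_frac)) scan_frac <- if (data$p > 1e4) 0.25 else 1
  lp_size <- vapply(0:size_prior$T, function(k) {
    if (size_prior$mode == "binomial") {
      k * log(size_prior$pi_avg) + (size_prior$p - k) * log1p(-size_prior$pi_avg)
    } else {
      lbeta(k + size_prior$a, size_prior$p - k + size_prior$b) -
        lbeta(size_prior$a, size_prior$b)
    }
  }, numeric(1))

  t0 <- proc.time()[["elapsed"]]
  raw <- ess_run_cpp(
    data$X, data$Y, data$n_eff, gp$rate, lp_size, size_prior$T,
    if (is.na(size_prior$a)) 1 else size_prior$a,
    if (is.na(size_prior$b)) 1 else size_prior$b,
    size_prior$pi_avg, size_prior$mode == "beta-binomial",
    config$n_sweeps, config$burn_in, config$n_chains,
    scan_frac, config$p_crossover, config$ladder_base, config$g_step,
    config$exchange_target[1], config$exchange_target[2], config$g_acc_target,
    config$adapt_window, config$refresh_every, config$record_all_chains
  )
  elapsed <- proc.time()[["elapsed"]] - t0

  n_ret <- length(raw$history_sizes)
  models <- split_models(raw$history_models, raw$history_sizes)
  history <- data.frame(
    sweep = config$burn_in + seq_len(n_ret),
    model_size = raw$history_sizes,
    log_posterior = raw$history_logpost,
    g = raw$history_g
  )
  structure(
    list(models = models, history = history,
         traces = list(model_size = raw$trace_size,
                       log_posterior = raw$trace_logpost,
                       g = raw$trace_g),
         acceptance = raw$counters,
         ladder = as.numeric(raw$ladder),
         ladder_base = raw$ladder_base,
         g_steps = as.numeric(raw$g_steps),
         data = list(n = data$n, p = data$p, q = data$q, c_eff = data$c_eff,
                     snp_ids = data$snp_ids, trait_names = data$trait_names),
         size_prior = size_prior, g_prior = gp, config = config,
         elapsed = elapsed),
    class = "ess_fit"
  )
}

split_models <- function(flat, sizes) {
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1
  lapply(seq_along(sizes), function(i) {
    if (sizes[i] == 0) integer(0) else as.integer(flat[starts[i]:ends[i]])
  })
}

#' @export
print.ess_fit <- function(x, ...) {
  cat(sprintf("ess_fit: %d retained sweeps (of %d, burn-in %d), %d chains, p = %d, q = %d\n",
              nrow(x$history), x$config$n_sweeps, x$config$burn_in,
              x$config$n_chains, x$data$p, x$data$q))
  cat(sprintf("  mean model size %.2f; FSMH acceptance %.3f; exchange acceptance %.3f\n",
              mean(x$history$model_size),
              x$acceptance$fsmh_accepted / max(1, x$acceptance$fsmh_proposed),
              x$acceptance$exchange_accepted / max(1, x$acceptance$exchange_proposed)))
  invisible(x)
}

#' Write the visited-model history to a file
#'
#' Tab-delimited, one row per retained sweep of the non-heated chain:
#' sweep, model size, log-posterior, g, and the space-separated SNP ids of
#' the model.
#'
#' @param fit an [run_ess()] result.
#' @param file output path.
#' @export
write_history <- function(fit, file) {
  ids <- vapply(fit$models, function(m) paste(fit$data$snp_ids[m], collapse = " "),
                character(1))
  out <- cbind(fit$history, model = ids)
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
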