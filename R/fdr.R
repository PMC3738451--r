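#' Row-permuted null trait matrices
#'
#' Creates `K` artificial datasets by permuting the rows (subjects) of the
#' observed traits. All traits are permuted together, preserving the
#' between-trait correlation while breaking any trait-genotype association.
#' Each permutation is checked against the identity.
#'
#' @param Y a [trait_matrix()] or matrix with at least two rows.
#' @param K number of permutations (default 3).
#' @param seed optional seed.
#' @return list of `K` matrices, each a row permutation of `Y`; the
#'   permutations are stored in attribute `"perm"`.
#' @export
permute_traits <- function(Y, K = 3, seed = NULL) {
  Ym <- as_values(Y)
  n <- nrow(Ym)
  stopifnot(n >= 2, K >= 1)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", K)
  for (k in seq_len(K)) {
    repeat {
      perm <- sample.int(n)
      if (!identical(perm, seq_len(n))) break
    }
    Yk <- Ym[perm, , drop = FALSE]
    attr(Yk, "perm") <- perm
    out[[k]] <- Yk
  }
  out
}

#' Empirical-FDR threshold on MPPI
#'
#' Finds the smallest observed MPPI value `m*` at which the ratio between the
#' per-dataset expected number of declared associations in the permuted
#' (null) datasets and the number declared in the observed dataset does not
#' exceed the FDR level:
#' \deqn{\frac{\#\{\mathrm{null\ MPPI} \ge m^*\}/K}{\#\{\mathrm{obs\ MPPI} \ge m^*\}} \le \alpha.}
#' The pooled null count is divided by the number of permuted datasets `K` so
#' the numerator estimates the null exceedances of one dataset; otherwise the
#' estimate would scale with `K`. Candidate thresholds are the observed MPPI
#' values themselves (the criterion is a step function), which yields the
#' least conservative valid threshold. If no observed value qualifies, `Inf`
#' is returned and nothing is declared.
#'
#' @param observed observed MPPI vector.
#' @param null_pool pooled null MPPI values (from `K` permuted runs, possibly
#'   combined across trait groups of equal cardinality).
#' @param alpha FDR level (default 0.05).
#' @param K number of permuted datasets each contributing group supplied.
#' @return the threshold `m*` (scalar, possibly `Inf`), with the estimated
#'   FDR at `m*` as attribute `"fdr"`.
#' @export
mppi_threshold <- function(observed, null_pool, alpha = 0.05, K = 3) {
  stopifnot(length(null_pool) >= 1, alpha > 0, alpha < 1, K >= 1)
  cand <- sort(unique(observed[observed > 0]))
  for (m in cand) {
    n_obs <- sum(observed >= m)
    n_null <- sum(null_pool >= m) / K
    if (n_null / n_obs <= alpha) {
      return(structure(m, fdr = n_null / n_obs))
    }
  }
  structure(Inf, fdr = NA_real_)
}

#' Declare significant SNPs at a calibrated threshold
#'
#' @param observed observed MPPI vector (named by SNP).
#' @param m_star threshold from [mppi_threshold()] for the same group (or a
#'   pooled calibration of groups with the same cardinality).
#' @return logical vector: `MPPI >= m_star`.
#' @export
declare_significant <- function(observed, m_star) {
  observed >= m_star
}

#' Permutation-based empirical FDR calibration of one trait group
#'
#' Runs the sampler on the observed traits and on `K` row-permuted copies
#' with identical prior and sampler settings, then calibrates the MPPI
#' significance threshold at the requested FDR level.
#'
#' @param Y traits ([trait_matrix()] or matrix).
#' @param G genotypes ([genotype_matrix()] or matrix).
#' @param C covariates or `NULL`.
#' @param size_prior a [model_size_prior()].
#' @param gp a [g_prior()].
#' @param config a [sampler_config()]; its seed drives both the observed run
#'   and the permutations.
#' @param K number of permutations (default 3).
#' @param alpha FDR level (default 0.05).
#' @param transform_traits apply the inverse-normal transform per trait.
#' @return list of class `fdr_calibration`: `fit` (observed run),
#'   `observed_mppi`, `null_mppi` (length-K list), `null_pool`, `m_star`,
#'   `significant` (logical vector), `n_significant`, `alpha`, `K`,
#'   `cardinality`.
#' @export
empirical_fdr <- function(Y, G, C = NULL, size_prior, gp, config,
                          K = 3, alpha = 0.05, transform_traits = FALSE) {
  bundle <- data_bundle(Y, G, C, transform_traits = transform_traits)
  fit <- run_ess(bundle, size_prior, gp, config)
  observed <- compute_mppi(fit)
  perms <- permute_traits(as_values(Y),
                          K = K,
                          seed = if (is.null(config$seed)) NULL else config$seed + 1L)
  null_mppi <- vector("list", K)
  for (k in seq_len(K)) {
    cfgk <- config
    cfgk$seed <- if (is.null(config$seed)) NULL else config$seed + 1L + k
    bk <- data_bundle(perms[[k]], G, C, transform_traits = transform_traits)
    null_mppi[[k]] <- compute_mppi(run_ess(bk, size_prior, gp, cfgk))
  }
  null_pool <- unlist(null_mppi, use.names = FALSE)
  m_star <- mppi_threshold(observed, null_pool, alpha = alpha, K = K)
  sig <- declare_significant(observed, m_star)
  structure(list(fit = fit, observed_mppi = observed, null_mppi = null_mppi,
                 null_pool = null_pool, m_star = m_star, significant = sig,
                 n_significant = sum(sig), alpha = alpha, K = K,
                 cardinality = ncol(as_values(Y))),
            class = "fdr_calibration")
}

#' @export
print.fdr_calibration <- function(x, ...) {
  cat(sprintf("empirical FDR calibration: alpha = %g, K = %d permutations, pool size %d\n",
              x$alpha, x$K, length(x$null_pool)))
  cat(sprintf("  MPPI threshold m* = %s; %d SNP(s) declared significant\n",
              format(x$m_star), x$n_significant))
  invisible(x)
}

#' Pool permutation nulls across trait groups of equal cardinality
#'
#' The tail of the null MPPI distribution needs a large sample to be
#' estimated well, so when several trait groups of the same dimension
#' (singletons, pairs, triplets, ...) are analyzed, their permuted-run MPPI
#' values are combined into a single null pool per cardinality.
#'
#' @param calibrations list of [empirical_fdr()] results (or lists with
#'   elements `null_mppi` and `cardinality`).
#' @param alpha FDR level used to recompute thresholds on the pooled nulls.
#' @return data.frame with one row per calibration: `group`, `cardinality`,
#'   `null_pool_size`, `mppi_threshold`, `n_significant`; the recalibrated
#'   significance vectors are attached as attribute `"significant"`.
#' @export
pool_null_calibrations <- function(calibrations, alpha = 0.05) {
  stopifnot(length(calibrations) >= 1)
  if (is.null(names(calibrations)))
    names(calibrations) <- paste0("group", seq_along(calibrations))
  card <- vapply(calibrations, function(x) x$cardinality, numeric(1))
  pools <- lapply(unique(card), function(d) {
    unlist(lapply(calibrations[card == d], function(x) x$null_mppi),
           use.names = FALSE)
  })
  names(pools) <- as.character(unique(card))
  n_runs <- vapply(unique(card), function(d)
    sum(vapply(calibrations[card == d], function(x) length(x$null_mppi), numeric(1))),
    numeric(1))
  names(n_runs) <- as.character(unique(card))
  sig_list <- list()
  rows <- lapply(names(calibrations), function(gname) {
    x <- calibrations[[gname]]
    d <- as.character(x$cardinality)
    m_star <- mppi_threshold(x$observed_mppi, pools[[d]], alpha = alpha,
                             K = n_runs[[d]])
    sig <- declare_significant(x$observed_mppi, m_star)
    sig_list[[gname]] <<- sig
    data.frame(group = gname, cardinality = x$cardinality,
               null_pool_size = length(pools[[d]]),
               mppi_threshold = as.numeric(m_star),
               n_significant = sum(sig), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "significant") <- sig_list
  out
}
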