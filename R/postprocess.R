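#' Best models visited
#'
#' Deduplicates the models visited by the non-heated chain and attaches to
#' each unique model its posterior mass renormalized over the set of unique
#' visited models (MPP). A model visited at several values of g is scored by
#' the maximum recorded log-posterior, since the posterior mass is attached to
#' the model, not to a (model, g) pair. Ranking is by MPP descending, ties
#' broken by lexicographic model indices.
#'
#' @param fit an [run_ess()] result.
#' @param max_models optionally keep only the top models (after computing the
#'   normalization over all of them).
#' @return data.frame of class `best_models` with columns `rank`, `model`
#'   (list of integer vectors), `snp_ids`, `model_size`, `log_posterior`,
#'   `mpp`, `cum_mpp`, `n_visits`, `first_visit_sweep`.
#' @export
best_models <- function(fit, max_models = Inf) {
  stopifnot(inherits(fit, "ess_fit"))
  if (length(fit$models) == 0) stop("empty post-burn-in history")
  keys <- vapply(fit$models, paste, character(1), collapse = ",")
  grp <- split(seq_along(keys), keys)
  lp <- vapply(grp, function(i) max(fit$history$log_posterior[i]), numeric(1))
  visits <- lengths(grp)
  first <- vapply(grp, function(i) fit$history$sweep[min(i)], numeric(1))
  models <- lapply(grp, function(i) fit$models[[i[1]]])
  mpp <- exp(lp - logsumexp(lp))
  # order by MPP descending, ties lexicographic on the index vectors
  keypad <- vapply(models, function(m) paste(sprintf("%09d", m), collapse = ","),
                   character(1))
  ord <- order(-mpp, keypad)
  out <- data.frame(rank = seq_along(ord), model_size = lengths(models)[ord],
                    log_posterior = lp[ord], mpp = mpp[ord],
                    cum_mpp = cumsum(mpp[ord]),
                    n_visits = as.integer(visits[ord]),
                    first_visit_sweep = first[ord], row.names = NULL)
  out$model <- models[ord]
  out$snp_ids <- vapply(out$model, function(m)
    paste(fit$data$snp_ids[m], collapse = " "), character(1))
  if (is.finite(max_models)) out <- out[seq_len(min(nrow(out), max_models)), ]
  class(out) <- c("best_models", "data.frame")
  out
}

logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Marginal posterior probability of inclusion
#'
#' MPPI of SNP j is the fraction of retained non-heated-chain sweeps whose
#' model contains j: a model-averaged measure of the strength of association
#' between one SNP and the trait group.
#'
#' @param fit an [run_ess()] result.
#' @return named numeric vector of length p.
#' @export
compute_mppi <- function(fit) {
  stopifnot(inherits(fit, "ess_fit"))
  if (length(fit$models) == 0) stop("empty post-burn-in history")
  counts <- tabulate(unlist(fit$models), nbins = fit$data$p)
  stats::setNames(counts / length(fit$models), fit$data$snp_ids)
}

#' Bayes factor from an inclusion probability
#'
#' Converts MPPI to a Bayes factor as posterior odds over prior odds:
#' `BF = [m/(1-m)] / [pi/(1-pi)]`, with `m` clipped to `[eps, 1-eps]` so the
#' frequency estimator's resolution limit yields finite values when
#' `m` is exactly 0 or 1.
#'
#' @param mppi inclusion probabilities in `[0, 1]` (vectorized).
#' @param pi_avg average prior inclusion probability (`E/p` of the size
#'   prior).
#' @param eps clipping constant; the natural choice is
#'   `1/(10 * retained sweeps)`.
#' @return list with `bf` and `log10_bf` (unclipped scale; figures
#'   conventionally truncate the display at 20).
#' @export
bayes_factor_from_mppi <- function(mppi, pi_avg, eps = 1e-6) {
  stopifnot(all(mppi >= 0 & mppi <= 1), pi_avg > 0, pi_avg < 1, eps > 0, eps < 0.5)
  m <- pmin(pmax(mppi, eps), 1 - eps)
  bf <- (m / (1 - m)) / (pi_avg / (1 - pi_avg))
  list(bf = bf, log10_bf = log10(bf))
}

#' Bayes-factor significance threshold for a trait group
#'
#' Applies the same odds-ratio transform to the group's MPPI significance
#' threshold, giving the threshold on the Bayes-factor scale at the chosen
#' FDR level.
#'
#' @param mppi_threshold the group's MPPI threshold from the empirical FDR
#'   calibration, in `(0, 1)`.
#' @param pi_avg average prior inclusion probability.
#' @return scalar Bayes-factor threshold.
#' @export
bf_threshold <- function(mppi_threshold, pi_avg) {
  stopifnot(mppi_threshold > 0, mppi_threshold < 1)
  (mppi_threshold / (1 - mppi_threshold)) / (pi_avg / (1 - pi_avg))
}

#' Ratio of Bayes factors
#'
#' Rescales a SNP's Bayes factor by the group's Bayes-factor threshold at the
#' FDR baseline level. Within a group the RBF preserves the BF ranking; across
#' trait groups it is comparable because each group is standardized by its own
#' baseline, so for a given SNP the groups can be ranked by the strength of
#' association.
#'
#' @param bf Bayes factor(s).
#' @param bf_thr the group's Bayes-factor threshold (positive).
#' @return `bf / bf_thr`; at least 1 for any SNP declared significant.
#' @export
rbf <- function(bf, bf_thr) {
  stopifnot(bf_thr > 0)
  bf / bf_thr
}

#' Per-SNP marginal summary table
#'
#' Assembles MPPI, Bayes factors, RBF and significance flags for one trait
#' group into the package's standard output table.
#'
#' @param fit an [run_ess()] result.
#' @param mppi_threshold the group's MPPI significance threshold
#'   ([mppi_threshold()]); `Inf` (nothing declared) and `NULL` (no
#'   calibration; RBF and flags omitted) are allowed.
#' @param map optional SNP map (data.frame `snp_id`, `chromosome`,
#'   `position`).
#' @return data.frame of class `marginal_summary` with columns `snp_id`
#'   (+ `chromosome`, `position` when mapped), `mppi`, `bf`, `log10_bf`,
#'   `log10_rbf`, `significant`, `in_top_bmv`; the thresholds are attached as
#'   attributes `mppi_threshold` and `bf_threshold`, the trait group's
#'   cardinality as `cardinality`.
#' @export
marginal_summary <- function(fit, mppi_threshold = NULL, map = NULL) {
  mppi <- compute_mppi(fit)
  eps <- 1 / (10 * length(fit$models))
  bfres <- bayes_factor_from_mppi(mppi, fit$size_prior$pi_avg, eps)
  out <- data.frame(snp_id = names(mppi), mppi = as.numeric(mppi),
                    bf = bfres$bf, log10_bf = bfres$log10_bf,
                    stringsAsFactors = FALSE)
  if (!is.null(map)) {
    m <- map[match(out$snp_id, map$snp_id), ]
    out$chromosome <- m$chromosome
    out$position <- m$position
  }
  bthr <- NA_real_
  if (!is.null(mppi_threshold)) {
    if (is.finite(mppi_threshold)) {
      bthr <- bf_threshold(min(max(mppi_threshold, eps), 1 - eps),
                           fit$size_prior$pi_avg)
      out$log10_rbf <- log10(rbf(out$bf, bthr))
      out$significant <- out$mppi >= mppi_threshold
    } else {
      out$log10_rbf <- -Inf
      out$significant <- FALSE
    }
  }
  bm <- best_models(fit, max_models = 1)
  out$in_top_bmv <- seq_len(nrow(out)) %in% bm$model[[1]]
  attr(out, "mppi_threshold") <- if (is.null(mppi_threshold)) NA_real_ else mppi_threshold
  attr(out, "bf_threshold") <- bthr
  attr(out, "cardinality") <- fit$data$q
  attr(out, "trait_group") <- paste(fit$data$trait_names, collapse = "-")
  class(out) <- c("marginal_summary", "data.frame")
  out
}

#' Rank trait groups by RBF for one SNP
#'
#' Orders the analyzed trait groups by their RBF for a given SNP, providing a
#' formal ranking of the strength of association of the SNP across groups of
#' phenotypes. Ties are broken by group cardinality (larger first), then by
#' group name.
#'
#' @param snp_id the SNP identifier.
#' @param summaries named list of [marginal_summary()] tables, one per trait
#'   group (names are the group labels).
#' @return data.frame with `group`, `cardinality`, `log10_rbf`, ordered by
#'   decreasing RBF; groups whose panel lacks the SNP are omitted with a
#'   warning.
#' @export
rank_groups_by_rbf <- function(snp_id, summaries) {
  stopifnot(length(summaries) >= 1)
  if (is.null(names(summaries)))
    names(summaries) <- paste0("group", seq_along(summaries))
  rows <- lapply(names(summaries), function(gname) {
    s <- summaries[[gname]]
    i <- match(snp_id, s$snp_id)
    if (is.na(i)) {
      warning("SNP ", snp_id, " absent from panel of group ", gname, "; omitted")
      return(NULL)
    }
    if (is.null(s$log10_rbf)) stop("group ", gname, " has no RBF (no FDR threshold supplied)")
    data.frame(group = gname, cardinality = attr(s, "cardinality"),
               log10_rbf = s$log10_rbf[i], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out) || nrow(out) == 0) stop("SNP ", snp_id, " absent from every group")
  out <- out[order(-out$log10_rbf, -out$cardinality, out$group), ]
  rownames(out) <- NULL
  out
}

#' Sampler diagnostics
#'
#' Trace tables for the standard convergence checks: log-posterior, model
#' size and g over all chains, the shrinkage factor g/(1+g), and the sweep at
#' which each of the top best models was first visited.
#'
#' @param fit an [run_ess()] result.
#' @param n_top number of top models to annotate with their first-visit
#'   sweep.
#' @return list of class `ess_diagnostics`: data.frames `log_posterior`,
#'   `model_size`, `g` (long format: `sweep`, `chain`, `value`),
#'   `shrinkage` (non-heated chain, `g/(1+g)`), `first_visits`, and
#'   `burn_in`.
#' @export
diagnostics <- function(fit, n_top = 5) {
  stopifnot(inherits(fit, "ess_fit"))
  if (nrow(fit$history) == 0) stop("empty history")
  longify <- function(m, what) {
    L <- ncol(m)
    data.frame(sweep = rep(seq_len(nrow(m)), L),
               chain = rep(seq_len(L), each = nrow(m)),
               value = as.numeric(m))
  }
  g1 <- fit$traces$g[, 1]
  bm <- best_models(fit, max_models = n_top)
  structure(
    list(log_posterior = longify(fit$traces$log_posterior),
         model_size = longify(fit$traces$model_size),
         g = longify(fit$traces$g),
         shrinkage = data.frame(sweep = seq_along(g1), g = g1,
                                shrinkage = g1 / (1 + g1)),
         first_visits = data.frame(rank = bm$rank, snp_ids = bm$snp_ids,
                                   first_visit_sweep = bm$first_visit_sweep),
         burn_in = fit$config$burn_in),
    class = "ess_diagnostics"
  )
}

#' Plot sampler diagnostics
#'
#' Four-panel trace plot: log-posterior, model size, g and the shrinkage
#' factor g/(1+g). The burn-in boundary is marked with a dashed line.
#'
#' @param x an `ess_diagnostics` object.
#' @param ... unused.
#' @export
plot.ess_diagnostics <- function(x, ...) {
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  panels <- list(`log-posterior` = x$log_posterior, `model size` = x$model_size,
                 g = x$g)
  for (nm in names(panels)) {
    d <- panels[[nm]]
    chains <- unique(d$chain)
    graphics::plot(NULL, xlim = range(d$sweep), ylim = range(d$value[is.finite(d$value)]),
                   xlab = "sweep", ylab = nm, main = nm)
    for (l in chains) {
      di <- d[d$chain == l, ]
      graphics::lines(di$sweep, di$value, col = l)
    }
    graphics::abline(v = x$burn_in, lty = 2)
  }
  graphics::plot(x$shrinkage$sweep, x$shrinkage$shrinkage, type = "l",
                 xlab = "sweep", ylab = "g/(1+g)", main = "shrinkage factor",
                 ylim = c(0, 1))
  graphics::abline(v = x$burn_in, lty = 2)
  invisible(x)
}

#' Write the per-SNP marginal summary table
#' @param summary a [marginal_summary()] table.
#' @param file output path (tab-delimited).
#' @export
write_marginal_summary <- function(summary, file) {
  utils::write.table(summary, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Write the best-models table
#' @param bm a [best_models()] table.
#' @param file output path (tab-delimited).
#' @export
write_best_models <- function(bm, file) {
  out <- bm[, setdiff(names(bm), "model")]
  utils::write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
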