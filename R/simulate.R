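#' Simulate an additive genotype panel
#'
#' Genotypes are drawn in Hardy-Weinberg equilibrium by summing two
#' haplotypes. Linkage disequilibrium is generated within blocks by a
#' copy-with-mutation chain along each haplotype: the allele at a SNP copies
#' the allele at the previous SNP with probability `rho` and is otherwise
#' drawn fresh from the block's allele frequency. With a common frequency
#' within a block this yields genotype correlations that decay geometrically
#' with distance, `cor(x_j, x_{j+d}) = rho^d`, so `rho` is directly the
#' adjacent-SNP correlation. Blocks are mutually independent ("chromosomes").
#' A synthetic map is attached (one chromosome label per block, 5 kb spacing).
#'
#' @param n individuals.
#' @param p SNPs.
#' @param maf_range minor-allele-frequency range; each block (or each
#'   independent SNP) draws its frequency uniformly from it.
#' @param blocks integer vector of block sizes summing to `p`, or `NULL` for
#'   independent SNPs.
#' @param rho adjacent-SNP correlation within a block (0 = independent).
#' @param seed optional seed.
#' @param spacing_bp base pairs between adjacent SNPs on the synthetic map.
#' @return a [genotype_matrix()] with map.
#' @export
simulate_genotypes <- function(n, p, maf_range = c(0.01, 0.5), blocks = NULL,
                               rho = 0, seed = NULL, spacing_bp = 5000) {
  stopifnot(n >= 1, p >= 1, length(maf_range) == 2,
            maf_range[1] > 0, maf_range[2] <= 0.5, rho >= 0, rho < 1)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(blocks)) blocks <- rep(1L, p)
  if (sum(blocks) != p) stop("'blocks' must sum to p")
  X <- matrix(0, n, p)
  chrom <- integer(p)
  pos <- integer(p)
  col <- 1L
  for (b in seq_along(blocks)) {
    sz <- blocks[b]
    f <- stats::runif(1, maf_range[1], maf_range[2])
    h1 <- matrix(0L, n, sz)
    h2 <- matrix(0L, n, sz)
    h1[, 1] <- stats::rbinom(n, 1, f)
    h2[, 1] <- stats::rbinom(n, 1, f)
    if (sz > 1) {
      for (j in 2:sz) {
        copy1 <- stats::runif(n) < rho
        copy2 <- stats::runif(n) < rho
        h1[, j] <- ifelse(copy1, h1[, j - 1], stats::rbinom(n, 1, f))
        h2[, j] <- ifelse(copy2, h2[, j - 1], stats::rbinom(n, 1, f))
      }
    }
    idx <- col:(col + sz - 1L)
    X[, idx] <- h1 + h2
    chrom[idx] <- b
    pos[idx] <- seq(1L, by = as.integer(spacing_bp), length.out = sz)
    col <- col + sz
  }
  ids <- paste0("snp", seq_len(p))
  genotype_matrix(X, snp_ids = ids,
                  map = data.frame(snp_id = ids, chromosome = as.character(chrom),
                                   position = pos))
}

#' Calibrate per-trait error variances to a variance-explained cap
#'
#' For each trait t with genetic effect vector b_t over the causal SNPs, the
#' error variance is set to
#' `sigma_t^2 = Var(X_causal b_t) * (1 - max_r2) / max_r2`
#' (empirical variance over individuals), so the expected proportion of
#' phenotypic variance explained by the causal SNPs equals `max_r2` exactly.
#' Traits with a zero effect vector get unit error variance.
#'
#' @param G a [genotype_matrix()] or matrix.
#' @param causal integer indices of the causal SNPs.
#' @param B effect matrix (length(causal) x q).
#' @param max_r2 variance-explained cap (default 0.05).
#' @return numeric vector of per-trait error standard deviations.
#' @export
calibrate_error_variance <- function(G, causal, B, max_r2 = 0.05) {
  stopifnot(max_r2 > 0, max_r2 < 1)
  X <- as_values(G)[, causal, drop = FALSE]
  B <- as.matrix(B)
  if (nrow(B) != length(causal)) stop("'B' rows must match the causal set")
  vapply(seq_len(ncol(B)), function(t) {
    b <- B[, t]
    if (all(b == 0)) return(1)
    v <- stats::var(as.numeric(X %*% b))
    if (v <= 0) stop("zero genetic variance with a nonzero effect vector")
    sqrt(v * (1 - max_r2) / max_r2)
  }, numeric(1))
}

#' Simulate traits from a matrix-variate normal model
#'
#' `Y = X_causal B + E`, with the rows of `E` independent multivariate normal
#' with covariance `D R D` (`D = diag(sigma)`), inducing the requested
#' residual correlation `R` between traits.
#'
#' @param G genotypes.
#' @param causal causal SNP indices.
#' @param B effect matrix (length(causal) x q).
#' @param R q x q residual correlation matrix (symmetric positive-definite,
#'   unit diagonal).
#' @param sigma per-trait residual standard deviations.
#' @param seed optional seed.
#' @return a [trait_matrix()].
#' @export
simulate_traits <- function(G, causal, B, R, sigma, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  X <- as_values(G)[, causal, drop = FALSE]
  B <- as.matrix(B)
  R <- as.matrix(R)
  q <- ncol(B)
  stopifnot(nrow(R) == q, ncol(R) == q, length(sigma) == q)
  if (max(abs(R - t(R))) > 1e-12 || max(abs(diag(R) - 1)) > 1e-12)
    stop("'R' must be symmetric with unit diagonal")
  ch <- tryCatch(chol(R), error = function(e)
    stop("'R' must be positive-definite"))
  n <- nrow(X)
  E <- matrix(stats::rnorm(n * q), n, q) %*% ch %*% diag(sigma, q)
  trait_matrix(X %*% B + E, trait_names = paste0("trait", seq_len(q)))
}

#' Simulation scenario presets
#'
#' The four power-study designs. All use eight causal SNPs placed on four
#' independent LD blocks ("chromosomes"), an expected variance-explained cap
#' of 5% per trait, n = 3,175 individuals and 20 replicates.
#' \describe{
#'   \item{MT1}{three traits; fixed effect vectors
#'     (0.2, 0.1, 0.2, 0.1, 0.075, 0.1, 0.075, 0.1),
#'     (0.1, 0.075, 0.1, 0.075, 0.1, 0.2, 0.1, 0.2) and
#'     (0.075, 0.1, 0.075, 0.1, 0.2, 0.1, 0.2, 0.1) over the causal SNPs;
#'     residual correlations 0.95 (traits 1-2), 0.50 (2-3), 0.30 (1-3);
#'     two causal SNPs per block, placed at random.}
#'   \item{MT2}{as MT1 with the residual correlations halved
#'     (0.475, 0.25, 0.15) — the weak-correlation stress case.}
#'   \item{ST1}{single trait: the first trait of MT1.}
#'   \item{ST2}{single trait with four primary/secondary pairs of effects
#'     (4, 1), (1, 6), (1.5, 3), (4, 0.5); the secondary SNP sits in the same
#'     LD block within 25 kb of the primary.}
#' }
#'
#' @return named list of `sim_scenario` objects with fields `name`, `n`, `q`,
#'   `B` (8 x q), `R`, `max_r2`, `n_replicates`, `maf_range`, `n_blocks`,
#'   `rho`, `placement` (`"random_pairs"` or `"nearby_pairs"`).
#' @export
scenario_presets <- function() {
  b1 <- c(0.2, 0.1, 0.2, 0.1, 0.075, 0.1, 0.075, 0.1)
  b2 <- c(0.1, 0.075, 0.1, 0.075, 0.1, 0.2, 0.1, 0.2)
  b3 <- c(0.075, 0.1, 0.075, 0.1, 0.2, 0.1, 0.2, 0.1)
  Rmt <- function(r12, r23, r13) {
    R <- diag(3)
    R[1, 2] <- R[2, 1] <- r12
    R[2, 3] <- R[3, 2] <- r23
    R[1, 3] <- R[3, 1] <- r13
    R
  }
  base <- list(n = 3175, max_r2 = 0.05, n_replicates = 20,
               maf_range = c(0.05, 0.5), n_blocks = 4, rho = 0.6)
  mk <- function(name, q, B, R, placement) {
    structure(c(list(name = name, q = q, B = B, R = R, placement = placement),
                base),
              class = "sim_scenario")
  }
  list(
    MT1 = mk("MT1", 3, cbind(b1, b2, b3), Rmt(0.95, 0.50, 0.30), "random_pairs"),
    MT2 = mk("MT2", 3, cbind(b1, b2, b3), Rmt(0.475, 0.25, 0.15), "random_pairs"),
    ST1 = mk("ST1", 1, cbind(b1), matrix(1, 1, 1), "random_pairs"),
    ST2 = mk("ST2", 1, cbind(c(4, 1, 1, 6, 1.5, 3, 4, 0.5)), matrix(1, 1, 1),
             "nearby_pairs")
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("scenario %s: q = %d trait(s), 8 causal SNPs on %d blocks, n = %d, cap %.0f%%\n",
              x$name, x$q, x$n_blocks, x$n, 100 * x$max_r2))
  invisible(x)
}

#' Simulate one replicate of a scenario
#'
#' Draws a genotype panel of `p` SNPs split over the scenario's independent
#' LD blocks, places the eight causal SNPs (two per block: at random for the
#' multi-trait designs, a primary/secondary pair within 25 kb for ST2),
#' calibrates the per-trait error variances to the variance-explained cap and
#' simulates the traits from the matrix-variate model.
#'
#' @param scenario a scenario from [scenario_presets()].
#' @param p panel size (default 500; the causal SNPs are among them).
#' @param n individuals (default: the scenario's n).
#' @param seed seed for the replicate.
#' @return list of class `sim_replicate`: `G` ([genotype_matrix()]), `Y`
#'   ([trait_matrix()]), `truth` (data.frame `snp_id`, `index`, `block` and
#'   per-trait effects), `causal` (indices), `B`, `sigma`, `scenario`.
#' @export
simulate_replicate <- function(scenario, p = 500, n = scenario$n, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"), p >= 16)
  if (!is.null(seed)) set.seed(seed)
  nb <- scenario$n_blocks
  sizes <- rep(p %/% nb, nb)
  sizes[seq_len(p %% nb)] <- sizes[seq_len(p %% nb)] + 1L
  G <- simulate_genotypes(n, p, maf_range = scenario$maf_range,
                          blocks = sizes, rho = scenario$rho)
  offsets <- cumsum(c(0L, sizes[-nb]))
  causal <- integer(0)
  for (b in seq_len(nb)) {
    within <- if (scenario$placement == "nearby_pairs") {
      # primary at random, secondary within 25 kb (5 SNPs at 5 kb spacing)
      prim <- sample.int(sizes[b], 1)
      lo <- max(1, prim - 5); hi <- min(sizes[b], prim + 5)
      nb_cand <- setdiff(lo:hi, prim)
      c(prim, nb_cand[sample.int(length(nb_cand), 1)])
    } else {
      sample.int(sizes[b], 2)
    }
    causal <- c(causal, offsets[b] + within)
  }
  causal <- sort(causal)
  sigma <- calibrate_error_variance(G, causal, scenario$B, scenario$max_r2)
  Y <- simulate_traits(G, causal, scenario$B, scenario$R, sigma)
  truth <- data.frame(snp_id = G$snp_ids[causal], index = causal,
                      block = G$map$chromosome[causal])
  truth <- cbind(truth, as.data.frame(scenario$B))
  names(truth)[-(1:3)] <- paste0("effect_trait", seq_len(scenario$q))
  structure(list(G = G, Y = Y, truth = truth, causal = causal,
                 B = scenario$B, sigma = sigma, scenario = scenario$name),
            class = "sim_replicate")
}

#' ROC evaluation of per-SNP association scores
#'
#' Sweeps thresholds over a score vector (MPPI, log10 BF, |loading|, ...) and
#' reports detection power against the count and proportion of false
#' positives. With `window_bp > 0` the definition of a positive association is
#' relaxed: any declared SNP within the window of a true SNP counts as
#' detecting it (one true positive per true SNP), and false-positive SNPs
#' falling within one window of each other are collapsed into a single
#' interval.
#'
#' @param score numeric vector, one score per SNP (larger = stronger).
#' @param truth indices (or logical vector) of the truly associated SNPs.
#' @param positions optional base-pair positions (required for
#'   `window_bp > 0`); SNPs on different chromosomes are never merged when
#'   `chromosome` is supplied.
#' @param chromosome optional chromosome labels.
#' @param window_bp half-width of the matching window in base pairs
#'   (0 = exact matching; 25, 50 or 100 kb are the conventional relaxations).
#' @param fp_cap truncate the curve at this proportion of false positives
#'   (`NULL` for no truncation; genome-scale comparisons conventionally stop
#'   at 1e-4).
#' @return data.frame with `threshold`, `n_declared`, `tp`, `power`, `fp`,
#'   `fp_prop`, one row per distinct score threshold.
#' @export
evaluate_roc <- function(score, truth, positions = NULL, chromosome = NULL,
                         window_bp = 0, fp_cap = NULL) {
  p <- length(score)
  if (is.logical(truth)) truth <- which(truth)
  stopifnot(length(truth) >= 1, all(truth >= 1), all(truth <= p))
  if (window_bp > 0 && is.null(positions))
    stop("'positions' are required for windowed matching")
  if (is.null(chromosome)) chromosome <- rep(1L, p)
  thresholds <- sort(unique(score), decreasing = TRUE)
  rows <- lapply(thresholds, function(thr) {
    declared <- which(score >= thr)
    if (window_bp == 0) {
      tp <- sum(declared %in% truth)
      fp <- length(declared) - tp
    } else {
      near_truth <- vapply(declared, function(j) {
        any(chromosome[truth] == chromosome[j] &
              abs(positions[truth] - positions[j]) <= window_bp)
      }, logical(1))
      tp <- sum(vapply(truth, function(tt) {
        any(chromosome[declared] == chromosome[tt] &
              abs(positions[declared] - positions[tt]) <= window_bp)
      }, logical(1)))
      fpos <- declared[!near_truth]
      fp <- 0L
      for (ch in unique(chromosome[fpos])) {
        ps <- sort(positions[fpos[chromosome[fpos] == ch]])
        if (length(ps)) fp <- fp + 1L + sum(diff(ps) > window_bp)
      }
    }
    data.frame(threshold = thr, n_declared = length(declared),
               tp = tp, power = tp / length(truth),
               fp = fp, fp_prop = fp / p)
  })
  out <- do.call(rbind, rows)
  if (!is.null(fp_cap)) out <- out[out$fp_prop <= fp_cap, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a simulated replicate to disk
#'
#' Genotypes and traits in the package's delimited dialects plus a truth file
#' (snp_id and per-trait effects).
#'
#' @param rep a [simulate_replicate()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_replicate <- function(rep, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(rep$G, file.path(dir, "genotypes.tsv"))
  utils::write.table(rep$G$map, file.path(dir, "genotypes.map"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(as_values(rep$Y), file.path(dir, "traits.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(rep$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
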