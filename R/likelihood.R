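#' Bundle projected data for the sampler
#'
#' Applies mean imputation, covariate projection (intercept always included)
#' and column centering, and precomputes the cross-products used by the
#' marginal likelihood. The residual covariance of the traits carries a
#' Jeffreys-style prior, so the coefficient matrix and the residual covariance
#' are both integrated out analytically and the sampler only ever needs the
#' quantities stored here.
#'
#' @param Y a [trait_matrix()] or n x q matrix of phenotypes.
#' @param G a [genotype_matrix()] or n x p matrix of additive genotypes.
#' @param C a [covariate_matrix()], matrix, or `NULL`.
#' @param transform_traits if `TRUE`, apply [inverse_normal_transform()] to
#'   each trait before projection.
#' @return object of class `data_bundle` with `Y` (n x q projected traits),
#'   `X` (n x p projected genotypes), `n`, `p`, `q`, `c_eff`, `n_eff = n - c_eff`,
#'   `snp_ids`, `trait_names`.
#' @export
data_bundle <- function(Y, G, C = NULL, transform_traits = FALSE) {
  Ym <- as_values(Y)
  if (transform_traits) Ym <- apply(Ym, 2, inverse_normal_transform)
  adj <- adjust_for_covariates(Ym, G, C)
  q <- ncol(adj$Y)
  n <- nrow(adj$Y)
  if (n - adj$c_eff <= q) stop("too few individuals for the number of traits")
  structure(
    list(Y = adj$Y, X = adj$X, n = n, p = ncol(adj$X), q = q,
         c_eff = adj$c_eff, n_eff = n - adj$c_eff,
         snp_ids = if (is.null(adj$snp_ids)) paste0("snp", seq_len(ncol(adj$X))) else adj$snp_ids,
         trait_names = if (is.null(colnames(adj$Y))) paste0("trait", seq_len(q)) else colnames(adj$Y)),
    class = "data_bundle"
  )
}

#' @export
print.data_bundle <- function(x, ...) {
  cat(sprintf("data_bundle: n = %d, p = %d SNPs, q = %d trait(s), c_eff = %d\n",
              x$n, x$p, x$q, x$c_eff))
  invisible(x)
}

#' Log marginal likelihood of a model
#'
#' Conjugate multi-response g-prior marginal likelihood with the coefficient
#' matrix and the residual covariance integrated out:
#' \deqn{\log p(Y \mid \gamma, g) = -\frac{kq}{2}\log(1+g)
#'   - \frac{n - c_{\mathrm{eff}}}{2}\log\det S(\gamma, g) + \mathrm{const},}
#' where \eqn{k} is the rank of the selected genotype columns,
#' \eqn{S(\gamma,g) = Y^\top Y - \frac{g}{1+g} Y^\top H_\gamma Y} and
#' \eqn{H_\gamma} is the orthogonal projector onto the span of the selected
#' columns. The projector is obtained from a column-pivoted QR factorization,
#' which also determines \eqn{k}, so duplicated or collinear columns are
#' handled safely. The additive constant is fixed per dataset (taken as zero
#' here), so differences between models are exact.
#'
#' @param data a [data_bundle()].
#' @param gamma integer vector of included SNP column indices (possibly empty).
#' @param g positive selection coefficient.
#' @return scalar log marginal likelihood (up to the per-dataset constant).
#' @export
log_marginal_likelihood <- function(data, gamma, g) {
  stopifnot(inherits(data, "data_bundle"), g > 0)
  gamma <- validate_model(gamma, data$p)
  k_sel <- length(gamma)
  if (k_sel >= data$n - data$c_eff) stop("model too large for the available degrees of freedom")
  YtY <- crossprod(data$Y)
  if (k_sel == 0) {
    return(-(data$n_eff / 2) * logdet_pd(YtY, data$q))
  }
  Xg <- data$X[, gamma, drop = FALSE]
  qrx <- qr(Xg, LAPACK = TRUE)
  rdiag <- abs(diag(qr.R(qrx)))
  tol <- max(dim(Xg)) * .Machine$double.eps * max(rdiag, 0)
  k <- sum(rdiag > tol)
  if (k == 0) return(-(data$n_eff / 2) * logdet_pd(YtY, data$q))
  Qk <- qr.Q(qrx)[, seq_len(k), drop = FALSE]
  QtY <- crossprod(Qk, data$Y)
  S <- YtY - (g / (1 + g)) * crossprod(QtY)
  -(k * data$q / 2) * log1p(g) - (data$n_eff / 2) * logdet_pd(S, data$q)
}

# log determinant of a symmetric positive-definite matrix via Cholesky,
# falling back to eigenvalue clipping at 1e-12 * trace for near-singular input
logdet_pd <- function(S, q) {
  ch <- tryCatch(chol(S), error = function(e) NULL)
  if (!is.null(ch)) return(2 * sum(log(diag(ch))))
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  floor_ev <- 1e-12 * sum(diag(S)) / q
  if (all(ev < floor_ev)) {
    stop("residual cross-product matrix is numerically non-positive-definite")
  }
  warning("near-singular residual cross-product; clipping eigenvalues")
  sum(log(pmax(ev, floor_ev)))
}

#' Log posterior of a model
#'
#' Assembles the log posterior (up to a constant) from the marginal
#' likelihood, the model-space prior and the g hyper-prior. `-Inf` propagates
#' from the size truncation.
#'
#' @param data a [data_bundle()].
#' @param gamma integer vector of included SNP indices.
#' @param g positive selection coefficient.
#' @param size_prior a [model_size_prior()].
#' @param g_prior a [g_prior()].
#' @return object of class `log_posterior`: list with `value`, `logML`,
#'   `log_prior_gamma`, `log_prior_g`; `value` is their sum.
#' @export
log_posterior <- function(data, gamma, g, size_prior, g_prior) {
  gamma <- validate_model(gamma, data$p)
  lp_gamma <- log_prior_model(gamma, size_prior)
  lp_g <- log_prior_g(g, g_prior)
  lml <- if (length(gamma) < data$n - data$c_eff) {
    log_marginal_likelihood(data, gamma, g)
  } else {
    -Inf
  }
  structure(list(value = lml + lp_gamma + lp_g, logML = lml,
                 log_prior_gamma = lp_gamma, log_prior_g = lp_g),
            class = "log_posterior")
}

#' @export
print.log_posterior <- function(x, ...) {
  cat(sprintf("log posterior = %.6f (logML %.6f, log prior gamma %.6f, log prior g %.6f)\n",
              x$value, x$logML, x$log_prior_gamma, x$log_prior_g))
  invisible(x)
}
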