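#' Sparsity prior on model size
#'
#' Builds the prior on the number of SNPs included in the regression model,
#' parameterized by the natural quantities a user can elicit: the a priori
#' expected number of true associations `E`, its standard deviation `S`, and
#' the truncation multiplier `F`. Each SNP enters the model independently with
#' probability `omega`, and `omega` itself receives a Beta(a, b) prior, so the
#' marginal model size is beta-binomial. The hyper-parameters (a, b) are
#' obtained by moment matching so that the model size has mean `E` and
#' standard deviation `S`. Models larger than the truncation bound
#' `T = floor(E + F * S)` receive zero prior mass; the sampler rejects any
#' proposal beyond that size.
#'
#' The beta-binomial parameterization requires overdispersion relative to a
#' plain binomial, i.e. `S^2 > E * (1 - E/p)`. At exact equality the prior
#' degenerates to a binomial with inclusion probability `E/p`, which is what
#' `mode = "binomial"` provides explicitly.
#'
#' @param E prior mean model size (expected number of true associations),
#'   `0 < E < p`.
#' @param S prior standard deviation of the model size, `S > 0`.
#' @param F truncation multiplier; the hard cap on model size is
#'   `T = floor(E + F * S)`. Default 7, for which the untruncated prior mass
#'   beyond `T` is negligible (about `1 - pnorm(F)`).
#' @param p number of SNPs in the panel.
#' @param mode `"beta-binomial"` (default) or `"binomial"` (no
#'   overdispersion; `S` is then the implied binomial standard deviation and
#'   is computed, not supplied).
#' @return An object of class `model_size_prior`: a list with elements `E`,
#'   `S`, `F`, `p`, `T`, `a`, `b`, `pi_avg = E/p`, `likely_range = c(0, E + 3*S)`
#'   and `mode`.
#' @examples
#' pr <- model_size_prior(E = 2, S = 2, F = 7, p = 100)
#' pr$T
#' @export
model_size_prior <- function(E, S = NULL, F = 7, p, mode = c("beta-binomial", "binomial")) {
  mode <- match.arg(mode)
  stopifnot(length(E) == 1, length(p) == 1, is.finite(E), is.finite(p))
  if (!(E > 0 && E < p)) stop("'E' must satisfy 0 < E < p")
  if (F < 0) stop("'F' must be non-negative")
  pi_avg <- E / p
  binom_var <- E * (1 - pi_avg)   # p * pi * (1 - pi)

  if (mode == "binomial") {
    if (is.null(S)) S <- sqrt(binom_var)
    a <- b <- NA_real_
  } else {
    if (is.null(S)) stop("'S' is required for the beta-binomial prior")
    if (S <= 0) stop("'S' must be positive")
    if (S^2 < binom_var * (1 - 1e-9)) {
      stop("infeasible model-size prior: S^2 <= E*(1 - E/p) leaves no ",
           "overdispersion for the beta-binomial; use mode = \"binomial\"")
    }
    if (S^2 <= binom_var * (1 + 1e-9)) {
      # zero-overdispersion limit: fall back to the plain binomial prior
      warning("S^2 equals the binomial variance E*(1 - E/p); ",
              "using the plain binomial prior with inclusion probability E/p")
      return(model_size_prior(E, S, F, p, mode = "binomial"))
    }
    # solve S^2 = p*pi*(1-pi)*(p + c)/(1 + c) for the concentration c = a + b
    conc <- (p * binom_var - S^2) / (S^2 - binom_var)
    if (conc <= 0) {
      stop("infeasible model-size prior: S too large for panel size p ",
           "(requires S^2 < p * E * (1 - E/p))")
    }
    a <- pi_avg * conc
    b <- (1 - pi_avg) * conc
  }

  T_cap <- floor(E + F * S)
  if (T_cap < 1) stop("truncation bound T = floor(E + F*S) must be >= 1")
  structure(
    list(E = E, S = S, F = F, p = as.integer(p), T = as.integer(min(T_cap, p)),
         a = a, b = b, pi_avg = pi_avg,
         likely_range = c(0, E + 3 * S), mode = mode),
    class = "model_size_prior"
  )
}

#' @export
print.model_size_prior <- function(x, ...) {
  cat(sprintf("Model-size prior (%s): E = %g, S = %g, F = %g, p = %d\n",
              x$mode, x$E, x$S, x$F, x$p))
  cat(sprintf("  truncation T = %d; likely size range [%g, %g]\n",
              x$T, x$likely_range[1], x$likely_range[2]))
  cat(sprintf("  average per-SNP prior inclusion probability pi = %.3g\n", x$pi_avg))
  invisible(x)
}

#' Log prior mass of a specific model
#'
#' Returns the unnormalized log prior probability of one specific model
#' `gamma` (a set of included SNP indices): `log[f(k) / choose(p, k)]` where
#' `k` is the model size and `f` the (untruncated) beta-binomial or binomial
#' model-size pmf. All models of the same size are exchangeable a priori.
#' Models with `k > T` have probability zero (`-Inf`). The truncation
#' normalization constant is deliberately omitted; it cancels in every
#' Metropolis-Hastings acceptance ratio.
#'
#' @param gamma integer vector of included SNP column indices (1-based), or an
#'   empty vector for the null model.
#' @param prior a [model_size_prior()] object.
#' @return log prior mass (scalar), `-Inf` beyond the truncation bound.
#' @export
log_prior_model <- function(gamma, prior) {
  stopifnot(inherits(prior, "model_size_prior"))
  gamma <- validate_model(gamma, prior$p)
  k <- length(gamma)
  if (k > prior$T) return(-Inf)
  if (prior$mode == "binomial") {
    k * log(prior$pi_avg) + (prior$p - k) * log1p(-prior$pi_avg)
  } else {
    lbeta(k + prior$a, prior$p - k + prior$b) - lbeta(prior$a, prior$b)
  }
}

#' Validate a model indicator
#'
#' A model is a strictly increasing vector of included SNP column indices.
#'
#' @param gamma integer vector (possibly empty).
#' @param p panel size; all indices must lie in `1..p`.
#' @return the validated, sorted integer vector.
#' @export
validate_model <- function(gamma, p) {
  if (length(gamma) == 0) return(integer(0))
  gamma <- as.integer(gamma)
  if (anyNA(gamma) || any(gamma < 1L) || any(gamma > p)) {
    stop("model indices must lie in 1..p")
  }
  if (anyDuplicated(gamma)) stop("model indices must be distinct")
  sort(gamma)
}

#' Size of the truncated model space
#'
#' Number of models with at most `T` of `p` SNPs included,
#' `sum_{k=0}^{T} choose(p, k)`, computed in exact integer arithmetic (the
#' count overflows double precision already for moderate panels).
#'
#' @param p panel size.
#' @param T truncation bound, `0 <= T <= p`.
#' @return the exact count as a decimal character string; convert with
#'   `as.numeric()` when small enough. The base-10 logarithm is attached as
#'   attribute `"log10"`.
#' @examples
#' model_space_size(10, 3)  # "176"
#' @export
model_space_size <- function(p, T) {
  stopifnot(T >= 0, T <= p, p >= 0)
  p <- as.integer(p); T <- as.integer(T)
  # exact big-integer arithmetic in base 1e7; C(p,k+1) = C(p,k)*(p-k)/(k+1)
  # (the division is exact at every step)
  total <- bigint(1)
  term <- bigint(1)
  for (k in seq_len(T)) {
    term <- bigint_div_small(bigint_mul_small(term, p - k + 1L), k)
    total <- bigint_add(total, term)
  }
  out <- bigint_format(total)
  attr(out, "log10") <- log10_sum_choose(p, T)
  out
}

# -- minimal exact big-integer helpers (little-endian digit vectors, base 1e7) --

bigint_base <- 1e7

bigint <- function(x) {
  stopifnot(x >= 0, x < bigint_base)
  as.numeric(x)
}

bigint_carry <- function(d) {
  i <- 1L
  while (i <= length(d)) {
    if (d[i] >= bigint_base) {
      carry <- floor(d[i] / bigint_base)
      d[i] <- d[i] - carry * bigint_base
      if (i == length(d)) d <- c(d, 0)
      d[i + 1L] <- d[i + 1L] + carry
    }
    i <- i + 1L
  }
  while (length(d) > 1L && d[length(d)] == 0) d <- d[-length(d)]
  d
}

bigint_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  bigint_carry(a + b)
}

bigint_mul_small <- function(a, m) {
  # m <= ~2^31; split m to keep digit products exact in doubles
  m <- as.numeric(m)
  lo <- m %% 1e4
  hi <- (m - lo) / 1e4
  res <- bigint_carry(a * lo)
  if (hi > 0) {
    shifted <- bigint_carry(a * hi * 1e4)
    res <- bigint_add(res, shifted)
  }
  res
}

bigint_div_small <- function(a, m) {
  # exact division by small integer, most-significant digit first
  m <- as.numeric(m)
  rem <- 0
  out <- numeric(length(a))
  for (i in rev(seq_along(a))) {
    cur <- rem * bigint_base + a[i]
    out[i] <- floor(cur / m)
    rem <- cur - out[i] * m
  }
  if (rem != 0) stop("internal error: inexact big-integer division")
  while (length(out) > 1L && out[length(out)] == 0) out <- out[-length(out)]
  out
}

bigint_format <- function(a) {
  digits <- rev(a)
  paste0(digits[1], paste(sprintf("%07d", digits[-1]), collapse = ""))
}

log10_sum_choose <- function(p, T) {
  lg <- lchoose(p, 0:T) / log(10)
  m <- max(lg)
  m + log10(sum(10^(lg - m)))
}

#' Zellner-Siow hyper-prior on the selection coefficient g
#'
#' The g-prior on the regression coefficients is coupled with an
#' inverse-gamma(1/2, n/2) hyper-prior on the selection coefficient `g`,
#' which gives the coefficients a heavy-tailed (Cauchy-like) marginal prior.
#'
#' @param n sample size (number of individuals).
#' @return An object of class `g_prior`: list with `shape = 1/2`,
#'   `rate = n/2`, `n`.
#' @export
g_prior <- function(n) {
  stopifnot(n > 0)
  structure(list(shape = 0.5, rate = n / 2, n = n), class = "g_prior")
}

#' @export
print.g_prior <- function(x, ...) {
  cat(sprintf("Zellner-Siow g hyper-prior: inverse-gamma(shape = %g, rate = %g), n = %g\n",
              x$shape, x$rate, x$n))
  invisible(x)
}

#' Log density of the g hyper-prior
#'
#' @param g positive selection coefficient (vectorized).
#' @param spec a [g_prior()] object.
#' @return log density of InverseGamma(shape, rate) at `g`.
#' @export
log_prior_g <- function(g, spec) {
  stopifnot(inherits(spec, "g_prior"))
  if (any(g <= 0)) stop("'g' must be positive")
  spec$shape * log(spec$rate) - lgamma(spec$shape) -
    (spec$shape + 1) * log(g) - spec$rate / g
}

#' Draw from the g hyper-prior
#'
#' @param n_draws number of draws.
#' @param spec a [g_prior()] object.
#' @return numeric vector of inverse-gamma draws.
#' @export
r_prior_g <- function(n_draws, spec) {
  stopifnot(inherits(spec, "g_prior"))
  1 / stats::rgamma(n_draws, shape = spec$shape, rate = spec$rate)
}
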