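# Gamma-Poisson empirical-Bayes expression inference.
#
# Read sampling is modelled as Poisson: k ~ Poisson(lambda) with lambda the
# (linear-scale) probe-region expression. A conjugate Gamma(shape = alpha,
# rate = beta) prior on lambda gives posterior Gamma(alpha + k, beta + 1)
# after one observation, hence posterior mean (alpha + k) / (beta + 1).
# Marginally k is negative binomial with size alpha and success probability
# beta / (beta + 1); the hyperparameters are set per sample by maximising
# this marginal likelihood over the sample's full probe-region count vector.

#' Posterior-mean expression for one count
#'
#' Closed-form posterior mean of a Gamma(`shape`, `rate`) prior updated by a
#' single Poisson observation `k`: `(shape + k) / (rate + 1)`. Strictly
#' positive for any `k >= 0`, strictly increasing in `k`, and a convex
#' combination of the prior mean and `k` (shrinkage weight
#' `rate / (rate + 1)` on the prior mean).
#'
#' @param k non-negative integer count (vectorised).
#' @param prior a [gamma_prior()] or any list with `shape` and `rate`.
#' @return numeric vector of expression estimates (linear scale).
#' @export
posterior_mean <- function(k, prior) {
  if (any(k < 0)) stop("counts must be non-negative")
  (prior$shape + k) / (prior$rate + 1)
}

#' Gamma prior hyperparameters
#'
#' Container for the empirical-Bayes prior of one sample.
#'
#' @param shape,rate strictly positive gamma hyperparameters
#'   (shape--rate parameterisation).
#' @param fit_scope sample id the prior was fitted on, or `"pooled"`.
#' @param log_marginal,iterations,converged fit diagnostics.
#' @export
gamma_prior <- function(shape, rate, fit_scope = NA_character_,
                        log_marginal = NA_real_, iterations = NA_integer_,
                        converged = NA) {
  stopifnot(is.finite(shape), is.finite(rate), shape > 0, rate > 0)
  structure(list(shape = shape, rate = rate, fit_scope = fit_scope,
                 log_marginal = log_marginal, iterations = iterations,
                 converged = converged),
            class = "gamma_prior")
}

#' @export
print.gamma_prior <- function(x, ...) {
  cat(sprintf(
    "gamma_prior: shape %.4g, rate %.4g (mean %.4g), log marginal %.6g\n",
    x$shape, x$rate, x$shape / x$rate, x$log_marginal))
  invisible(x)
}

# Negative binomial log marginal likelihood of counts k under
# Gamma(a, b)-Poisson, parameterised by log(a), log(b).
nb_log_marginal <- function(log_par, k) {
  a <- exp(log_par[1]); b <- exp(log_par[2])
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0) return(-1e300)
  val <- suppressWarnings(
    sum(stats::dnbinom(k, size = a, prob = b / (b + 1), log = TRUE)))
  if (!is.finite(val)) return(-1e300)
  val
}

nb_log_marginal_grad <- function(log_par, k) {
  a <- exp(log_par[1]); b <- exp(log_par[2])
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    return(c(0, 0))
  da <- sum(digamma(a + k) - digamma(a) + log(b / (b + 1)))
  db <- sum(a / b - (a + k) / (b + 1))
  g <- c(a * da, b * db)
  g[!is.finite(g)] <- 0
  g
}

#' Fit the empirical-Bayes gamma prior
#'
#' Maximises the gamma--Poisson marginal likelihood (negative binomial with
#' size `shape` and success probability `rate / (rate + 1)`) of one
#' sample's probe-region counts over `(shape, rate)`, by BFGS with analytic
#' gradients in unconstrained log-parameter space, from three starts
#' (moment-matched, `(1, 1)`, `(0.1, 0.1)`) with the best marginal kept.
#'
#' Counts with no overdispersion (all equal, so the NB variance cannot
#' exceed the mean) make the optimum degenerate (`shape -> Inf`); in that
#' case a near-Poisson prior with the matching mean is returned with a
#' warning (`shape = 1e6 * max(mean, 1e-12) , rate = shape / mean`; an
#' all-zero vector falls back to `shape = 1e-6, rate = 1`).
#'
#' @param counts non-negative integer vector (one sample, all probe
#'   regions).
#' @param sample_id optional label stored in the prior's `fit_scope`.
#' @param grad_tol gradient-norm convergence tolerance (log-parameter
#'   space).
#' @return a [gamma_prior()].
#' @export
fit_gamma_prior <- function(counts, sample_id = NA_character_,
                            grad_tol = 1e-6) {
  if (any(counts < 0)) stop("counts must be non-negative")
  m <- mean(counts)
  if (length(unique(counts)) < 2L) {
    warning("degenerate counts (all equal); using near-Poisson fallback prior")
    if (m > 0) {
      shape <- 1e6 * m
      return(gamma_prior(shape, shape / m, fit_scope = sample_id,
                         log_marginal = sum(stats::dpois(counts, m,
                                                         log = TRUE)),
                         iterations = 0L, converged = TRUE))
    }
    return(gamma_prior(1e-6, 1, fit_scope = sample_id,
                       log_marginal = 0, iterations = 0L, converged = TRUE))
  }
  v <- var(counts)
  starts <- list(c(1, 1), c(0.1, 0.1))
  if (v > m) {
    starts <- c(list(c(m^2 / (v - m), m / (v - m))), starts)
  } else {
    starts <- c(list(c(max(m, 1e-3) * 10, 10)), starts)
  }
  best <- NULL
  total_iter <- 0L
  for (s in starts) {
    fit <- stats::optim(log(s), fn = nb_log_marginal,
                        gr = nb_log_marginal_grad, k = counts,
                        method = "BFGS",
                        control = list(fnscale = -1, maxit = 500L,
                                       reltol = 1e-14))
    total_iter <- total_iter + fit$counts[["function"]]
    if (is.null(best) || fit$value > best$value) best <- fit
  }
  gnorm <- sqrt(sum(nb_log_marginal_grad(best$par, counts)^2))
  converged <- gnorm < grad_tol * max(1, length(counts))
  if (!converged && gnorm > 1e-2 * length(counts))
    stop(sprintf(
      "prior fit did not converge (gradient norm %.3g, log marginal %.6g)",
      gnorm, best$value))
  gamma_prior(exp(best$par[1]), exp(best$par[2]), fit_scope = sample_id,
              log_marginal = best$value, iterations = total_iter,
              converged = converged)
}

#' Estimate probe-region expression from counts
#'
#' For each sample, fits the empirical-Bayes gamma prior on that sample's
#' full probe-region count vector (`prior_scope = "sample"`, the default;
#' `"pooled"` fits one prior on all samples' counts) and applies the
#' closed-form posterior mean elementwise. All estimates are strictly
#' positive, so the downstream log2 transform is always defined.
#'
#' @param counts a [count_matrix()] object or a non-negative integer matrix
#'   (regions x samples).
#' @param prior_scope `"sample"` or `"pooled"`.
#' @return list of class `probe_expression` with `estimates` (positive
#'   matrix, regions x samples, linear scale) and `priors` (named list of
#'   [gamma_prior()] per sample).
#' @export
estimate_expression <- function(counts, prior_scope = c("sample", "pooled")) {
  prior_scope <- match.arg(prior_scope)
  mat <- if (inherits(counts, "count_matrix")) counts$counts else
    as.matrix(counts)
  if (is.null(colnames(mat)))
    colnames(mat) <- paste0("sample_", seq_len(ncol(mat)))
  if (prior_scope == "pooled") {
    pooled <- fit_gamma_prior(as.vector(mat), sample_id = "pooled")
    priors <- setNames(rep(list(pooled), ncol(mat)), colnames(mat))
  } else {
    priors <- lapply(setNames(colnames(mat), colnames(mat)),
                     function(s) fit_gamma_prior(mat[, s], sample_id = s))
  }
  est <- mat
  for (s in colnames(mat)) est[, s] <- posterior_mean(mat[, s], priors[[s]])
  structure(list(estimates = est, priors = priors), class = "probe_expression")
}

#' @export
print.probe_expression <- function(x, ...) {
  cat(sprintf("probe_expression: %d regions x %d samples\n",
              nrow(x$estimates), ncol(x$estimates)))
  invisible(x)
}
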