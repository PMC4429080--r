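# Microarray-style summarisation of probe-level expression estimates:
# quantile normalisation across samples on the linear scale, log2, then
# per-group (gene or probe set) summarisation by median polish (RMA-style
# probe affinities) or by a probe-variance-weighted Gaussian model
# (RPA-style). Background correction is deliberately absent: sequencing
# counts have no optical background, and low-end noise is handled by the
# top-fraction filtering in the evaluation layer.

#' Quantile normalisation
#'
#' Forces every column (sample) to the common reference distribution: the
#' across-column mean of sorted columns. Within-column ranks are preserved;
#' tied values all receive the average of the reference values over their
#' tied rank positions, which makes the transform deterministic and
#' invariant to row permutations.
#'
#' @param x numeric matrix, features x samples, no missing values.
#' @return matrix of the same shape and dimnames.
#' @export
quantile_normalise <- function(x) {
  x <- as.matrix(x)
  if (anyNA(x)) stop("quantile_normalise: missing values not supported")
  if (ncol(x) == 1L) {
    warning("single-sample input: quantile normalisation is the identity")
    return(x)
  }
  sorted <- apply(x, 2L, sort)
  if (!is.matrix(sorted)) sorted <- matrix(sorted, nrow = 1L)
  ref <- rowMeans(sorted)
  out <- x
  for (j in seq_len(ncol(x))) {
    v <- x[, j]
    o <- order(v)
    col <- numeric(length(v))
    col[o] <- ref
    # average the reference values across tied ranks
    col <- stats::ave(col, match(v, v), FUN = mean)
    out[, j] <- col
  }
  out
}

#' Median polish decomposition
#'
#' Decomposes a probes x samples log-intensity matrix into
#' `overall + probe_effect + sample_effect + residual` (exact
#' reconstruction) by alternately sweeping out row then column medians
#' (classic Tukey median polish, via [stats::medpolish()]). Probe effects
#' are re-centred to sum to zero, with the shift absorbed into the overall
#' term, so summaries are unchanged. The summarised expression of sample
#' `j` is `overall + sample_effects[j]`.
#'
#' @param log_matrix numeric matrix, probes x samples (log2 scale).
#' @param tol convergence tolerance on the change in the sum of absolute
#'   residuals between sweeps.
#' @param max_iter maximum number of sweeps.
#' @return list with `overall`, `probe_effects`, `sample_effects`,
#'   `residuals` and `summaries` (`overall + sample_effects`).
#' @export
median_polish <- function(log_matrix, tol = 0.01, max_iter = 10L) {
  x <- as.matrix(log_matrix)
  stopifnot(nrow(x) >= 1L, ncol(x) >= 1L)
  if (nrow(x) == 1L) {
    probe <- setNames(0, rownames(x))
    summaries <- setNames(as.vector(x[1L, ]), colnames(x))
    return(list(overall = 0, probe_effects = probe,
                sample_effects = summaries,
                residuals = matrix(0, 1L, ncol(x), dimnames = dimnames(x)),
                summaries = summaries))
  }
  mp <- suppressWarnings(
    stats::medpolish(x, eps = tol, maxiter = max_iter, trace.iter = FALSE,
                     na.rm = FALSE))
  shift <- mean(mp$row)
  list(overall = mp$overall + shift,
       probe_effects = mp$row - shift,
       sample_effects = mp$col,
       residuals = mp$residuals,
       summaries = setNames(mp$overall + shift + mp$col, colnames(x)))
}

#' Probe-variance-weighted summarisation
#'
#' Summarises a probe group under the Gaussian model
#' `x[p, j] = mu[j] + a[p] + e[p, j]`, `e[p, j] ~ N(0, sigma2[p])`, by
#' alternating maximisation: sample summaries `mu` are precision-weighted
#' means over probes of `x - a`; probe affinities `a` are per-probe means
#' of `x - mu`, re-centred to sum to zero; probe variances are residual
#' mean squares floored at `variance_floor`. Probes with large variance are
#' down-weighted in the summaries — the probe-specific-noise idea behind
#' probabilistic summarisation methods. In the equal-variance limit the
#' summaries reduce to unweighted probe means after affinity centring.
#'
#' @param log_matrix numeric matrix, probes x samples (log2 scale); at
#'   least 2 samples are needed to estimate variances (with 1 sample the
#'   function falls back to [median_polish()] with a warning).
#' @param tol stop when the largest absolute parameter change over a sweep
#'   is below this.
#' @param max_iter maximum sweeps; non-convergence returns the current
#'   state with `converged = FALSE`.
#' @param variance_floor lower bound on fitted probe variances.
#' @return list with `summaries` (per sample), `probe_effects`,
#'   `probe_variances`, `iterations`, `converged`, `objective` (Gaussian
#'   log-likelihood at the final state).
#' @export
rpa_summarise <- function(log_matrix, tol = 1e-8, max_iter = 200L,
                          variance_floor = 1e-6) {
  x <- as.matrix(log_matrix)
  if (ncol(x) < 2L) {
    warning("fewer than 2 samples: falling back to median polish")
    mp <- median_polish(x)
    return(list(summaries = mp$summaries, probe_effects = mp$probe_effects,
                probe_variances = rep(variance_floor, nrow(x)),
                iterations = 0L, converged = TRUE, objective = NA_real_))
  }
  p <- nrow(x); n <- ncol(x)
  a <- rowMeans(x) - mean(x)
  s2 <- rep(max(variance_floor, stats::var(as.vector(x))), p)
  mu <- colMeans(x - a)
  objective <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    w <- 1 / s2
    mu_new <- colSums((x - a) * w) / sum(w)
    a_new <- rowMeans(x - rep(mu_new, each = p))
    a_new <- a_new - mean(a_new)
    resid <- x - rep(mu_new, each = p) - a_new
    s2_new <- pmax(variance_floor, rowMeans(resid^2))
    delta <- max(abs(mu_new - mu), abs(a_new - a), abs(s2_new - s2))
    mu <- mu_new; a <- a_new; s2 <- s2_new
    objective_new <- sum(-0.5 * (log(2 * pi * s2) * n + rowSums(resid^2) / s2))
    if (objective_new + 1e-12 < objective && delta > tol)
      warning("rpa_summarise: objective decreased")
    objective <- objective_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(summaries = setNames(mu, colnames(x)),
       probe_effects = setNames(a, rownames(x)),
       probe_variances = setNames(s2, rownames(x)),
       iterations = iter, converged = converged, objective = objective)
}

#' Summarise probe expression into gene / probe-set expression
#'
#' The summarisation pipeline applied to probe-level (linear-scale)
#' expression estimates: no background correction, quantile normalisation
#' across samples on the linear scale, log2, then one summarisation per
#' probe group. The group namespace (genes for custom-CDF style
#' annotations, or manufacturer probe sets) is taken from the index; both
#' modes share this code path.
#'
#' @param probe_expr a `probe_expression` object from
#'   [estimate_expression()], or a positive matrix (probes x samples) with
#'   probe-id rownames — e.g. a microarray probe-intensity table, which
#'   flows through the identical pipeline.
#' @param index a [build_probe_index()] object assigning probes to groups.
#' @param mode `"rma"` (median polish) or `"rpa"` (probe-variance
#'   weighting).
#' @param ... passed to [median_polish()] or [rpa_summarise()].
#' @return an [expression_table()] (groups x samples, log2 scale), with the
#'   index's namespace.
#' @export
summarise_expression <- function(probe_expr, index, mode = c("rma", "rpa"),
                                 ...) {
  mode <- match.arg(mode)
  mat <- if (inherits(probe_expr, "probe_expression")) probe_expr$estimates
         else as.matrix(probe_expr)
  if (is.null(rownames(mat))) stop("probe expression needs probe-id rownames")
  if (any(mat <= 0)) stop("probe expression must be strictly positive")
  known <- unlist(index$groups, use.names = FALSE)
  missing <- setdiff(rownames(mat), known)
  if (length(missing))
    stop("probes absent from the index: ", paste(head(missing, 3),
                                                 collapse = ", "))
  norm <- quantile_normalise(mat)
  logm <- log2(norm)
  groups <- index$groups
  present <- vapply(groups, function(p) any(p %in% rownames(logm)),
                    logical(1))
  if (any(!present)) {
    warning(sprintf("excluding %d group(s) with no probes in the matrix",
                    sum(!present)))
    groups <- groups[present]
  }
  summaries <- t(vapply(groups, function(probes) {
    sub <- logm[intersect(probes, rownames(logm)), , drop = FALSE]
    if (mode == "rma") median_polish(sub, ...)$summaries
    else rpa_summarise(sub, ...)$summaries
  }, numeric(ncol(logm))))
  if (ncol(logm) == 1L) summaries <- matrix(summaries, ncol = 1L,
                                            dimnames = list(names(groups),
                                                            colnames(logm)))
  colnames(summaries) <- colnames(logm)
  expression_table(summaries, namespace = index$namespace)
}
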