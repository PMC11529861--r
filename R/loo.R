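# Leave-one-out sufficient statistics.
#
# Everything here is computed by downdating two global accumulators — the
# per-gene sum and the gene-by-gene sum of outer products — so one pass over
# the samples suffices and peak memory stays at O(g^2) regardless of N.

loo_accumulators <- function(expr) {
  g <- nrow(expr)
  n <- ncol(expr)
  list(
    g = g, n = n,
    total_sum = rowSums(expr),
    total_outer = tcrossprod(expr),  # sum_i x_i x_i^T
    expr = expr
  )
}

.loo_cov_from_acc <- function(acc, i, divisor = c("unbiased", "ml")) {
  divisor <- match.arg(divisor)
  n <- acc$n
  x <- acc$expr[, i]
  m <- (acc$total_sum - x) / (n - 1)              # leave-one-out mean
  ss <- acc$total_outer - tcrossprod(x) - (n - 1) * tcrossprod(m)
  d <- if (divisor == "unbiased") n - 2 else n - 1
  s <- ss / d
  (s + t(s)) / 2                                   # enforce exact symmetry
}

#' Leave-one-out covariance matrix
#'
#' The sample covariance of the N - 1 samples excluding `sample_index`,
#' centred at their own leave-one-out mean. This matrix is the prior mean
#' for the excluded sample's covariance: each sample's network is shrunk
#' toward the covariance of everyone else. Computed by downdating global
#' accumulators, not by re-scanning the data per sample.
#'
#' @param expr expression matrix (genes x samples), see [as_expression()].
#' @param sample_index integer in 1..N.
#' @param divisor `"unbiased"` (N - 2, the default: the estimator is
#'   unbiased for the population covariance) or `"ml"` (N - 1).
#' @return g x g symmetric matrix.
#' @export
loo_covariance <- function(expr, sample_index, divisor = c("unbiased", "ml")) {
  expr <- as_expression(expr)
  if (ncol(expr) < 3) stop("insufficient-samples error: need N >= 3", call. = FALSE)
  stopifnot(sample_index >= 1, sample_index <= ncol(expr))
  .loo_cov_from_acc(loo_accumulators(expr), sample_index, divisor)
}

#' Leave-one-out variance statistics
#'
#' For each gene k, leaving out one sample at a time yields N estimates
#' eta_j^k of that gene's variance; their dispersion eta^(k) — the
#' population variance (divisor N) of the N leave-one-out variances —
#' measures how much any single sample can move the variance estimate.
#' Homogeneous data give small dispersions and hence strong shrinkage
#' toward the population covariance in [calibrate_dof()].
#'
#' @inheritParams loo_covariance
#' @return object of class `loo_stats`: list with `grand_mean` (length g),
#'   `loo_gene_variances` (N x g matrix, row j = leave-one-out variances
#'   with sample j removed), `eta_dispersion` (length g), `g`, `n`,
#'   `divisor`, and the accumulators used downstream.
#' @export
compute_loo_stats <- function(expr, divisor = c("unbiased", "ml")) {
  divisor <- match.arg(divisor)
  expr <- as_expression(expr)
  g <- nrow(expr)
  n <- ncol(expr)
  if (n < 3) stop("insufficient-samples error: need N >= 3", call. = FALSE)

  total_sum <- rowSums(expr)
  total_sq <- rowSums(expr^2)
  d <- if (divisor == "unbiased") n - 2 else n - 1
  # eta_j^k: variance of gene k over samples != j, via scalar downdates
  loo_var <- matrix(0, n, g, dimnames = list(colnames(expr), rownames(expr)))
  for (j in seq_len(n)) {
    x <- expr[, j]
    m <- (total_sum - x) / (n - 1)
    loo_var[j, ] <- pmax((total_sq - x^2 - (n - 1) * m^2) / d, 0)
  }
  eta_bar <- colMeans(loo_var)
  eta_dispersion <- colMeans(sweep(loo_var, 2, eta_bar)^2)  # divisor N

  structure(list(
    grand_mean = rowMeans(expr),
    total_sum = total_sum,
    total_outer = tcrossprod(expr),
    loo_gene_variances = loo_var,
    eta_dispersion = eta_dispersion,
    g = g, n = n, divisor = divisor, expr = expr
  ), class = "loo_stats")
}

#' @export
print.loo_stats <- function(x, ...) {
  cat(sprintf("Leave-one-out statistics: %d genes x %d samples (divisor: %s)\n",
              x$g, x$n, x$divisor))
  cat(sprintf("  sum of variance dispersions sum_k eta^(k) = %.6g\n",
              sum(x$eta_dispersion)))
  invisible(x)
}

#' Calibrate prior degrees of freedom for one sample
#'
#' Data-driven choice of the prior degrees of freedom nu_i and the mixing
#' weight delta_i = 1/(nu_i - g). Matching the total prior variance of the
#' diagonal entries of the sample's covariance, 2 sum_k s_kk^2 / (nu - g - 3),
#' to the observed leave-one-out dispersion sum_k eta^(k) gives
#' nu_i = g + 3 + 2 sum_k s_kk^2 / sum_k eta^(k), so delta_i is always in
#' (0, 1/3]. Samples that look like the rest of the population (small
#' dispersion) get small delta_i, i.e. heavy shrinkage toward the
#' leave-one-out covariance.
#'
#' @param stats a `loo_stats` object from [compute_loo_stats()].
#' @param S_i_diag diagonal of the sample's leave-one-out covariance.
#' @param g number of genes.
#' @param sample_id optional label carried into the result.
#' @return object of class `prior_spec`: list with `sample_id`, `nu`,
#'   `delta`, `g`, `prior_mean_diag_sq_sum` and a `degenerate` flag set when
#'   the data are perfectly homogeneous (delta -> 0 limit).
#' @export
calibrate_dof <- function(stats, S_i_diag, g, sample_id = NA_character_) {
  stopifnot(inherits(stats, "loo_stats"), length(S_i_diag) == g)
  if (any(S_i_diag < 0)) stop("validation error: negative diagonal in S_i", call. = FALSE)
  diag_sq <- sum(S_i_diag^2)
  eta_sum <- sum(stats$eta_dispersion)
  if (eta_sum == 0) {
    # perfectly homogeneous data: the delta -> 0 limit; downstream uses
    # Sigma_i = S_i exactly
    warning("degenerate calibration: zero leave-one-out dispersion; using delta -> 0 limit (posterior mean = leave-one-out covariance)",
            call. = FALSE)
    return(structure(list(sample_id = sample_id, nu = Inf, delta = 0, g = g,
                          prior_mean_diag_sq_sum = diag_sq, degenerate = TRUE),
                     class = "prior_spec"))
  }
  if (diag_sq == 0) {
    stop("degenerate-gene error: all leave-one-out variances are zero for this sample yet the dispersion is positive",
         call. = FALSE)
  }
  nu <- g + 3 + 2 * diag_sq / eta_sum
  structure(list(sample_id = sample_id, nu = nu, delta = 1 / (nu - g), g = g,
                 prior_mean_diag_sq_sum = diag_sq, degenerate = FALSE),
            class = "prior_spec")
}

#' Fixed mixing weight prior
#'
#' Bypasses calibration and uses the same delta for every sample
#' (nu = g + 1/delta). delta = 1 puts all weight on the sample's own
#' rank-one deviation (nu = g + 1, the smallest admissible degrees of
#' freedom); small delta shrinks hard toward the leave-one-out covariance.
#' Note edge p-values require nu - g > 3, i.e. delta < 1/3.
#'
#' @param delta mixing weight in (0, 1].
#' @param g number of genes.
#' @param sample_id optional label.
#' @return `prior_spec` object.
#' @export
fixed_delta_prior <- function(delta, g, sample_id = NA_character_) {
  if (!is.numeric(delta) || length(delta) != 1 || is.na(delta) ||
      delta <= 0 || delta > 1) {
    stop("parameter error: delta must lie in (0, 1]", call. = FALSE)
  }
  structure(list(sample_id = sample_id, nu = g + 1 / delta, delta = delta,
                 g = g, prior_mean_diag_sq_sum = NA_real_, degenerate = FALSE),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("prior_spec: nu = %.4g, delta = %.4g (g = %d)%s\n",
              x$nu, x$delta, x$g,
              if (isTRUE(x$degenerate)) " [degenerate: delta -> 0 limit]" else ""))
  invisible(x)
}
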