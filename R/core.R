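# Closed-form posterior for each sample-specific covariance, per-edge
# significance, correlation conversion and sparsification.

#' Posterior mean of a sample-specific covariance matrix
#'
#' The conjugate inverse-Wishart update has a closed-form posterior mean:
#' a convex combination of the sample's rank-one deviation from the grand
#' mean and the leave-one-out covariance,
#' `Sigma_i = delta * (x_i - xbar)(x_i - xbar)' + (1 - delta) * S_i`.
#' Both terms are positive semidefinite, so the estimate is too — the
#' structural guarantee that interpolation-based single-sample estimators
#' lack. The grand mean includes sample i itself.
#'
#' @param expr expression matrix.
#' @param sample_index integer in 1..N.
#' @param prior `prior_spec` from [calibrate_dof()] or [fixed_delta_prior()].
#' @param S_i the sample's leave-one-out covariance; computed via
#'   [loo_covariance()] when omitted.
#' @return g x g symmetric positive-semidefinite matrix.
#' @export
posterior_mean <- function(expr, sample_index, prior, S_i = NULL) {
  expr <- as_expression(expr)
  if (is.null(S_i)) S_i <- loo_covariance(expr, sample_index)
  g <- nrow(expr)
  if (!identical(dim(S_i), c(g, g)) || prior$g != g) {
    stop("validation error: dimension mismatch between expression, prior and S_i",
         call. = FALSE)
  }
  dev <- expr[, sample_index] - rowMeans(expr)
  delta <- prior$delta
  sig <- delta * tcrossprod(dev) + (1 - delta) * S_i
  dimnames(sig) <- list(rownames(expr), rownames(expr))
  (sig + t(sig)) / 2
}

#' Standard deviation of an edge's covariance under the model
#'
#' The spread of the covariance v_jk implied by an inverse-Wishart with
#' degrees of freedom nu and mean S:
#' `Var(v_jk) = ((nu-g+1) s_jk^2 + (nu-g-1) s_jj s_kk) / ((nu-g)(nu-g-3))`.
#' Used to build central-limit-theorem credible regions for each edge.
#' Requires nu - g > 3, which the data-driven calibration guarantees
#' strictly whenever the data are not perfectly homogeneous.
#'
#' All of `s_jj`, `s_kk`, `s_jk` may be vectors (recycled elementwise).
#'
#' @param prior `prior_spec`.
#' @param s_jj,s_kk diagonal entries of S for genes j and k.
#' @param s_jk off-diagonal entry of S.
#' @return psi_jk = sqrt(Var(v_jk)), same length as the inputs.
#' @export
posterior_edge_sd <- function(prior, s_jj, s_kk, s_jk) {
  m <- prior$nu - prior$g
  if (!is.finite(m) || m <= 3) {
    stop("degrees-of-freedom error: nu - g must exceed 3 for edge variances; use the calibrated prior (delta = \"auto\"), which guarantees nu >= g + 3",
         call. = FALSE)
  }
  if (any(s_jj < 0) || any(s_kk < 0)) {
    stop("validation error: negative diagonal entries", call. = FALSE)
  }
  v <- ((m + 1) * s_jk^2 + (m - 1) * s_jj * s_kk) / (m * (m - 3))
  sqrt(pmax(v, 0))
}

#' Per-edge p-values for a sample network
#'
#' Two-sided test of H0: v_jk = 0 from the normal approximation to the
#' posterior: `p_jk = 2 (1 - Phi(|sigma_jk| / psi_jk))` with sigma_jk the
#' posterior-mean entry and psi_jk from [posterior_edge_sd()]. An edge is
#' retained at level alpha exactly when the 100(1-alpha)% credible region
#' for v_jk excludes zero. Diagonal entries are computed for completeness
#' but flagged untestable (a null of zero variance is not meaningful); the
#' `diag_untestable` attribute on the result records this.
#'
#' @param post_mean posterior mean covariance from [posterior_mean()].
#' @param prior `prior_spec`.
#' @param S_i leave-one-out covariance supplying the spread entries.
#' @param edge_var `"as_printed"` evaluates the variance formula at the
#'   prior parameters (nu, S_i); `"posterior_params"` evaluates the same
#'   formula at the posterior parameters (nu + 1, Sigma_i), for users
#'   matching other implementations.
#' @return g x g symmetric matrix of p-values in [0, 1].
#' @export
edge_pvalues <- function(post_mean, prior, S_i,
                         edge_var = c("as_printed", "posterior_params")) {
  edge_var <- match.arg(edge_var)
  if (edge_var == "as_printed") {
    sref <- S_i
    vprior <- prior
  } else {
    sref <- post_mean
    vprior <- prior
    vprior$nu <- prior$nu + 1
  }
  d <- diag(sref)
  psi <- posterior_edge_sd(vprior, outer(d, rep(1, length(d))),
                           outer(rep(1, length(d)), d), sref)
  z <- abs(post_mean)
  p <- matrix(1, nrow(post_mean), ncol(post_mean), dimnames = dimnames(post_mean))
  ok <- psi > 0
  p[ok] <- 2 * stats::pnorm(z[ok] / psi[ok], lower.tail = FALSE)
  degen <- !ok & z > 0
  if (any(degen)) {
    warning("degenerate edge(s): zero spread with nonzero posterior mean; p set to 0",
            call. = FALSE)
    p[degen] <- 0
  }
  p <- (p + t(p)) / 2
  attr(p, "diag_untestable") <- TRUE
  p
}

#' Convert a covariance matrix to a correlation matrix
#'
#' Divides each covariance by the product of the two genes' standard
#' deviations. The transform is a congruence, so positive semidefiniteness
#' is preserved exactly; entries are clipped to [-1, 1] only when the
#' overshoot is at floating-point scale (<= 1e-12) — anything larger
#' signals an internal inconsistency and raises an error.
#'
#' @param cov g x g positive-semidefinite matrix with strictly positive
#'   diagonal.
#' @return correlation matrix with unit diagonal.
#' @export
cov_to_corr <- function(cov) {
  d <- diag(cov)
  if (any(d <= 0)) {
    bad <- if (!is.null(rownames(cov))) rownames(cov)[d <= 0] else which(d <= 0)
    stop("degenerate-gene error: nonpositive variance for gene(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  s <- 1 / sqrt(d)
  r <- cov * tcrossprod(s)
  over <- max(abs(r)) - 1
  if (over > 1e-12) {
    stop(sprintf("internal-consistency error: correlation overshoot %.3g exceeds 1e-12", over),
         call. = FALSE)
  }
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  (r + t(r)) / 2
}

#' Sparsify a sample network by edge significance
#'
#' Retains the edges whose credible region excludes zero: p_jk <= alpha,
#' optionally after Benjamini-Hochberg adjustment across the g(g-1)/2
#' upper-triangle p-values of this network (each sample's network is a
#' separate inference, so correction is per network, not across samples).
#'
#' @param net `bonobo_network` with p-values (see [bonobo()]).
#' @param alpha significance level in (0, 1); an edge with adjusted p equal
#'   to alpha is retained.
#' @param correction `"none"` or `"benjamini_hochberg"`.
#' @return object of class `bonobo_sparse`: list with `sample_id`, `alpha`,
#'   `correction` and `edges`, a tibble with columns gene_a, gene_b, weight
#'   (correlation), pvalue (adjusted when correction is applied), sorted by
#'   ascending p-value.
#' @export
sparsify <- function(net, alpha = 0.05,
                     correction = c("none", "benjamini_hochberg")) {
  correction <- match.arg(correction)
  if (!inherits(net, "bonobo_network")) stop("state error: expected a bonobo_network", call. = FALSE)
  if (is.null(net$pvalues)) stop("state error: network has no p-values; rerun with compute_pvalues = TRUE", call. = FALSE)
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
    stop("parameter error: alpha must lie in (0, 1)", call. = FALSE)
  }
  g <- nrow(net$correlation)
  genes <- rownames(net$correlation)
  ut <- which(upper.tri(net$pvalues))
  p <- net$pvalues[ut]
  if (correction == "benjamini_hochberg") p <- stats::p.adjust(p, method = "BH")
  keep <- p <= alpha
  idx <- arrayInd(ut[keep], dim(net$pvalues))
  edges <- tibble::tibble(
    gene_a = genes[idx[, 1]],
    gene_b = genes[idx[, 2]],
    weight = net$correlation[ut][keep],
    pvalue = p[keep]
  )
  edges <- tibble::as_tibble(.canonical_edges(edges))
  structure(list(sample_id = net$sample_id, alpha = alpha,
                 correction = correction, edges = edges),
            class = "bonobo_sparse")
}

#' @export
print.bonobo_sparse <- function(x, ...) {
  cat(sprintf("Sparse network for sample '%s': %d edges at alpha = %g (%s)\n",
              x$sample_id, nrow(x$edges), x$alpha, x$correction))
  invisible(x)
}

.one_sample_network <- function(expr, i, stats, prior, divisor,
                                compute_pvalues, edge_var) {
  S_i <- .loo_cov_from_acc(stats, i, divisor)
  if (isTRUE(prior$degenerate)) {
    sig <- S_i
  } else {
    dev <- expr[, i] - stats$grand_mean
    sig <- prior$delta * tcrossprod(dev) + (1 - prior$delta) * S_i
    sig <- (sig + t(sig)) / 2
  }
  dimnames(sig) <- list(rownames(expr), rownames(expr))
  pv <- NULL
  if (compute_pvalues) {
    if (isTRUE(prior$degenerate)) {
      # delta -> 0 limit: the model spread collapses, so only exact zeros
      # are untestable nulls
      pv <- ifelse(sig != 0, 0, 1)
      dimnames(pv) <- dimnames(sig)
      attr(pv, "diag_untestable") <- TRUE
    } else {
      pv <- edge_pvalues(sig, prior, S_i, edge_var = edge_var)
    }
  }
  structure(list(
    sample_id = colnames(expr)[i],
    post_mean_cov = sig,
    correlation = cov_to_corr(sig),
    pvalues = pv,
    nu = prior$nu,
    delta = prior$delta
  ), class = "bonobo_network")
}

#' @export
print.bonobo_network <- function(x, ...) {
  cat(sprintf("Sample-specific network '%s': %d genes, delta = %.4g, nu = %.4g%s\n",
              x$sample_id, nrow(x$correlation), x$delta, x$nu,
              if (is.null(x$pvalues)) "" else ", with p-values"))
  invisible(x)
}

#' Estimate one coexpression network per sample
#'
#' Runs the full empirical-Bayes pipeline: leave-one-out sufficient
#' statistics, per-sample calibration of the prior mixing weight delta_i
#' (or a fixed delta), the closed-form posterior mean covariance, its
#' correlation matrix, and per-edge p-values. Each sample's network is
#' computed independently from downdated accumulators, so results never
#' depend on sample order and the working state per sample is O(g^2).
#'
#' @param expr expression matrix or data frame (first column gene ids).
#' @param delta `"auto"` for per-sample calibration, or a fixed value in
#'   (0, 1] used for every sample. Edge p-values require delta < 1/3 when
#'   fixed.
#' @param compute_pvalues logical; skip to halve memory when only weights
#'   are needed.
#' @param cov_divisor divisor convention for the leave-one-out covariance,
#'   see [loo_covariance()].
#' @param edge_var see [edge_pvalues()].
#' @param drop_zero_variance see [as_expression()].
#' @return object of class `bonobo_fit`: list of `bonobo_network` objects
#'   (one per sample, input order) plus a `priors` tibble
#'   (sample_id, nu, delta).
#' @examples
#' expr <- matrix(rnorm(60), 5, 12,
#'                dimnames = list(paste0("g", 1:5), paste0("s", 1:12)))
#' fit <- bonobo(expr)
#' glance(fit)
#' @export
bonobo <- function(expr, delta = "auto", compute_pvalues = TRUE,
                   cov_divisor = c("unbiased", "ml"),
                   edge_var = c("as_printed", "posterior_params"),
                   drop_zero_variance = FALSE) {
  cov_divisor <- match.arg(cov_divisor)
  edge_var <- match.arg(edge_var)
  expr <- as_expression(expr, drop_zero_variance = drop_zero_variance)
  g <- nrow(expr)
  n <- ncol(expr)
  stats <- compute_loo_stats(expr, divisor = cov_divisor)
  auto <- identical(delta, "auto")
  if (!auto) {
    fixed <- fixed_delta_prior(delta, g)
  }
  nets <- vector("list", n)
  for (i in seq_len(n)) {
    prior <- if (auto) {
      calibrate_dof(stats, diag(.loo_cov_from_acc(stats, i, cov_divisor)),
                    g, sample_id = colnames(expr)[i])
    } else {
      fixed
    }
    nets[[i]] <- .one_sample_network(expr, i, stats, prior, cov_divisor,
                                     compute_pvalues, edge_var)
  }
  names(nets) <- colnames(expr)
  structure(list(
    networks = nets,
    priors = tibble::tibble(
      sample_id = colnames(expr),
      nu = vapply(nets, `[[`, numeric(1), "nu"),
      delta = vapply(nets, `[[`, numeric(1), "delta")
    ),
    g = g, n = n,
    delta_mode = if (auto) "auto" else "fixed",
    cov_divisor = cov_divisor,
    edge_var = edge_var
  ), class = "bonobo_fit")
}

#' @export
print.bonobo_fit <- function(x, ...) {
  cat(sprintf("bonobo fit: %d samples x %d genes (delta: %s, divisor: %s)\n",
              x$n, x$g, x$delta_mode, x$cov_divisor))
  cat(sprintf("  delta range: [%.4g, %.4g]\n",
              min(x$priors$delta), max(x$priors$delta)))
  invisible(x)
}
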