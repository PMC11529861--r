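# Baseline single-sample coexpression estimators used as benchmark
# comparators. Both are reference methods from the single-sample network
# literature; neither guarantees a positive-semidefinite result, which is
# exactly what the benchmark illustrates.

#' Linear-interpolation single-sample Pearson network
#'
#' The interpolation estimator applied to Pearson correlation:
#' `N * C_all - (N - 1) * C_minus_i`, where `C_all` is the correlation over
#' all N samples and `C_minus_i` over the N - 1 samples excluding sample i.
#' On heterogeneous data entries can leave [-1, 1] and the matrix can be
#' indefinite.
#'
#' @param expr expression matrix.
#' @param sample_index integer in 1..N.
#' @return object of class `baseline_network` with fields `sample_id`,
#'   `method`, `weights` (g x g), `pvalues` (NULL).
#' @export
lioness_pearson <- function(expr, sample_index) {
  expr <- as_expression(expr)
  n <- ncol(expr)
  if (n < 3) stop("insufficient-samples error: need N >= 3", call. = FALSE)
  c_all <- stats::cor(t(expr))
  c_loo <- stats::cor(t(expr[, -sample_index, drop = FALSE]))
  w <- n * c_all - (n - 1) * c_loo
  structure(list(sample_id = colnames(expr)[sample_index],
                 method = "lioness_pearson",
                 weights = (w + t(w)) / 2, pvalues = NULL),
            class = "baseline_network")
}

#' Single-sample Pearson contribution (z-score product) network
#'
#' Decomposes the Pearson correlation into per-sample contributions:
#' `w_jk = z_ij * z_ik` with z-scores computed against the across-sample
#' mean and population (divisor N) standard deviation, so the mean of
#' w_jk over samples equals the Pearson correlation exactly. Significance
#' is a two-sided Z-test of each sample's contribution against the
#' across-sample spread of that edge's contributions.
#'
#' @inheritParams lioness_pearson
#' @return `baseline_network` with `weights` and `pvalues`.
#' @export
spcc <- function(expr, sample_index) {
  expr <- as_expression(expr)
  n <- ncol(expr)
  mu <- rowMeans(expr)
  sd_pop <- sqrt(rowMeans((expr - mu)^2))  # divisor N
  if (any(sd_pop == 0)) {
    stop("degenerate-gene error: zero variance for gene(s): ",
         paste(rownames(expr)[sd_pop == 0], collapse = ", "), call. = FALSE)
  }
  z <- (expr - mu) / sd_pop                 # g x N matrix of z-scores
  w <- tcrossprod(z[, sample_index])
  # null spread: per-edge standard deviation of contributions across samples
  m1 <- tcrossprod(z) / n                   # mean of w over samples = Pearson r
  m2 <- tcrossprod(z^2) / n                 # mean over samples of z_j^2 z_k^2
  sd_w <- sqrt(pmax(m2 - m1^2, 0))
  p <- matrix(1, nrow(expr), nrow(expr), dimnames = list(rownames(expr), rownames(expr)))
  ok <- sd_w > 0
  p[ok] <- 2 * stats::pnorm(abs(w[ok] - m1[ok]) / sd_w[ok], lower.tail = FALSE)
  dimnames(w) <- list(rownames(expr), rownames(expr))
  structure(list(sample_id = colnames(expr)[sample_index], method = "spcc",
                 weights = (w + t(w)) / 2, pvalues = (p + t(p)) / 2),
            class = "baseline_network")
}

#' @export
print.baseline_network <- function(x, ...) {
  cat(sprintf("Baseline network (%s) for sample '%s': %d genes\n",
              x$method, x$sample_id, nrow(x$weights)))
  invisible(x)
}

#' All baseline networks for a data set
#'
#' @param expr expression matrix.
#' @param method `"lioness_pearson"` or `"spcc"`.
#' @return list of `baseline_network`, one per sample in input order.
#' @export
baseline_all_samples <- function(expr, method = c("lioness_pearson", "spcc")) {
  method <- match.arg(method)
  expr <- as_expression(expr)
  f <- switch(method, lioness_pearson = lioness_pearson, spcc = spcc)
  nets <- lapply(seq_len(ncol(expr)), function(i) f(expr, i))
  names(nets) <- colnames(expr)
  nets
}
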