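#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a sample-specific network into an edge tibble
#'
#' One row per unordered gene pair (upper triangle; self-edges dropped
#' because their null is untestable), with the correlation weight and,
#' when available, the p-value.
#'
#' @param x `bonobo_network`.
#' @param ... unused.
#' @return tibble with columns sample_id, gene_a, gene_b, weight
#'   (and pvalue).
#' @method tidy bonobo_network
#' @export
tidy.bonobo_network <- function(x, ...) {
  genes <- rownames(x$correlation)
  ut <- which(upper.tri(x$correlation), arr.ind = TRUE)
  out <- tibble::tibble(
    sample_id = x$sample_id,
    gene_a = genes[ut[, 1]],
    gene_b = genes[ut[, 2]],
    weight = x$correlation[upper.tri(x$correlation)]
  )
  if (!is.null(x$pvalues)) out$pvalue <- x$pvalues[upper.tri(x$pvalues)]
  out
}

#' Tidy a whole fit into a long edge tibble
#' @param x `bonobo_fit`.
#' @param ... unused.
#' @return row-bound [tidy.bonobo_network()] tibbles across samples.
#' @method tidy bonobo_fit
#' @export
tidy.bonobo_fit <- function(x, ...) {
  dplyr::bind_rows(lapply(x$networks, tidy))
}

#' One-row-per-sample summary of a fit
#' @param x `bonobo_fit`.
#' @param ... unused.
#' @return tibble with sample_id, nu, delta, mean absolute off-diagonal
#'   correlation, and the fraction of edges with p <= 0.05 when p-values
#'   are present.
#' @method glance bonobo_fit
#' @export
glance.bonobo_fit <- function(x, ...) {
  dplyr::mutate(
    x$priors,
    mean_abs_corr = vapply(x$networks, function(nw) {
      mean(abs(nw$correlation[upper.tri(nw$correlation)]))
    }, numeric(1)),
    prop_significant = vapply(x$networks, function(nw) {
      if (is.null(nw$pvalues)) return(NA_real_)
      mean(nw$pvalues[upper.tri(nw$pvalues)] <= 0.05)
    }, numeric(1))
  )
}

#' Tidy a sparse network
#' @param x `bonobo_sparse`.
#' @param ... unused.
#' @return the edge tibble with sample_id attached.
#' @method tidy bonobo_sparse
#' @export
tidy.bonobo_sparse <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(sample_id = rep(x$sample_id, nrow(x$edges))),
                   x$edges)
}

#' Plot benchmark results
#'
#' Mean squared Frobenius error per method across replicates, one panel
#' per (g, N) condition.
#'
#' @param object `bonobo_benchmark` tibble from [run_benchmark()].
#' @param scaled plot the scaled MSE instead.
#' @param ... unused.
#' @return ggplot object.
#' @method autoplot bonobo_benchmark
#' @export
autoplot.bonobo_benchmark <- function(object, scaled = FALSE, ...) {
  yvar <- if (scaled) "scaled_mse" else "mean_mse"
  ggplot2::ggplot(object, ggplot2::aes(x = .data$method, y = .data[[yvar]],
                                       fill = .data$method)) +
    ggplot2::geom_boxplot(alpha = 0.7, outlier.size = 0.6) +
    ggplot2::facet_wrap(~ paste0("g = ", .data$g, ", N = ", .data$N),
                        scales = "free_y") +
    ggplot2::labs(x = NULL,
                  y = if (scaled) "scaled MSE" else "squared Frobenius error",
                  title = paste("Scenario:", object$scenario[1])) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @importFrom rlang .data
NULL
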