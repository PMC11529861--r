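# Synthetic-data generators and the Frobenius-MSE benchmark.
#
# The generator emulates bulk log-expression: every individual has its own
# true covariance matrix drawn from an inverse-Wishart scattered around a
# population covariance, the observed data set holds exactly one draw per
# individual, and ground truth per individual is the empirical correlation
# of many held-out replicate draws under that individual's covariance.

#' Simulation configuration
#'
#' @param g number of genes.
#' @param n number of samples (individuals).
#' @param n_replicates benchmark replicates.
#' @param seed master seed; replicate seeds are derived deterministically.
#' @param scenario `"homogeneous"`, `"mixture"` or `"gene_loss"`.
#' @param mixture_fraction share of samples in the smaller population,
#'   in (0, 0.5].
#' @param loss_gene_fraction fraction of genes silenced in affected
#'   samples, in (0, 1).
#' @param loss_sample_fraction fraction of samples affected by the loss,
#'   in (0, 1).
#' @param truth_draws held-out replicate draws per individual whose
#'   empirical correlation defines that individual's ground truth
#'   (>= 100).
#' @param population_spread inverse-Wishart degrees of freedom controlling
#'   how far per-individual covariances scatter around the population
#'   covariance; must exceed g + 3. Larger values give a more homogeneous
#'   population. Default g + 40.
#' @param n_factors rank of the loading model behind the population
#'   correlation matrix.
#' @param mean_shift standard deviation of the per-gene mean offset of the
#'   minor mixture population (log2 units).
#' @return list of class `sim_config`.
#' @export
simulation_config <- function(g = 100, n = 100, n_replicates = 20, seed = 1,
                              scenario = c("homogeneous", "mixture", "gene_loss"),
                              mixture_fraction = 0.2,
                              loss_gene_fraction = 0.01,
                              loss_sample_fraction = 0.2,
                              truth_draws = 200,
                              population_spread = g + 40,
                              n_factors = 5,
                              mean_shift = 1) {
  scenario <- match.arg(scenario)
  stopifnot(g >= 2, n >= 3, n_replicates >= 1, truth_draws >= 100)
  if (mixture_fraction <= 0 || mixture_fraction > 0.5) {
    stop("parameter error: mixture_fraction must lie in (0, 0.5]", call. = FALSE)
  }
  if (loss_gene_fraction <= 0 || loss_gene_fraction >= 1 ||
      loss_sample_fraction <= 0 || loss_sample_fraction >= 1) {
    stop("parameter error: loss fractions must lie in (0, 1)", call. = FALSE)
  }
  if (population_spread <= g + 3) {
    stop("parameter error: population_spread must exceed g + 3", call. = FALSE)
  }
  structure(list(g = g, n = n, n_replicates = n_replicates, seed = seed,
                 scenario = scenario, mixture_fraction = mixture_fraction,
                 loss_gene_fraction = loss_gene_fraction,
                 loss_sample_fraction = loss_sample_fraction,
                 truth_draws = truth_draws,
                 population_spread = population_spread,
                 n_factors = n_factors, mean_shift = mean_shift),
            class = "sim_config")
}

# random population correlation from a low-rank factor model: correlated
# blocks of genes, unit diagonal
.random_population_corr <- function(g, n_factors) {
  b <- matrix(stats::rnorm(g * n_factors), g, n_factors)
  psi <- stats::runif(g, 0.3, 1)
  sig <- tcrossprod(b) + diag(psi)
  s <- 1 / sqrt(diag(sig))
  sig * tcrossprod(s)
}

# V ~ InvWishart((df - g - 1) * Sigma, df), so E[V] = Sigma
.rinvwishart_mean <- function(sigma, df) {
  g <- nrow(sigma)
  psi <- (df - g - 1) * sigma
  w <- stats::rWishart(1, df, solve(psi))[, , 1]
  v <- solve(w)
  (v + t(v)) / 2
}

#' Generate a synthetic population with per-individual ground truth
#'
#' Draws a population correlation matrix, scatters per-individual true
#' covariances around it via an inverse-Wishart, and emits (a) an observed
#' expression matrix with exactly one multivariate-normal draw per
#' individual and (b) one ground-truth correlation matrix per individual,
#' computed empirically from `truth_draws` held-out replicate draws under
#' that individual's covariance. The mixture scenario draws the configured
#' fraction of individuals from a second population with its own
#' correlation structure and mean offset; the gene-loss scenario silences
#' a gene subset in a sample subset (values set to 0 plus jitter of
#' sd 1e-6, in both the observed draw and the truth draws, so the loss is
#' part of the ground truth).
#'
#' @param config `sim_config` from [simulation_config()].
#' @return list with `expr` (g x n observed matrix), `truth` (list of n
#'   g x g true correlation matrices), `scenario` metadata (`minor_samples`,
#'   `lost_genes`, `affected_samples` where applicable).
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  g <- config$g
  n <- config$n
  genes <- sprintf("g%03d", seq_len(g))
  samples <- sprintf("s%03d", seq_len(n))
  base_mean <- stats::rnorm(g, mean = 6, sd = 2)   # log2-scale baselines

  pop_a <- .random_population_corr(g, config$n_factors)
  minor <- integer(0)
  means <- matrix(base_mean, g, n)
  pops <- rep(1L, n)
  if (config$scenario == "mixture") {
    pop_b <- .random_population_corr(g, config$n_factors)
    n_minor <- round(config$mixture_fraction * n)
    minor <- seq_len(n_minor)                     # which samples is arbitrary
    pops[minor] <- 2L
    means[, minor] <- base_mean + stats::rnorm(g, 0, config$mean_shift)
  }

  lost_genes <- integer(0)
  affected <- integer(0)
  if (config$scenario == "gene_loss") {
    lost_genes <- sample.int(g, max(1L, round(config$loss_gene_fraction * g)))
    affected <- sample.int(n, max(1L, round(config$loss_sample_fraction * n)))
  }

  expr <- matrix(0, g, n, dimnames = list(genes, samples))
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sigma_pop <- if (pops[i] == 2L) pop_b else pop_a
    v_i <- .rinvwishart_mean(sigma_pop, config$population_spread)
    ch <- chol(v_i)
    draws <- matrix(stats::rnorm((config$truth_draws + 1) * g),
                    config$truth_draws + 1, g) %*% ch
    colnames(draws) <- genes
    draws <- sweep(draws, 2, means[, i], `+`)
    if (i %in% affected) {
      draws[, lost_genes] <- stats::rnorm(nrow(draws) * length(lost_genes),
                                          0, 1e-6)
    }
    expr[, i] <- draws[1, ]
    truth[[i]] <- stats::cor(draws[-1, , drop = FALSE])
  }
  names(truth) <- samples
  list(expr = expr, truth = truth,
       minor_samples = samples[minor],
       lost_genes = genes[lost_genes],
       affected_samples = samples[affected])
}

#' Squared Frobenius distance between two matrices
#'
#' The benchmark's error measure: the sum of squared entrywise differences
#' between an estimated and a true correlation matrix. The scaled variant
#' divides by the variance of the upper-triangle entries of the truth, so
#' errors are comparable across truths of different overall correlation
#' strength.
#'
#' @param estimate,truth matrices of equal shape.
#' @param scaled divide by the variance of the truth's upper triangle.
#' @return nonnegative scalar.
#' @export
frobenius_mse <- function(estimate, truth, scaled = FALSE) {
  if (!all(dim(estimate) == dim(truth))) {
    stop("validation error: shape mismatch", call. = FALSE)
  }
  mse <- sum((estimate - truth)^2)
  if (scaled) {
    v <- stats::var(truth[upper.tri(truth)])
    mse <- mse / v
  }
  mse
}

.estimate_networks <- function(method, expr, alpha) {
  switch(method,
    bonobo = lapply(bonobo(expr, compute_pvalues = FALSE)$networks,
                    `[[`, "correlation"),
    bonobo_sparse = lapply(bonobo(expr)$networks, function(nw) {
      r <- nw$correlation
      r[nw$pvalues > alpha] <- 0
      diag(r) <- 1
      r
    }),
    lioness = lapply(baseline_all_samples(expr, "lioness_pearson"),
                     `[[`, "weights"),
    spcc = lapply(baseline_all_samples(expr, "spcc"), `[[`, "weights"),
    stop("unknown method: ", method, call. = FALSE)
  )
}

#' Run the simulation benchmark
#'
#' For each replicate, generates a fresh population (replicate seeds are
#' derived deterministically from `config$seed`), estimates all n sample
#' networks with each method, scores every network against that
#' individual's ground-truth correlation by squared Frobenius distance,
#' and averages over individuals.
#'
#' @param config `sim_config`.
#' @param methods subset of `c("bonobo", "bonobo_sparse", "lioness",
#'   "spcc")`, or a named list of externally computed estimators (functions
#'   `expr -> list of g x g matrices`).
#' @param alpha significance level used by `bonobo_sparse`.
#' @return tibble of class `bonobo_benchmark` with columns method,
#'   scenario, g, N, replicate, mean_mse, scaled_mse.
#' @export
run_benchmark <- function(config, methods = c("bonobo", "lioness", "spcc"),
                          alpha = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  known <- c("bonobo", "bonobo_sparse", "lioness", "spcc")
  if (is.character(methods)) {
    bad <- setdiff(methods, known)
    if (length(bad)) stop("unknown method: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  rep_seeds <- .derive_seeds(config$seed, config$n_replicates)
  rows <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    cfg_r <- config
    cfg_r$seed <- rep_seeds[r]
    pop <- generate_population(cfg_r)
    rows[[r]] <- purrr::map_dfr(methods, function(m) {
      nets <- if (is.function(m)) m(pop$expr) else .estimate_networks(m, pop$expr, alpha)
      mses <- purrr::map2_dbl(nets, pop$truth, frobenius_mse)
      smses <- purrr::map2_dbl(nets, pop$truth, frobenius_mse, scaled = TRUE)
      tibble::tibble(
        method = if (is.function(m)) "external" else m,
        scenario = config$scenario,
        g = config$g, N = config$n, replicate = r,
        mean_mse = mean(mses), scaled_mse = mean(smses)
      )
    })
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("bonobo_benchmark", class(out))
  attr(out, "config") <- config
  out
}

# deterministic, collision-free derivation of per-replicate seeds that
# stays inside 32-bit integer range
.derive_seeds <- function(master, k) {
  (as.integer(master) %% 1000003L) * 2048L + 7L * seq_len(k)
}

#' Gene-loss block error for one replicate
#'
#' Compares dense and sparse estimates on the edges incident to the lost
#' genes, restricted to the affected samples — the part of the network
#' where the ground truth is the silencing itself.
#'
#' @param pop output of [generate_population()] under the gene-loss
#'   scenario.
#' @param alpha significance level for the sparse estimate.
#' @return tibble with one row per estimator (`dense`, `sparse`) and the
#'   mean squared error over the lost-gene block of affected samples.
#' @export
gene_loss_block_error <- function(pop, alpha = 0.05) {
  stopifnot(length(pop$lost_genes) > 0, length(pop$affected_samples) > 0)
  fit <- bonobo(pop$expr)
  block_mse <- function(est, truth) {
    sel <- rownames(truth) %in% pop$lost_genes
    sum((est[sel, , drop = FALSE] - truth[sel, , drop = FALSE])^2) +
      sum((est[!sel, sel, drop = FALSE] - truth[!sel, sel, drop = FALSE])^2)
  }
  dense <- sparse <- 0
  for (sid in pop$affected_samples) {
    nw <- fit$networks[[sid]]
    r_dense <- nw$correlation
    r_sparse <- r_dense
    r_sparse[nw$pvalues > alpha] <- 0
    diag(r_sparse) <- 1
    dense <- dense + block_mse(r_dense, pop$truth[[sid]])
    sparse <- sparse + block_mse(r_sparse, pop$truth[[sid]])
  }
  k <- length(pop$affected_samples)
  tibble::tibble(estimator = c("dense", "sparse"),
                 block_mse = c(dense, sparse) / k)
}
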