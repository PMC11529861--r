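test_that("posterior mean is the stated convex combination", {
  expr <- rand_expr(2, 6, seed = 7)
  # delta = 1: the rank-one deviation term alone
  p1 <- fixed_delta_prior(1, g = 2)
  dev <- expr[, 3] - rowMeans(expr)
  expect_equal(posterior_mean(expr, 3, p1), tcrossprod(dev), tolerance = 1e-12,
               ignore_attr = TRUE)
  # a sample sitting exactly at the grand mean contributes nothing
  expr2 <- expr
  expr2[, 3] <- rowMeans(expr2[, -3])  # x_3 = mean of others = grand mean
  ph <- fixed_delta_prior(0.4, g = 2)
  S3 <- loo_covariance(expr2, 3)
  expect_equal(posterior_mean(expr2, 3, ph, S3), 0.6 * S3, tolerance = 1e-10)
})

test_that("posterior mean matches the hand-computed rank-one example", {
  # g = 2, deviation (1, 2), S = I, delta = 0.5:
  # 0.5 [[1,2],[2,4]] + 0.5 I = [[1, 1], [1, 2.5]]
  g <- 2
  expr <- matrix(c(0, 0, 3, 6, -3, -6), 2, 3,
                 dimnames = list(c("gA", "gB"), c("s1", "s2", "s3")))
  # grand mean is (0, 0); sample 2 deviates by (3, 6) -- rescale to (1, 2)
  expr <- expr / 3
  prior <- fixed_delta_prior(0.5, g)
  S <- diag(2)
  got <- posterior_mean(expr, 2, prior, S)
  expect_equal(unname(got), matrix(c(1, 1, 1, 2.5), 2), tolerance = 1e-12)
})

test_that("the two algebraic forms of the posterior mean agree", {
  # delta (x - xbar)(x - xbar)' + (1 - delta) S  vs
  # [(x - xbar)(x - xbar)' + (nu - g - 1) S] / (nu - g)
  for (seed in 1:5) {
    expr <- rand_expr(6, 9, seed = 200 + seed)
    st <- compute_loo_stats(expr)
    for (i in c(1, 5, 9)) {
      S_i <- loo_covariance(expr, i)
      prior <- calibrate_dof(st, diag(S_i), 6)
      sig <- posterior_mean(expr, i, prior, S_i)
      dev <- expr[, i] - rowMeans(expr)
      ratio <- (tcrossprod(dev) + (prior$nu - 6 - 1) * S_i) / (prior$nu - 6)
      expect_equal(unname(sig), unname(ratio), tolerance = 1e-12)
    }
  }
})

test_that("edge spread follows the closed form and guards its domain", {
  pr <- fixed_delta_prior(0.2, g = 0)  # nu - g = 5
  expect_equal(posterior_edge_sd(pr, 1, 1, 0)^2, 0.4, tolerance = 1e-12)
  expect_equal(posterior_edge_sd(pr, 1, 1, 0), 0.6325, tolerance = 1e-4)
  expect_equal(posterior_edge_sd(pr, 1, 1, 1)^2, 1.0, tolerance = 1e-12)
  pr3 <- fixed_delta_prior(1 / 3, g = 0)  # nu - g = 3: boundary errors
  expect_error(posterior_edge_sd(pr3, 1, 1, 0), "degrees-of-freedom")
})

test_that("p-values are two-sided, symmetric and correctly scaled", {
  expr <- rand_expr(3, 8, seed = 77)
  S <- loo_covariance(expr, 1)
  prior <- fixed_delta_prior(0.1, g = 3)
  sig <- posterior_mean(expr, 1, prior, S)
  p <- edge_pvalues(sig, prior, S)
  expect_true(isSymmetric(unclass(p), tol = 1e-12))
  expect_true(all(p >= 0 & p <= 1))
  expect_true(isTRUE(attr(p, "diag_untestable")))
  # zero posterior mean -> p = 1; |z| = 1.959964 -> p = 0.05; sign-invariance
  psi <- posterior_edge_sd(prior, S[1, 1], S[2, 2], S[1, 2])
  sig2 <- sig
  sig2[1, 2] <- sig2[2, 1] <- 0
  expect_equal(edge_pvalues(sig2, prior, S)[1, 2], 1)
  sig2[1, 2] <- sig2[2, 1] <- 1.959964 * psi
  expect_equal(edge_pvalues(sig2, prior, S)[1, 2], 0.05, tolerance = 1e-4)
  sig2[1, 2] <- sig2[2, 1] <- -1.959964 * psi
  expect_equal(edge_pvalues(sig2, prior, S)[1, 2], 0.05, tolerance = 1e-4)
})

test_that("covariance converts to correlation with exact unit diagonal", {
  d <- diag(c(2, 5, 9))
  dimnames(d) <- list(paste0("g", 1:3), paste0("g", 1:3))
  expect_equal(unname(cov_to_corr(d)), diag(3))
  m <- matrix(c(4, 2, 2, 9), 2, dimnames = list(c("gA", "gB"), c("gA", "gB")))
  r <- cov_to_corr(m)
  expect_equal(r["gA", "gB"], 1 / 3)
  expect_equal(diag(r), c(gA = 1, gB = 1))
  bad <- m
  bad[1, 1] <- 0
  expect_error(cov_to_corr(bad), "degenerate-gene")
})

test_that("correlation from any posterior mean stays positive semidefinite", {
  for (seed in 1:10) {
    g <- sample(3:15, 1)
    n <- sample(4:20, 1)
    expr <- rand_expr(g, n, seed = 300 + seed)
    fit <- bonobo(expr, compute_pvalues = FALSE)
    for (nw in fit$networks) {
      expect_psd(nw$post_mean_cov)
      expect_psd(nw$correlation)
      expect_true(all(abs(nw$correlation) <= 1 + 1e-12))
    }
  }
})

test_that("sparsification honours the retention rule and the BH oracle", {
  expr <- rand_expr(3, 10, seed = 41)
  fit <- bonobo(expr)
  nw <- fit$networks[[2]]
  # all p forced to 1 -> empty edge set
  nw1 <- nw
  nw1$pvalues[] <- 1
  expect_equal(nrow(sparsify(nw1, 0.05)$edges), 0)
  # hand BH: {0.01, 0.02, 0.04} -> adjusted {0.03, 0.03, 0.04}, all <= 0.05
  set_upper <- function(nw, vals) {
    pm <- matrix(1, 3, 3, dimnames = dimnames(nw$pvalues))
    pm[upper.tri(pm)] <- vals
    pm[lower.tri(pm)] <- t(pm)[lower.tri(pm)]
    nw$pvalues <- pm
    nw
  }
  nw2 <- set_upper(nw, c(0.01, 0.02, 0.04))
  sp <- sparsify(nw2, 0.05, correction = "benjamini_hochberg")
  expect_equal(sort(sp$edges$pvalue), c(0.03, 0.03, 0.04))
  expect_equal(nrow(sp$edges), 3)
  expect_equal(sort(sp$edges$pvalue), sort(brute_bh(c(0.01, 0.02, 0.04))))
  # an edge at exactly alpha is retained (rule is <=)
  nw3 <- set_upper(nw, c(0.05, 0.5, 0.9))
  expect_equal(nrow(sparsify(nw3, 0.05)$edges), 1)
  # missing p-values is a state error
  nw4 <- nw
  nw4$pvalues <- NULL
  expect_error(sparsify(nw4, 0.05), "state error")
})

test_that("estimation is deterministic and label-invariant", {
  expr <- rand_expr(10, 8, seed = 61)
  f1 <- bonobo(expr)
  f2 <- bonobo(expr)
  for (i in seq_along(f1$networks)) {
    expect_identical(f1$networks[[i]]$correlation, f2$networks[[i]]$correlation)
    expect_identical(f1$networks[[i]]$pvalues, f2$networks[[i]]$pvalues)
  }
  # relabelling samples changes nothing but the labels
  expr2 <- expr
  colnames(expr2) <- paste0("x", 1:8)
  f3 <- bonobo(expr2)
  expect_equal(unname(f3$networks[[4]]$correlation),
               unname(f1$networks[[4]]$correlation), tolerance = 1e-15)
})

test_that("shrinkage limit: small fixed delta recovers the leave-one-out covariance", {
  expr <- rand_expr(5, 9, seed = 71)
  dist_at <- function(delta) {
    fit <- bonobo(expr, delta = delta, compute_pvalues = FALSE)
    max(vapply(seq_len(9), function(i) {
      norm(fit$networks[[i]]$post_mean_cov - loo_covariance(expr, i), "F")
    }, numeric(1)))
  }
  d <- vapply(c(0.3, 0.1, 0.01, 0.001), dist_at, numeric(1))
  expect_true(all(diff(d) < 0))     # monotone decrease
  expect_lt(d[4], d[1] / 100)
})

test_that("at g = 1 the posterior reduces to the inverse-gamma update", {
  expr <- matrix(c(2, 4, 9, 5, 1), 1, 5,
                 dimnames = list("gA", paste0("s", 1:5)))
  nu <- 8
  prior <- fixed_delta_prior(1 / (nu - 1), g = 1)   # nu = g + 1/delta = 8
  for (i in 1:5) {
    s2 <- loo_covariance(expr, i)[1, 1]
    dev <- expr[1, i] - mean(expr)
    # scalar form of the closed-form posterior mean at g = 1
    expect_equal(posterior_mean(expr, i, prior)[1, 1],
                 (dev^2 + (nu - 2) * s2) / (nu - 1), tolerance = 1e-12)
  }
})

test_that("both edge-variance conventions are available and differ", {
  expr <- rand_expr(4, 12, seed = 81)
  f1 <- bonobo(expr, edge_var = "as_printed")
  f2 <- bonobo(expr, edge_var = "posterior_params")
  expect_false(isTRUE(all.equal(f1$networks[[1]]$pvalues,
                                f2$networks[[1]]$pvalues)))
  expect_true(all(f2$networks[[1]]$pvalues >= 0 &
                  f2$networks[[1]]$pvalues <= 1))
})
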