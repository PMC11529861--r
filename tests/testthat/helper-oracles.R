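# Shared fixtures and independent brute-force oracles. The oracles apply
# definitions directly (re-scan the data per leave-out) and never share code
# with the downdating implementation they check.

rand_expr <- function(g, n, seed, mean = 6, sd = 1) {
  set.seed(seed)
  matrix(rnorm(g * n, mean, sd), g, n,
         dimnames = list(paste0("g", seq_len(g)), paste0("s", seq_len(n))))
}

# definition applied directly: covariance of the remaining columns
brute_loo_cov <- function(expr, i, divisor = "unbiased") {
  m <- cov(t(expr[, -i, drop = FALSE]))  # divisor (N-1)-1 = N-2
  if (divisor == "ml") m <- m * (ncol(expr) - 2) / (ncol(expr) - 1)
  m
}

brute_loo_gene_vars <- function(expr) {
  n <- ncol(expr)
  t(vapply(seq_len(n), function(j) {
    apply(expr[, -j, drop = FALSE], 1, var)  # divisor N-2
  }, numeric(nrow(expr))))
}

brute_eta_dispersion <- function(loo_vars) {
  apply(loo_vars, 2, function(v) mean((v - mean(v))^2))  # divisor N
}

brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

min_rel_eigen <- function(m) {
  ev <- eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values
  min(ev) / max(abs(ev))
}

expect_psd <- function(m, tol = 1e-8) {
  expect_gte(min_rel_eigen(m), -tol)
}
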