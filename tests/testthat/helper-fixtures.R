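# Shared fixtures (built once per test run) and independent oracles.

# OpenBLAS thread-spinning is counterproductive on the single-CPU test boxes
set_blas_threads(1)

# small half-sib panel: 200 animals x ~390 SNPs after MAF pruning
fix_G <- simulate_genotypes(10, 20, 400, ld_rho = 0.5, seed = 42)
fix_kernels <- build_kernels(fix_G, which = c("A", "D", "AA", "AD", "DD"))

fix_effects <- simulate_effects(fix_G, c(A = 0.45, D = 0.05, AA = 0.15),
                                directional_shift = 1, seed = 43)
fix_pheno <- simulate_phenotypes(
  fix_G, fix_effects, factor_spec = c(sex = 2, farm = 8, slaughter_date = 10),
  seed = 44)
fix_design <- build_design(fix_pheno, min_level_size = 5)

# plain matrix view of a grm (drops class and name attribute)
as_mat <- function(K) {
  K <- unclass(K)
  attr(K, "kernel_name") <- NULL
  K
}

# brute-force unordered-pair additive-by-additive sum (pre-scaling oracle)
brute_pairwise_aa <- function(W) {
  n <- nrow(W); m <- ncol(W)
  K <- matrix(0, n, n)
  for (j in seq_len(m - 1)) for (k in (j + 1):m)
    K <- K + tcrossprod(W[, j]) * tcrossprod(W[, k])
  K
}

# Henderson mixed-model-equations solve: independent route to beta and BLUPs
# for one kernel with variances (s2g, s2e); obs = phenotyped indices.
mme_solve <- function(y, X, K, obs, s2g, s2e) {
  Kobs <- K[obs, obs]
  Ginv <- solve(Kobs * s2g)
  n <- length(y)
  Z <- diag(n)
  lhs <- rbind(cbind(crossprod(X), t(X)),
               cbind(X, diag(n) + s2e * Ginv))
  rhs <- c(crossprod(X, y), y)
  sol <- solve(lhs, rhs)
  beta <- sol[seq_len(ncol(X))]
  u_obs <- sol[-seq_len(ncol(X))]
  u_all <- drop(K[, obs] %*% solve(Kobs, u_obs))
  list(beta = beta, u_obs = u_obs, u_all = u_all)
}

# dense grid maximum of the restricted log-likelihood (oracle for the
# optimizer); multiplicative grid per component around var(y)
grid_loglik_max <- function(y, X, kernels, n_grid = 20) {
  vy <- stats::var(y)
  grid1 <- vy * exp(seq(log(0.02), log(4), length.out = n_grid))
  K <- length(kernels)
  grids <- c(rep(list(c(0, grid1)), K), list(grid1))
  combos <- expand.grid(grids)
  best <- -Inf
  for (i in seq_len(nrow(combos))) {
    ll <- restricted_loglik(y, X, kernels, as.numeric(combos[i, ]))
    if (ll > best) best <- ll
  }
  best
}
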