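test_that("null model recovers the closed-form OLS residual variance", {
  set.seed(21)
  y <- rnorm(40, mean = 3)
  fit <- fit_reml(y)
  expect_equal(unname(fit$varcomps["residual"]), stats::var(y), tolerance = 1e-6)
  expect_equal(unname(fit$beta), mean(y), tolerance = 1e-8)
  # restricted_loglik at the closed-form optimum beats nearby values
  X <- matrix(1, 40, 1)
  ll_opt <- restricted_loglik(y, X, list(), stats::var(y))
  expect_gt(ll_opt, restricted_loglik(y, X, list(), stats::var(y) * 1.3))
  expect_gt(ll_opt, restricted_loglik(y, X, list(), stats::var(y) * 0.7))
})

test_that("REML is invariant to translating y when X has an intercept", {
  set.seed(22)
  n <- 30
  K <- scale_trace(crossprod(matrix(rnorm(n * n), n)), "A")
  y <- rnorm(n)
  X <- cbind(1, rnorm(n))
  s <- c(0.5, 0.8)
  expect_equal(restricted_loglik(y, X, list(K), s),
               restricted_loglik(y + 100, X, list(K), s), tolerance = 1e-8)
})

test_that("optimizer matches the dense-grid oracle on random small instances", {
  set.seed(23)
  for (i in 1:5) {
    n <- sample(10:15, 1)
    nk <- sample(1:2, 1)
    kernels <- replicate(nk, {
      W <- matrix(rnorm(n * 20), n, 20)
      scale_trace(tcrossprod(W), "K")
    }, simplify = FALSE)
    names(kernels) <- paste0("K", seq_len(nk))
    y <- rnorm(n)
    X <- matrix(1, n, 1)
    fit <- suppressWarnings(fit_reml(y, X, kernels))
    expect_gte(fit$loglik, grid_loglik_max(y, X, kernels) - 1e-4)
  }
})

test_that("joint permutation of animals leaves the fit unchanged", {
  set.seed(24)
  n <- 60
  G <- subset_genotypes(fix_G, animals = 1:n)
  ks <- build_kernels(G, which = c("A", "AA"))
  eff <- simulate_effects(G, c(A = 0.5, AA = 0.2), seed = 1)
  y <- unname(eff$u_A + eff$u_AA + rnorm(n, sd = sqrt(0.3)))
  X <- cbind(1, rnorm(n))
  fit1 <- suppressWarnings(fit_reml(y, X, ks))
  perm <- sample(n)
  ksp <- lapply(ks, function(K) {
    M <- unclass(K)[perm, perm]
    scale_trace(M, kernel_name(K))
  })
  fit2 <- suppressWarnings(fit_reml(y[perm], X[perm, , drop = FALSE], ksp))
  expect_equal(fit1$varcomps, fit2$varcomps, tolerance = 1e-6)
  expect_equal(fit1$blups$A[perm], fit2$blups$A, tolerance = 1e-6)
})

test_that("BLUPs and extrapolation agree with a direct MME solve", {
  set.seed(25)
  n_all <- 50; n_obs <- 40
  W <- matrix(rnorm(n_all * 200), n_all, 200)
  rownames(W) <- sprintf("an%02d", 1:n_all)
  K <- build_kernel(W, "A")
  obs <- 1:n_obs
  # response with genuine additive signal so the variance stays off the boundary
  L <- chol(unclass(K) + diag(1e-8, n_all))
  u <- drop(crossprod(L, rnorm(n_all)))
  y <- u[obs] + rnorm(n_obs, sd = 0.7)
  X <- cbind(1, rnorm(n_obs))
  fit <- fit_reml(y, X, list(A = K), obs = obs, max_iter = 200)
  s2 <- fit$varcomps
  mme <- mme_solve(y, X, unclass(K), obs, s2["A"], s2["residual"])
  expect_equal(unname(fit$beta), unname(mme$beta), tolerance = 1e-6)
  expect_equal(unname(fit$blups$A), unname(mme$u_all), tolerance = 1e-6)
  # predict_unphenotyped consistency: in-fit animals reproduce their BLUPs
  pr <- predict_unphenotyped(fit, list(A = K), rownames(W))
  expect_equal(pr$A, unname(fit$blups$A), tolerance = 1e-10)
  expect_equal(pr$total, pr$A)
  expect_error(predict_unphenotyped(fit, list(A = K), "ghost"), "ghost")
})

test_that("a target unrelated to all phenotyped animals gets prediction zero", {
  set.seed(26)
  K <- diag(10) # identity kernel: no covariance between animals
  rownames(K) <- colnames(K) <- paste0("an", 1:10)
  K <- scale_trace(K, "A")
  y <- rnorm(8)
  fit <- suppressWarnings(fit_reml(y, kernels = list(A = K), obs = 1:8))
  pr <- predict_unphenotyped(fit, list(A = K), c("an9", "an10"))
  expect_equal(pr$total, c(0, 0))
})

test_that("AIC follows -2 logLik + 2 k and likelihood grows along nested models", {
  fit <- fit_model("AA2", fix_pheno, fix_kernels, design = fix_design)
  expect_equal(fit$aic, -2 * fit$loglik + 2 * 3)
  expect_equal(aic_reml(fit), fit$aic)
  lls <- vapply(c("A", "D", "AA", "AD", "Full"), function(m)
    suppressWarnings(fit_model(m, fix_pheno, fix_kernels,
                               design = fix_design))$loglik, numeric(1))
  expect_true(all(diff(lls) >= -1e-4)) # nested: loglik non-decreasing
})

test_that("variance proportions normalize to one and match direct computation", {
  set.seed(27)
  n <- 80
  G <- subset_genotypes(fix_G, animals = 1:n)
  A <- build_kernels(G, which = "A")$A
  eff <- simulate_effects(G, c(A = 0.5), seed = 2)
  y <- unname(eff$u_A) + rnorm(n, sd = sqrt(0.5))
  fit <- suppressWarnings(fit_reml(y, kernels = list(A = A)))
  vp <- variance_proportions(fit)
  expect_equal(sum(vp$proportion), 1)
  expect_equal(vp$proportion[vp$component == "A"],
               unname(fit$varcomps["A"] / sum(fit$varcomps)))
})

test_that("delta-method proportion SE is consistent with a parametric bootstrap", {
  set.seed(28)
  n <- 200
  G <- simulate_genotypes(10, 20, 500, ld_rho = 0.3, seed = 31)
  A <- build_kernels(G, which = "A")$A
  eff <- simulate_effects(G, c(A = 0.4), seed = 32)
  y <- unname(eff$u_A) + rnorm(n, sd = sqrt(0.6))
  X <- matrix(1, n, 1)
  fit <- fit_reml(y, X, list(A = A))
  vp <- variance_proportions(fit)
  se_delta <- vp$se[vp$component == "A"]
  th <- fit$varcomps
  V <- th["A"] * unclass(A) + diag(th["residual"], n)
  L <- chol(V)
  props <- replicate(100, {
    ystar <- drop(fit$beta) + drop(crossprod(L, rnorm(n)))
    f <- suppressWarnings(fit_reml(ystar, X, list(A = A), max_iter = 100))
    unname(f$varcomps["A"] / sum(f$varcomps))
  })
  expect_lt(abs(se_delta - stats::sd(props)) / stats::sd(props), 0.30)
})
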