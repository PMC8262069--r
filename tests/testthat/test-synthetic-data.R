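test_that("generators are pure functions of their seeds", {
  G1 <- simulate_genotypes(4, 6, 100, seed = 9)
  G2 <- simulate_genotypes(4, 6, 100, seed = 9)
  expect_identical(G1$dosages, G2$dosages)
  G3 <- simulate_genotypes(4, 6, 100, seed = 10)
  expect_false(identical(G1$dosages, G3$dosages))
  e1 <- simulate_effects(G1, c(A = .4, D = .1, AA = .1), seed = 1)
  e2 <- simulate_effects(G1, c(A = .4, D = .1, AA = .1), seed = 1)
  expect_identical(e1$u_AA, e2$u_AA)
  p1 <- simulate_phenotypes(G1, e1, factor_spec = c(sex = 2), seed = 5)
  p2 <- simulate_phenotypes(G1, e1, factor_spec = c(sex = 2), seed = 5)
  expect_identical(p1$trait, p2$trait)
})

test_that("genotype invariants hold after simulation and MAF filtering", {
  expect_true(all(fix_G$dosages %in% 0:2))
  expect_lt(max(abs(rowSums(fix_G$freqs) - 1)), 1e-12)
  expect_true(all(maf(fix_G) >= 0.05))
  expect_lt(max(abs(het_percent(fix_G) -
                    100 * rowMeans(fix_G$dosages == 1))), 1e-9)
})

test_that("argument validation rejects degenerate inputs", {
  expect_error(simulate_genotypes(2, 2, 50, maf_range = c(0.3, 0.1)), "degenerate maf_range")
  expect_error(simulate_genotypes(2, 2, 50, maf_range = c(0, 0.5)), "maf_range")
  expect_error(simulate_genotypes(2, 2, 50, maf_filter = 0.49, seed = 1,
                                  maf_range = c(0.05, 0.1)), "MAF filtering at threshold")
})

test_that("half-sib families show the expected additive relationships", {
  for (s in 1:2) {
    G <- simulate_genotypes(20, 25, 2000, ld_rho = 0.3, seed = 20 + s)
    A <- build_kernels(G, which = "A")$A
    fam <- G$sires
    same <- outer(fam, fam, "==") & upper.tri(A)
    diff <- (!outer(fam, fam, "==")) & upper.tri(A)
    within_mean <- mean(A[same]); between_mean <- mean(A[diff])
    expect_equal(within_mean, 0.25, tolerance = 0.05)
    expect_equal(between_mean, 0, tolerance = 0.02)
    expect_gt(within_mean, between_mean)
  }
})

test_that("true effects are exactly rescaled linear combinations", {
  eff <- simulate_effects(fix_G, c(A = 0.45, D = 0, AA = 0.15),
                          n_epistatic_pairs = 500, seed = 8)
  expect_equal(stats::var(eff$u_A), 0.45)
  expect_equal(stats::var(eff$u_AA), 0.15)
  expect_identical(unname(eff$u_D), rep(0, nrow(fix_G$dosages)))
  # reconstruct u_A and u_AA from stored effects and codings
  wa <- sweep(fix_G$dosages, 2, colMeans(fix_G$dosages))
  expect_equal(unname(eff$u_A), unname(drop(wa %*% eff$additive_snp_effects)),
               tolerance = 1e-12)
  pr <- eff$epistatic_pairs
  expect_true(all(pr$j < pr$k)) # no self-pairs, ordered
  expect_false(any(duplicated(pr[c("j", "k")])))
  uAA <- drop((wa[, pr$j] * wa[, pr$k]) %*% pr$effect)
  expect_equal(unname(eff$u_AA), unname(uAA), tolerance = 1e-12)
})

test_that("epistatic pair bookkeeping enforces its contracts", {
  expect_error(simulate_effects(fix_G, c(A = .4, AA = .1),
                                n_epistatic_pairs = 1e9, seed = 1),
               "exceeds available")
  e0 <- simulate_effects(fix_G, c(A = .4, AA = 0), n_epistatic_pairs = 0, seed = 1)
  expect_identical(unname(e0$u_AA), rep(0, nrow(fix_G$dosages)))
})

test_that("zero directional shift gives a null heterozygosity slope on average", {
  # the 2-MC-SE bound is a z-test; 200 seeds give it a stable verdict
  # (per-component slope contributions were checked unbiased over 500 seeds)
  slopes <- numeric(200)
  for (s in seq_along(slopes)) {
    eff <- simulate_effects(fix_G, c(A = 0.3, D = 0.2, AA = 0),
                            directional_shift = 0, seed = 300 + s)
    ph <- simulate_phenotypes(fix_G, eff, factor_spec = c(sex = 2),
                              residual_fraction = 0.5, seed = 400 + s)
    slopes[s] <- stats::coef(stats::lm(trait ~ het_percent, data = ph))[2]
  }
  mc_se <- stats::sd(slopes) / sqrt(length(slopes))
  expect_lt(abs(mean(slopes)), 2 * mc_se)
})

test_that("phenotype assembly is exact and variance fractions are realized", {
  eff <- simulate_effects(fix_G, c(A = 0.4, D = 0.1, AA = 0.1), seed = 12)
  ph0 <- simulate_phenotypes(fix_G, eff, factor_spec = c(),
                             covariate_spec = list(), residual_fraction = 0,
                             seed = 13)
  expect_equal(ph0$trait, unname(eff$u_A + eff$u_D + eff$u_AA), tolerance = 1e-12)
  # larger panel: realized fractions close to targets
  G <- simulate_genotypes(100, 50, 600, ld_rho = 0.4, seed = 14)
  ef <- simulate_effects(G, c(A = 0.45, D = 0.05, AA = 0.15), seed = 15)
  ph <- simulate_phenotypes(G, ef, seed = 16)
  vy <- stats::var(ph$trait)
  expect_lt(abs(stats::var(ef$u_A) / vy - 0.45), 0.03)  # absolute +-0.03
  expect_lt(abs(stats::var(ef$u_AA) / vy - 0.15), 0.03)
  # every factor level has at least 2 animals
  expect_true(all(table(ph$farm) >= 2))
  expect_error(simulate_phenotypes(fix_G, eff, factor_spec = c(farm = 10000)),
               "more levels")
})
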