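# Subsampling stability experiment: how do variance components and genetic
# effect estimates react when the phenotyped population shrinks?

#' Pearson correlation between effect estimates over an animal subset
#'
#' @param est_sub,est_full numeric vectors named by animal ID (or aligned).
#' @param id_subset IDs (or indices) defining the subset; must contain at
#'   least 3 animals.
#' @return Pearson correlation, or NA (with a warning) when either vector is
#'   constant over the subset.
#' @export
effect_correlation <- function(est_sub, est_full, id_subset) {
  a <- est_sub[id_subset]; b <- est_full[id_subset]
  stopifnot(length(a) == length(b), length(a) >= 3)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("zero variance in effect estimates; correlation undefined")
    return(NA_real_)
  }
  stats::cor(a, b)
}

# Re-scale a full-index kernel so that the mean diagonal over the sampled
# animals is 1 (trace over the sampled block = sample size), keeping the
# unsampled rows on the same scale for prediction.
.rescale_for_sample <- function(K, samp_idx) {
  d <- mean(diag(unclass(K))[samp_idx])
  if (d <= 0) stop("non-positive sampled-block trace")
  .new_grm(unclass(K) / d, kernel_name(K))
}

#' Subsampling stability of variance components and genetic effects
#'
#' Refits an intercept-only additive + additive-by-additive model on random
#' subsamples of the phenotyped animals (the response being phenotypes
#' already adjusted for fixed effects), predicts both components for ALL
#' animals, and correlates the estimates with those from the full-data fit —
#' separately for sampled animals (with phenotypes) and unsampled animals
#' (without). The experiment contrasts the stability of the variance
#' components against the instability of epistatic effect prediction.
#'
#' @param G a [genotype_matrix()] of all animals (used when
#'   `mode = "recompute"`, and to size the default subsample sizes).
#' @param y_adj numeric vector of adjusted phenotypes, one per animal of `G`,
#'   named by animal ID (e.g. from [adjusted_phenotypes()]).
#' @param sizes subsample sizes; default scales the canonical
#'   500/1000/5000/8865 schedule by `n / 9850` (dropping sizes below the
#'   identifiability minimum and above n).
#' @param n_replicates random draws per size (default 10).
#' @param mode `"recompute"` (default) rebuilds NOIA codings and kernels from
#'   each subsample's own genotype frequencies (applied to all animals for
#'   prediction); `"slice"` reuses the full-data kernels, re-scaled so the
#'   sampled block has mean diagonal 1.
#' @param nested if TRUE, within each replicate the smaller subsamples are
#'   subsets of the larger ones (one permutation per replicate).
#' @param seed integer seed.
#' @param ... passed to [fit_reml()].
#' @return Object of class `subsample_result`: `full_fit`, and a tidy
#'   data.frame `results` with one row per (size, replicate): variance
#'   components with SEs and the four correlations
#'   (`r_A_sampled`, `r_A_unsampled`, `r_AA_sampled`, `r_AA_unsampled`).
#' @export
run_subsampling <- function(G, y_adj, sizes = NULL, n_replicates = 10,
                            mode = c("recompute", "slice"), nested = FALSE,
                            seed = NULL, ...) {
  mode <- match.arg(mode)
  n <- nrow(G$dosages)
  ids <- animal_ids(G)
  stopifnot(length(y_adj) == n)
  if (!is.null(names(y_adj))) y_adj <- y_adj[ids]
  if (is.null(sizes)) {
    sizes <- unique(pmin(n, round(c(500, 1000, 5000, 8865) * n / 9850)))
  }
  if (any(sizes < 5)) stop("subsample size below identifiability minimum (5)")
  if (any(sizes > n)) stop("subsample size exceeds population size ", n)
  if (!is.null(seed)) set.seed(seed)

  kern_full <- build_kernels(G, which = c("A", "AA"))
  full_fit <- fit_reml(y = y_adj, kernels = kern_full, obs = ids, ...)
  uA_full <- full_fit$blups$A
  uAA_full <- full_fit$blups$AA

  perms <- if (nested)
    lapply(seq_len(n_replicates), function(i) sample.int(n)) else NULL
  rows <- list()
  for (sz in sizes) {
    for (rep_i in seq_len(n_replicates)) {
      samp <- if (nested) sort(perms[[rep_i]][seq_len(sz)])
              else sort(sample.int(n, sz))
      unsamp <- setdiff(seq_len(n), samp)
      if (sz == n) {
        kern <- kern_full
      } else if (mode == "recompute") {
        # codings from the subsample's genotype frequencies, applied to all
        # animals so unsampled effects can be predicted
        Gs <- subset_genotypes(G, animals = samp)
        f <- Gs$freqs
        p <- f[, "p1"] / 2 + f[, "p2"]
        poly <- which(p > 0 & p < 1)
        mcol <- (f[, "p1"] + 2 * f[, "p2"])[poly]
        W <- sweep(G$dosages[, poly, drop = FALSE], 2, mcol)
        A <- .rescale_for_sample(.new_grm(tcrossprod(W), "A"), samp)
        AA <- .rescale_for_sample(hadamard_kernel(A, A, "AA"), samp)
        kern <- list(A = A, AA = AA)
      } else {
        kern <- list(A = .rescale_for_sample(kern_full$A, samp),
                     AA = .rescale_for_sample(kern_full$AA, samp))
      }
      fit_s <- suppressWarnings(
        fit_reml(y = y_adj[samp], kernels = kern, obs = samp,
                 init = full_fit$varcomps, ...))
      rows[[length(rows) + 1]] <- data.frame(
        size = sz, replicate = rep_i,
        var_A = fit_s$varcomps[["A"]], se_A = fit_s$se[["A"]],
        var_AA = fit_s$varcomps[["AA"]], se_AA = fit_s$se[["AA"]],
        var_resid = fit_s$varcomps[["residual"]],
        se_resid = fit_s$se[["residual"]],
        converged = fit_s$converged,
        r_A_sampled = effect_correlation(fit_s$blups$A, uA_full, samp),
        r_A_unsampled = if (length(unsamp) >= 3)
          effect_correlation(fit_s$blups$A, uA_full, unsamp) else NA_real_,
        r_AA_sampled = effect_correlation(fit_s$blups$AA, uAA_full, samp),
        r_AA_unsampled = if (length(unsamp) >= 3)
          effect_correlation(fit_s$blups$AA, uAA_full, unsamp) else NA_real_)
    }
  }
  structure(list(full_fit = full_fit, results = do.call(rbind, rows),
                 sizes = sizes, mode = mode, n = n),
            class = "subsample_result")
}

#' @export
print.subsample_result <- function(x, ...) {
  cat(sprintf("subsampling experiment (n = %d, mode = %s)\n", x$n, x$mode))
  agg <- stats::aggregate(
    x$results[c("var_A", "var_AA", "r_A_unsampled", "r_AA_unsampled")],
    by = list(size = x$results$size), FUN = mean)
  print(agg, digits = 3, row.names = FALSE)
  invisible(x)
}
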