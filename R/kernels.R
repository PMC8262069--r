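# Genomic relationship matrices ("kernels") and their epistatic combinations.
#
# All kernels are dense symmetric matrices over a shared animal index, scaled
# so that their trace equals the number of animals; under that scaling the
# attached variance component is on the phenotypic scale.

.new_grm <- function(M, name) {
  structure(M, kernel_name = name, class = c("grm", "matrix", "array"))
}

#' Kernel name
#' @param K a `grm` kernel.
#' @return The kernel's name attribute.
#' @export
kernel_name <- function(K) attr(K, "kernel_name")

#' @export
print.grm <- function(x, ...) {
  cat(sprintf("grm kernel '%s': %d x %d, trace %.4f\n",
              kernel_name(x), nrow(x), ncol(x), sum(diag(x))))
  invisible(x)
}

#' Scale a relationship matrix to trace n
#'
#' Rescales a symmetric matrix so the sum of its diagonal elements equals the
#' number of animals. Idempotent.
#'
#' @param K symmetric numeric matrix (or `grm`).
#' @param name optional kernel name to attach.
#' @return A `grm` with trace equal to `nrow(K)`.
#' @export
scale_trace <- function(K, name = kernel_name(K)) {
  tr <- sum(diag(K))
  if (!is.finite(tr) || tr <= 0) stop("non-positive trace: ", tr)
  .new_grm(K * (nrow(K) / tr), if (is.null(name)) "K" else name)
}

#' Build a relationship kernel from a coding matrix
#'
#' `K = scale_trace(W W')`: the additive kernel A from the NOIA additive
#' coding, the dominance kernel D from the NOIA dominance coding.
#'
#' @param W animals x SNPs coding matrix with at least one column.
#' @param name kernel name (e.g. "A" or "D").
#' @return A trace-scaled `grm`.
#' @export
build_kernel <- function(W, name = "A") {
  if (is.null(dim(W)) || ncol(W) < 1) stop("coding matrix has no retained SNPs")
  K <- tcrossprod(W)
  rownames(K) <- colnames(K) <- rownames(W)
  scale_trace(K, name)
}

#' Hadamard-product epistatic kernel
#'
#' Element-wise product of two kernels over the same animal index, then
#' trace-scaled: AA = A o A, AD = A o D, DD = D o D.
#'
#' @param K1,K2 `grm` kernels with identical animal ordering.
#' @param name name for the product kernel.
#' @return A trace-scaled `grm`.
#' @export
hadamard_kernel <- function(K1, K2, name = paste0(kernel_name(K1), kernel_name(K2))) {
  if (!identical(dim(K1), dim(K2))) stop("kernel dimension mismatch")
  ids1 <- rownames(K1); ids2 <- rownames(K2)
  if (!is.null(ids1) && !is.null(ids2) && !identical(ids1, ids2)) {
    bad <- which(ids1 != ids2)[1]
    stop("animal index mismatch at position ", bad, ": '",
         ids1[bad], "' vs '", ids2[bad], "'")
  }
  scale_trace(unclass(K1) * unclass(K2), name)
}

#' Exact pairwise additive-by-additive kernel
#'
#' The Hadamard product A o A implicitly contains same-SNP squares and counts
#' each SNP pair twice (j,k and k,j). This constructor sums over unordered
#' SNP pairs j < k only:
#' `((W W') o (W W') - (W o W)(W o W)') / 2`, then trace-scales.
#'
#' @param W additive coding matrix with >= 2 SNP columns.
#' @param scale if FALSE, return the unscaled pair sum (used by the
#'   brute-force oracle tests).
#' @return A `grm` named "AAexact" (trace-scaled unless `scale = FALSE`).
#' @export
exact_pairwise_aa <- function(W, scale = TRUE) {
  if (is.null(dim(W)) || ncol(W) < 2) stop("need >= 2 SNPs for pairwise AA")
  WW <- tcrossprod(W)
  W2 <- W * W
  K <- (WW * WW - tcrossprod(W2)) / 2
  rownames(K) <- colnames(K) <- rownames(W)
  if (!scale) return(.new_grm(K, "AAexact"))
  scale_trace(K, "AAexact")
}

#' Build the standard kernel set for a genotype panel
#'
#' Computes NOIA codings and the requested trace-scaled kernels. Epistatic
#' kernels are Hadamard products of the (already trace-scaled) A and D,
#' re-scaled after the product.
#'
#' @param G a [genotype_matrix()].
#' @param which subset of `c("A","D","AA","AD","DD")`.
#' @param exact_aa if TRUE, additionally include the exact pairwise AA kernel
#'   as `"AAexact"`.
#' @return A named list of `grm` kernels (class `kernel_set`) with attributes
#'   recording the SNP counts used.
#' @export
build_kernels <- function(G, which = c("A", "D", "AA", "AD", "DD"),
                          exact_aa = FALSE) {
  which <- match.arg(which, c("A", "D", "AA", "AD", "DD"), several.ok = TRUE)
  cod <- noia_codings(G)
  out <- list()
  need_a <- any(c("A", "AA", "AD") %in% which) || exact_aa
  need_d <- any(c("D", "AD", "DD") %in% which)
  A <- if (need_a) build_kernel(cod$W_add, "A") else NULL
  D <- if (need_d) build_kernel(cod$W_dom, "D") else NULL
  for (w in which) {
    out[[w]] <- switch(w,
      A = A, D = D,
      AA = hadamard_kernel(A, A, "AA"),
      AD = hadamard_kernel(A, D, "AD"),
      DD = hadamard_kernel(D, D, "DD"))
  }
  if (exact_aa) out[["AAexact"]] <- exact_pairwise_aa(cod$W_add)
  structure(out, class = "kernel_set",
            n_snps_add = ncol(cod$W_add), n_snps_dom = ncol(cod$W_dom))
}

#' @export
print.kernel_set <- function(x, ...) {
  cat("kernel_set:", paste(names(x), collapse = ", "),
      sprintf("(%d animals)\n", nrow(x[[1]])))
  invisible(x)
}

#' Summary of off-diagonal kernel elements
#'
#' Mean, SD, mean absolute value and quantiles of the strictly off-diagonal
#' elements of each kernel — the diagnostic behind the observation that
#' additive-by-additive relationships are much closer to zero than additive
#' ones, which is why epistatic effects extrapolate poorly.
#'
#' @param kernels a `kernel_set` or named list of `grm` kernels.
#' @param probs quantiles to report.
#' @return data.frame with one row per kernel.
#' @export
offdiagonal_summary <- function(kernels, probs = c(0.05, 0.25, 0.5, 0.75, 0.95)) {
  if (inherits(kernels, "grm")) kernels <- stats::setNames(list(kernels), kernel_name(kernels))
  stopifnot(nrow(kernels[[1]]) >= 2)
  rows <- lapply(names(kernels), function(nm) {
    K <- kernels[[nm]]
    od <- K[lower.tri(K)]
    qs <- stats::quantile(od, probs)
    data.frame(kernel = nm, mean = mean(od), sd = stats::sd(od),
               mean_abs = mean(abs(od)), t(qs), check.names = FALSE)
  })
  do.call(rbind, rows)
}

#' Thin SNP density in consecutive blocks
#'
#' Emulates a SNP-density reduction experiment: within each consecutive block
#' of `block` SNPs (genome order within chromosome), retain
#' `round(fraction * block)` SNPs sampled uniformly without replacement; a
#' final partial block is sampled proportionally. `fraction = 1` is the
#' identity.
#'
#' @param G a [genotype_matrix()].
#' @param fraction fraction of SNPs to retain, in (0, 1]; the canonical
#'   experiment uses 0.125, 0.25, 0.5 and 0.75.
#' @param block block length (default 8 consecutive SNPs).
#' @param seed integer seed for the within-block sampling.
#' @return A `genotype_matrix` with the retained SNPs in original order.
#' @export
reduce_snp_density <- function(G, fraction, block = 8, seed = NULL) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (fraction == 1) return(G)
  if (!is.null(seed)) set.seed(seed)
  k_per_block <- fraction * block
  if (abs(k_per_block - round(k_per_block)) > 1e-9)
    message("fraction * block = ", k_per_block, " rounded to ", round(k_per_block))
  k_per_block <- round(k_per_block)
  m <- ncol(G$dosages)
  chrom <- if (!is.null(G$positions)) G$positions$chrom else rep(1L, m)
  keep <- unlist(lapply(split(seq_len(m), chrom), function(idx) {
    blocks <- split(idx, ceiling(seq_along(idx) / block))
    unlist(lapply(blocks, function(b) {
      k <- if (length(b) == block) k_per_block else round(fraction * length(b))
      if (k <= 0) return(integer(0))
      sort(b[sample.int(length(b), min(k, length(b)))])
    }))
  }), use.names = FALSE)
  keep <- sort(keep)
  if (length(keep) == 0) stop("no SNPs retained at fraction ", fraction)
  subset_genotypes(G, snps = keep)
}

#' Adjacent-SNP linkage disequilibrium summary
#'
#' Squared Pearson correlation of dosages for each pair of adjacent SNPs
#' (within chromosome when positions are available, else in column order),
#' with quantiles of the r-squared distribution.
#'
#' @param G a [genotype_matrix()].
#' @param probs quantiles to report (default 50/70/90%).
#' @return List with `r2` (full vector), `quantiles`, and `n_skipped` (pairs
#'   skipped because one member had zero variance).
#' @export
ld_adjacent_r2 <- function(G, probs = c(0.5, 0.7, 0.9)) {
  dos <- G$dosages
  m <- ncol(dos)
  stopifnot(m >= 2)
  chrom <- if (!is.null(G$positions)) G$positions$chrom else rep(1L, m)
  sds <- apply(dos, 2, stats::sd)
  r2 <- c(); skipped <- 0L
  for (idx in split(seq_len(m), chrom)) {
    if (length(idx) < 2) next
    j1 <- idx[-length(idx)]; j2 <- idx[-1]
    ok <- sds[j1] > 0 & sds[j2] > 0
    skipped <- skipped + sum(!ok)
    j1 <- j1[ok]; j2 <- j2[ok]
    if (length(j1))
      r2 <- c(r2, vapply(seq_along(j1), function(i)
        stats::cor(dos[, j1[i]], dos[, j2[i]])^2, numeric(1)))
  }
  list(r2 = r2, quantiles = stats::quantile(r2, probs), n_skipped = skipped)
}
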