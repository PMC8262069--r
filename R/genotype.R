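#' Genotype matrix container
#'
#' Holds a biallelic SNP dosage matrix (animals x SNPs, values 0/1/2 counting
#' copies of the alternative allele), per-SNP observed genotype frequencies,
#' optional map positions and, when produced by the simulator, the sire of
#' each animal.
#'
#' @param dosages integer matrix, animals in rows (rownames = animal IDs),
#'   SNPs in columns (colnames = SNP IDs); values must be 0, 1 or 2.
#' @param positions optional data.frame with columns `chrom` and `bp`, one row
#'   per SNP in column order.
#' @param sires optional character/integer vector of sire IDs, one per animal.
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `freqs` (n_snps x 3 matrix of observed genotype frequencies p0, p1, p2),
#'   `positions` and `sires`.
#' @export
genotype_matrix <- function(dosages, positions = NULL, sires = NULL) {
  dosages <- as.matrix(dosages)
  if (!all(dosages %in% c(0L, 1L, 2L))) {
    bad <- which(!(dosages %in% c(0L, 1L, 2L)), arr.ind = TRUE)[1, ]
    stop("dosage not in {0,1,2} at animal row ", bad[1], ", SNP column ", bad[2])
  }
  storage.mode(dosages) <- "integer"
  if (is.null(rownames(dosages)))
    rownames(dosages) <- sprintf("ind%04d", seq_len(nrow(dosages)))
  if (is.null(colnames(dosages)))
    colnames(dosages) <- sprintf("snp%05d", seq_len(ncol(dosages)))
  if (anyDuplicated(rownames(dosages))) stop("duplicated animal IDs")
  if (anyDuplicated(colnames(dosages))) stop("duplicated SNP IDs")
  if (!is.null(positions)) {
    stopifnot(nrow(positions) == ncol(dosages),
              all(c("chrom", "bp") %in% names(positions)))
    rownames(positions) <- colnames(dosages)
  }
  if (!is.null(sires)) stopifnot(length(sires) == nrow(dosages))
  structure(list(dosages = dosages,
                 freqs = .geno_freqs(dosages),
                 positions = positions,
                 sires = sires),
            class = "genotype_matrix")
}

.geno_freqs <- function(dos) {
  n <- nrow(dos)
  f <- cbind(p0 = colMeans(dos == 0L),
             p1 = colMeans(dos == 1L),
             p2 = colMeans(dos == 2L))
  rownames(f) <- colnames(dos)
  f
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d animals x %d SNPs\n",
              nrow(x$dosages), ncol(x$dosages)))
  m <- maf(x)
  cat(sprintf("  MAF range: %.3f - %.3f; mean heterozygosity: %.1f%%\n",
              min(m), max(m), mean(het_percent(x))))
  if (!is.null(x$sires))
    cat(sprintf("  %d sires recorded\n", length(unique(x$sires))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Animal IDs of a genotype matrix
#' @param G a `genotype_matrix`.
#' @return Character vector of animal IDs.
#' @export
animal_ids <- function(G) rownames(G$dosages)

#' SNP IDs of a genotype matrix
#' @param G a `genotype_matrix`.
#' @return Character vector of SNP IDs.
#' @export
snp_ids <- function(G) colnames(G$dosages)

#' Allele frequency of the alternative allele per SNP
#' @param G a `genotype_matrix`.
#' @return Numeric vector of alt-allele frequencies.
#' @export
alt_freq <- function(G) colMeans(G$dosages) / 2

#' Minor allele frequency per SNP
#' @param G a `genotype_matrix`.
#' @return Numeric vector of minor allele frequencies.
#' @export
maf <- function(G) {
  p <- alt_freq(G)
  pmin(p, 1 - p)
}

#' Per-animal SNP heterozygosity, in percent
#'
#' The proportion of heterozygous SNP genotypes per animal, times 100. Used as
#' the directional-dominance covariate in the model suite.
#'
#' @param G a `genotype_matrix`.
#' @return Numeric vector, one value per animal.
#' @export
het_percent <- function(G) 100 * rowMeans(G$dosages == 1L)

#' Subset a genotype matrix
#'
#' Subsets animals and/or SNPs and recomputes genotype frequencies on the
#' retained animal set (NOIA codings downstream always use the frequencies of
#' the analysed animals).
#'
#' @param G a `genotype_matrix`.
#' @param animals animal IDs or indices to keep (default all).
#' @param snps SNP IDs or indices to keep (default all).
#' @return A `genotype_matrix` over the selected animals and SNPs.
#' @export
subset_genotypes <- function(G, animals = NULL, snps = NULL) {
  dos <- G$dosages
  sir <- G$sires
  if (!is.null(animals)) {
    dos <- dos[animals, , drop = FALSE]
    if (!is.null(sir)) {
      idx <- if (is.character(animals)) match(animals, animal_ids(G)) else animals
      sir <- sir[idx]
    }
  }
  pos <- G$positions
  if (!is.null(snps)) {
    dos <- dos[, snps, drop = FALSE]
    if (!is.null(pos)) {
      idx <- if (is.character(snps)) match(snps, snp_ids(G)) else snps
      pos <- pos[idx, , drop = FALSE]
    }
  }
  genotype_matrix(dos, positions = pos, sires = sir)
}

#' Remove SNPs below a minor-allele-frequency threshold
#'
#' Drops monomorphic SNPs and SNPs with MAF below `threshold` (the study-style
#' QC is MAF > 0.05).
#'
#' @param G a `genotype_matrix`.
#' @param threshold minimum minor allele frequency to retain a SNP.
#' @return A filtered `genotype_matrix`.
#' @export
filter_maf <- function(G, threshold = 0.05) {
  keep <- maf(G) >= threshold & maf(G) > 0
  if (!any(keep))
    stop("all SNPs removed by MAF filtering at threshold ", threshold)
  subset_genotypes(G, snps = which(keep))
}
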