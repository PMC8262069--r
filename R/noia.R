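# NOIA (natural and orthogonal interactions) marker codings.
#
# Under the NOIA parameterisation, codings are defined from the OBSERVED
# genotype frequencies (p0, p1, p2) of the analysed animal set, which makes
# the per-SNP additive and dominance coding columns exactly orthogonal under
# those frequencies and the additive effect a least-squares (statistical)
# effect. Frequencies must be recomputed whenever the animal set changes.

#' NOIA additive coding for one SNP
#'
#' Returns the coded values assigned to dosages (0, 1, 2):
#' `(-m, 1 - m, 2 - m)` with `m = p1 + 2 p2` the mean dosage, i.e. centred
#' allele counts.
#'
#' @param freqs numeric length-3 vector `(p0, p1, p2)` of observed genotype
#'   frequencies (must sum to 1).
#' @return Numeric length-3 vector of codes for dosages 0, 1, 2, or `NA`s
#'   (with attribute `excluded = TRUE`) for a monomorphic SNP.
#' @examples
#' noia_additive_coding(c(0.25, 0.5, 0.25)) # -1 0 1
#' @export
noia_additive_coding <- function(freqs) {
  stopifnot(length(freqs) == 3, abs(sum(freqs) - 1) < 1e-8)
  p <- freqs[2] / 2 + freqs[3] # alt allele frequency
  if (p <= 0 || p >= 1) {
    out <- rep(NA_real_, 3)
    attr(out, "excluded") <- TRUE
    return(out)
  }
  m <- freqs[2] + 2 * freqs[3]
  c(-m, 1 - m, 2 - m)
}

#' NOIA dominance coding for one SNP
#'
#' Returns the coded values assigned to dosages (0, 1, 2):
#' `(-2 p1 p2 / den, 4 p0 p2 / den, -2 p0 p1 / den)` with
#' `den = p0 + p2 - (p0 - p2)^2`. The coding has frequency-weighted mean zero
#' and is orthogonal to the additive coding under the observed frequencies.
#'
#' @param freqs numeric length-3 vector `(p0, p1, p2)`.
#' @param eps exclusion threshold for the denominator.
#' @return Numeric length-3 vector of codes, or `NA`s (with attribute
#'   `excluded = TRUE`) when the denominator is degenerate (e.g. all
#'   heterozygotes) or the SNP is monomorphic.
#' @examples
#' noia_dominance_coding(c(0.25, 0.5, 0.25)) # -0.5 0.5 -0.5
#' @export
noia_dominance_coding <- function(freqs, eps = 1e-8) {
  stopifnot(length(freqs) == 3, abs(sum(freqs) - 1) < 1e-8)
  p0 <- freqs[1]; p1 <- freqs[2]; p2 <- freqs[3]
  den <- p0 + p2 - (p0 - p2)^2
  p <- p1 / 2 + p2
  if (p <= 0 || p >= 1 || den <= eps) {
    out <- rep(NA_real_, 3)
    attr(out, "excluded") <- TRUE
    return(out)
  }
  c(-2 * p1 * p2 / den, 4 * p0 * p2 / den, -2 * p0 * p1 / den)
}

#' NOIA coding matrices for a genotype panel
#'
#' Builds the animals x SNPs additive (`W_add`) and dominance (`W_dom`)
#' coding matrices from the observed genotype frequencies of `G`.
#' Monomorphic SNPs are excluded from both matrices; SNPs whose dominance
#' denominator is degenerate are excluded from `W_dom` only (their additive
#' information is still valid).
#'
#' @param G a [genotype_matrix()].
#' @param eps degeneracy threshold passed to the dominance coding.
#' @return List with `W_add`, `W_dom`, `excluded_snps` (monomorphic, dropped
#'   from both) and `excluded_dom` (dropped from `W_dom` only).
#' @export
noia_codings <- function(G, eps = 1e-8) {
  f <- G$freqs
  p <- f[, "p1"] / 2 + f[, "p2"]
  mono <- p <= 0 | p >= 1
  den <- f[, "p0"] + f[, "p2"] - (f[, "p0"] - f[, "p2"])^2
  dom_bad <- !mono & den <= eps
  if (any(dom_bad))
    message(sum(dom_bad), " SNP(s) excluded from dominance coding (degenerate denominator)")

  dos <- G$dosages
  keep_a <- which(!mono)
  if (length(keep_a) == 0) stop("no polymorphic SNPs available for coding")
  m <- f[, "p1"] + 2 * f[, "p2"]
  W_add <- sweep(dos[, keep_a, drop = FALSE], 2, m[keep_a])

  keep_d <- which(!mono & !dom_bad)
  dd <- dos[, keep_d, drop = FALSE]
  f0 <- f[keep_d, "p0"]; f1 <- f[keep_d, "p1"]; f2 <- f[keep_d, "p2"]
  dn <- den[keep_d]
  c0 <- -2 * f1 * f2 / dn; c1 <- 4 * f0 * f2 / dn; c2 <- -2 * f0 * f1 / dn
  W_dom <- matrix(0, nrow(dd), ncol(dd), dimnames = dimnames(dd))
  for (g in 0:2) {
    cc <- switch(g + 1L, c0, c1, c2)
    W_dom <- W_dom + (dd == g) * rep(cc, each = nrow(dd))
  }
  list(W_add = W_add, W_dom = W_dom,
       excluded_snps = colnames(dos)[mono],
       excluded_dom = colnames(dos)[dom_bad])
}
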