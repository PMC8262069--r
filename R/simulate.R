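# Synthetic half-sib population generator.
#
# The simulated world mirrors a progeny-testing design: a set of sires, each
# with a paternal half-sib family; offspring receive one recombined sire
# gamete and one population haplotype from an unrelated dam. Haplotype alleles
# follow a first-order (latent Gaussian AR(1)) chain along the genome, which
# gives a single tunable adjacent-LD parameter.

# Draw n_hap haplotypes for SNPs with minor-allele frequencies p under a
# latent AR(1) chain with correlation rho. Returns n_hap x n_snps 0/1 matrix.
.sim_haplotypes <- function(n_hap, p, rho) {
  m <- length(p)
  z <- matrix(0, n_hap, m)
  z[, 1] <- stats::rnorm(n_hap)
  if (m > 1) {
    s <- sqrt(1 - rho^2)
    for (j in 2:m) z[, j] <- rho * z[, j - 1] + s * stats::rnorm(n_hap)
  }
  thr <- stats::qnorm(p)
  (z < rep(thr, each = n_hap)) + 0L
}

# One gamete per row from a 2-haplotype parent: Markov switching between the
# two parental haplotypes with per-interval switch probability r.
.sim_gametes <- function(hap1, hap2, r) {
  n <- nrow(hap1); m <- ncol(hap1)
  state <- matrix(0L, n, m)
  state[, 1] <- stats::rbinom(n, 1, 0.5)
  if (m > 1) {
    sw <- matrix(stats::rbinom(n * (m - 1), 1, r), n)
    for (j in 2:m) state[, j] <- (state[, j - 1] + sw[, j - 1]) %% 2L
  }
  hap1 * (state == 0L) + hap2 * (state == 1L)
}

#' Simulate half-sib family genotypes
#'
#' Generates biallelic SNP genotypes for paternal half-sib families. Sires
#' carry two simulated haplotypes; each offspring receives one recombined
#' sire gamete plus one independently drawn dam haplotype (or, with
#' `full_sibs = TRUE`, a gamete from a single dam per family). Haplotype
#' alleles at adjacent SNPs follow a first-order correlation chain with
#' parameter `ld_rho`; `ld_rho = 0` gives independent SNPs. Monomorphic and
#' sub-MAF SNPs are removed after simulation.
#'
#' @param n_sires number of sires (>= 1).
#' @param offspring_per_sire family size (>= 1).
#' @param n_snps number of SNPs simulated before MAF filtering.
#' @param maf_range range (low, high) within (0, 0.5] from which per-SNP
#'   population minor allele frequencies are drawn uniformly.
#' @param ld_rho first-order haplotype correlation parameter in \[0, 1).
#' @param maf_filter post-hoc MAF threshold; SNPs with observed MAF below this
#'   are dropped (QC-style pruning, default 0.05).
#' @param recomb_rate per-adjacent-SNP-interval switch probability when
#'   forming parental gametes.
#' @param full_sibs if TRUE each family has a single dam, making families
#'   full-sib; default FALSE (paternal half-sibs).
#' @param n_chrom number of chromosomes the SNPs are spread over (equal
#'   blocks, genome order).
#' @param seed integer seed; identical seeds give bit-identical output.
#' @return A [genotype_matrix()] of offspring with positions and sire IDs.
#' @examples
#' G <- simulate_genotypes(5, 10, 200, seed = 1)
#' dim(G)
#' @export
simulate_genotypes <- function(n_sires, offspring_per_sire, n_snps,
                               maf_range = c(0.05, 0.5), ld_rho = 0.9,
                               maf_filter = 0.05, recomb_rate = 0.01,
                               full_sibs = FALSE, n_chrom = 1, seed = NULL) {
  stopifnot(n_sires >= 1, offspring_per_sire >= 1, n_snps >= 2)
  if (length(maf_range) != 2 || maf_range[1] >= maf_range[2])
    stop("degenerate maf_range: low must be < high")
  if (maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must lie within (0, 0.5]")
  if (ld_rho < 0 || ld_rho >= 1) stop("ld_rho must be in [0, 1)")
  if (!is.null(seed)) set.seed(seed)

  p <- stats::runif(n_snps, maf_range[1], maf_range[2])
  n_off <- n_sires * offspring_per_sire

  sire_h1 <- .sim_haplotypes(n_sires, p, ld_rho)
  sire_h2 <- .sim_haplotypes(n_sires, p, ld_rho)
  fam <- rep(seq_len(n_sires), each = offspring_per_sire)
  pat <- .sim_gametes(sire_h1[fam, , drop = FALSE],
                      sire_h2[fam, , drop = FALSE], recomb_rate)
  if (full_sibs) {
    dam_h1 <- .sim_haplotypes(n_sires, p, ld_rho)
    dam_h2 <- .sim_haplotypes(n_sires, p, ld_rho)
    mat <- .sim_gametes(dam_h1[fam, , drop = FALSE],
                        dam_h2[fam, , drop = FALSE], recomb_rate)
  } else {
    mat <- .sim_haplotypes(n_off, p, ld_rho)
  }
  dos <- pat + mat
  rownames(dos) <- sprintf("ind%04d", seq_len(n_off))
  colnames(dos) <- sprintf("snp%05d", seq_len(n_snps))

  chrom <- sort(rep_len(seq_len(n_chrom), n_snps))
  pos <- data.frame(chrom = chrom,
                    bp = unlist(lapply(split(seq_len(n_snps), chrom),
                                       function(i) seq_along(i) * 1e5)))
  G <- genotype_matrix(dos, positions = pos,
                       sires = sprintf("sire%03d", fam))
  keep <- maf(G) >= maf_filter & maf(G) > 0
  if (!any(keep))
    stop("all SNPs removed by MAF filtering at threshold ", maf_filter)
  subset_genotypes(G, snps = which(keep))
}

#' Simulate true genetic effects
#'
#' Draws SNP-level additive and dominance effects and SNP-pair
#' additive-by-additive (epistatic) effects, maps them to per-animal genetic
#' values, and rescales each component so that its empirical variance over
#' animals equals the requested fraction of the target phenotypic variance
#' exactly. Per-animal values are exact linear combinations of the stored
#' (rescaled) effects with the stored codings: centred allele counts for the
#' additive part, heterozygote indicators for the dominance part, and products
#' of centred allele counts for the epistatic pairs.
#'
#' Directional dominance is induced by drawing dominance effects with a
#' non-zero mean (`directional_shift`, in units of the dominance-effect SD
#' before rescaling); the mean of the rescaled dominance effects is recorded.
#'
#' @param G a [genotype_matrix()].
#' @param variance_fractions named numeric with entries `A`, `D`, `AA` giving
#'   target fractions of the phenotypic variance; non-negative, sum < 1.
#' @param n_epistatic_pairs number of unordered SNP pairs carrying
#'   additive-by-additive effects (default `2 * n_snps`).
#' @param directional_shift mean of dominance effects before rescaling.
#' @param target_var target phenotypic variance the fractions refer to.
#' @param epistasis_mode `"pairs"` (default) simulates explicit SNP-pair
#'   effects so downstream effect-prediction has a kernel-independent ground
#'   truth; `"kernel"` draws the epistatic values from MVN(0, AA kernel).
#' @param aa_kernel optional precomputed AA `grm` for `"kernel"` mode
#'   (avoids rebuilding it when the caller already has it).
#' @param seed integer seed.
#' @return A list of class `true_effects` with SNP(-pair) effects, per-animal
#'   values `u_A`, `u_D`, `u_AA`, the applied scale factors, and
#'   `directional_dominance_shift`.
#' @export
simulate_effects <- function(G, variance_fractions = c(A = 0.45, D = 0.05, AA = 0.15),
                             n_epistatic_pairs = NULL, directional_shift = 0,
                             target_var = 1, epistasis_mode = c("pairs", "kernel"),
                             aa_kernel = NULL, seed = NULL) {
  epistasis_mode <- match.arg(epistasis_mode)
  vf <- c(A = 0, D = 0, AA = 0)
  vf[names(variance_fractions)] <- variance_fractions
  if (any(vf < 0) || sum(vf) >= 1)
    stop("variance fractions must be non-negative and sum to < 1")
  if (!is.null(seed)) set.seed(seed)
  dos <- G$dosages
  n <- nrow(dos); m <- ncol(dos)
  if (is.null(n_epistatic_pairs)) n_epistatic_pairs <- 2L * m
  max_pairs <- m * (m - 1) / 2
  if (n_epistatic_pairs > max_pairs)
    stop("n_epistatic_pairs (", n_epistatic_pairs,
         ") exceeds available unordered pairs (", max_pairs, ")")

  wa <- sweep(dos, 2, colMeans(dos)) # centred allele counts
  hz <- (dos == 1L) + 0

  rescale <- function(u, frac) {
    if (frac == 0) return(list(u = rep(0, n), s = 0))
    v <- stats::var(u)
    if (v <= 0) stop("component has zero empirical variance; cannot rescale")
    s <- sqrt(frac * target_var / v)
    list(u = u * s, s = s)
  }

  a <- stats::rnorm(m)
  rA <- rescale(drop(wa %*% a), vf["A"])
  a <- if (vf["A"] > 0) a * rA$s else rep(0, m)

  d <- stats::rnorm(m, mean = directional_shift)
  rD <- rescale(drop(hz %*% d), vf["D"])
  d <- if (vf["D"] > 0) d * rD$s else rep(0, m)

  pairs <- NULL
  e <- numeric(0)
  if (epistasis_mode == "pairs") {
    if (n_epistatic_pairs > 0) {
      # sample unordered pairs without duplicates
      idx <- sample.int(max_pairs, n_epistatic_pairs)
      # map linear index over j<k to (j,k)
      k <- ceiling((1 + sqrt(1 + 8 * idx)) / 2)
      j <- idx - (k - 1) * (k - 2) / 2
      pairs <- cbind(j = as.integer(j), k = as.integer(k))
      e <- stats::rnorm(n_epistatic_pairs)
      uAA <- drop((wa[, pairs[, "j"], drop = FALSE] *
                   wa[, pairs[, "k"], drop = FALSE]) %*% e)
    } else uAA <- rep(0, n)
    if (vf["AA"] > 0 && n_epistatic_pairs == 0)
      stop("AA fraction > 0 requires n_epistatic_pairs > 0")
    rAA <- rescale(uAA, vf["AA"])
    e <- if (vf["AA"] > 0) e * rAA$s else numeric(0)
    if (vf["AA"] == 0) pairs <- NULL
  } else {
    if (vf["AA"] > 0) {
      if (is.null(aa_kernel)) {
        W <- noia_codings(G)$W_add
        WW <- tcrossprod(W)
        aa_kernel <- scale_trace(WW * WW)
      }
      L <- tryCatch(chol(unclass(aa_kernel) + diag(1e-8, n)),
                    error = function(e) NULL)
      if (is.null(L)) stop("AA kernel not factorizable for kernel-mode draw")
      rAA <- rescale(drop(crossprod(L, stats::rnorm(n))), vf["AA"])
    } else rAA <- list(u = rep(0, n), s = 0)
  }

  structure(list(
    additive_snp_effects = a,
    dominance_snp_effects = d,
    epistatic_pairs = if (!is.null(pairs))
      data.frame(snp_j = snp_ids(G)[pairs[, "j"]],
                 snp_k = snp_ids(G)[pairs[, "k"]],
                 j = pairs[, "j"], k = pairs[, "k"], effect = e) else NULL,
    directional_dominance_shift = if (vf["D"] > 0) mean(d) else 0,
    u_A = stats::setNames(rA$u, animal_ids(G)),
    u_D = stats::setNames(rD$u, animal_ids(G)),
    u_AA = stats::setNames(rAA$u, animal_ids(G)),
    variance_fractions = vf,
    target_var = target_var,
    scale_factors = c(A = rA$s, D = rD$s, AA = rAA$s),
    epistasis_mode = epistasis_mode
  ), class = "true_effects")
}

#' Simulate phenotypes with fixed effects
#'
#' Builds a trait as intercept + categorical factor effects + continuous
#' covariate effects + the true genetic values + i.i.d. normal residual at
#' the requested variance fraction. Factor levels are assigned in a balanced
#' way so every level has at least two animals; level effects are drawn once
#' per level. The heterozygosity covariate is recomputed from the genotypes
#' (it is reported, not added as an explicit effect: any phenotype-
#' heterozygosity slope arises from directional dominance in `effects`).
#'
#' @param G a [genotype_matrix()].
#' @param effects a `true_effects` object from [simulate_effects()].
#' @param factor_spec named integer vector: number of levels per categorical
#'   factor (defaults emulate sex/farm/slaughter-date structure).
#' @param covariate_spec named list of `c(mean, sd)` for continuous
#'   covariates simulated independently of genotype (default: age in months).
#' @param residual_fraction residual variance as a fraction of the target
#'   phenotypic variance; default `1 - sum(variance_fractions)`.
#' @param factor_sd SD of factor level effects, as a fraction of the target
#'   phenotypic SD (kept small so realized variance fractions stay near
#'   their targets).
#' @param covariate_beta effect per SD of each simulated covariate, on the
#'   same fractional scale.
#' @param seed integer seed.
#' @return A data.frame (class `phenotype_table`): `animal_id`, `trait`,
#'   factor columns, `age_months` (and any other covariates), `het_percent`,
#'   `phenotyped`.
#' @export
simulate_phenotypes <- function(G, effects,
                                factor_spec = c(sex = 2, farm = 20, slaughter_date = 24),
                                covariate_spec = list(age_months = c(mean = 29, sd = 1.4)),
                                residual_fraction = NULL,
                                factor_sd = 0.1, covariate_beta = 0.05,
                                seed = NULL) {
  n <- nrow(G$dosages)
  if (is.null(residual_fraction))
    residual_fraction <- 1 - sum(effects$variance_fractions)
  if (residual_fraction < 0) stop("residual_fraction must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  tv <- effects$target_var

  tab <- data.frame(animal_id = animal_ids(G), stringsAsFactors = FALSE)
  y <- rep(0, n)
  for (f in names(factor_spec)) {
    k <- factor_spec[[f]]
    if (k > n) stop("factor '", f, "' has more levels (", k,
                    ") than animals (", n, ")")
    if (2 * k > n) stop("factor '", f, "' cannot give every level >= 2 animals")
    lv <- sample(rep_len(seq_len(k), n))
    eff <- stats::rnorm(k, sd = factor_sd * sqrt(tv))
    tab[[f]] <- factor(sprintf("%s%02d", f, lv))
    y <- y + eff[lv]
  }
  for (cv in names(covariate_spec)) {
    sp <- covariate_spec[[cv]]
    x <- stats::rnorm(n, sp[["mean"]], sp[["sd"]])
    tab[[cv]] <- x
    y <- y + covariate_beta * sqrt(tv) * (x - sp[["mean"]]) / sp[["sd"]]
  }
  tab$het_percent <- het_percent(G)
  resid <- stats::rnorm(n, sd = sqrt(residual_fraction * tv))
  tab$trait <- y + effects$u_A + effects$u_D + effects$u_AA + resid
  tab$phenotyped <- TRUE
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}
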