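# Model suite: the six single-trait animal models and their fixed-effect
# design, including the directional-dominance (heterozygosity) covariate.

.model_table <- list(
  A    = "A",
  D    = c("A", "D"),
  AA   = c("A", "D", "AA"),
  AA2  = c("A", "AA"),
  AD   = c("A", "D", "AA", "AD"),
  Full = c("A", "D", "AA", "AD", "DD")
)

#' Kernels required by a named model
#'
#' Model A: additive only. D adds dominance; AA adds additive-by-additive;
#' AD adds additive-by-dominance; Full adds dominance-by-dominance. AA2 is
#' the additive + additive-by-additive model without the dominance component.
#'
#' @param name one of `"A"`, `"D"`, `"AA"`, `"AA2"`, `"AD"`, `"Full"`.
#' @return Character vector of kernel names.
#' @export
model_kernels <- function(name) {
  name <- match.arg(name, names(.model_table))
  .model_table[[name]]
}

#' Build the fixed-effect design matrix
#'
#' One-hot encodes categorical factors with the reference level dropped,
#' merging factor levels with fewer than `min_level_size` animals into a
#' single fallback level (the study-style grouping of small farms), and
#' standardizes continuous covariates to mean 0, SD 1, recording the
#' constants for back-transformation.
#'
#' @param pheno a `phenotype_table` (or data.frame with the named columns).
#' @param factors character vector of categorical column names.
#' @param covariates character vector of continuous column names (typically
#'   including `het_percent`, the directional-dominance covariate).
#' @param min_level_size factor levels with fewer animals than this are
#'   merged into `"other"`.
#' @return List of class `design_matrix`: `X`, `covariate_center`,
#'   `covariate_scale`, `factor_levels` (post-merge), `merged` (levels
#'   merged per factor).
#' @export
build_design <- function(pheno, factors = c("sex", "farm", "slaughter_date"),
                         covariates = c("age_months", "het_percent"),
                         min_level_size = 10) {
  missing_cols <- setdiff(c(factors, covariates), names(pheno))
  if (length(missing_cols))
    stop("columns not found in phenotype table: ",
         paste(missing_cols, collapse = ", "))
  df <- data.frame(row.names = seq_len(nrow(pheno)))
  merged <- list(); flevels <- list()
  for (f in factors) {
    x <- as.character(pheno[[f]])
    tab <- table(x)
    small <- names(tab)[tab < min_level_size]
    if (length(small) > 0 && length(small) < length(tab)) {
      x[x %in% small] <- "other"
      merged[[f]] <- small
    }
    df[[f]] <- factor(x)
    flevels[[f]] <- levels(df[[f]])
  }
  ctr <- scl <- stats::setNames(numeric(length(covariates)), covariates)
  for (cv in covariates) {
    x <- as.numeric(pheno[[cv]])
    ctr[cv] <- mean(x)
    scl[cv] <- stats::sd(x)
    if (scl[cv] <= 0) stop("covariate '", cv, "' has zero variance")
    df[[cv]] <- (x - ctr[cv]) / scl[cv]
  }
  X <- stats::model.matrix(~., data = df)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    bad <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop("rank-deficient design; aliased columns: ", paste(bad, collapse = ", "))
  }
  structure(list(X = X, covariate_center = ctr, covariate_scale = scl,
                 factor_levels = flevels, merged = merged,
                 factors = factors, covariates = covariates),
            class = "design_matrix")
}

#' Fit one of the named models
#'
#' Builds (or reuses) the fixed-effect design and delegates to [fit_reml()]
#' with the kernel list prescribed by the model name.
#'
#' @param name model name; see [model_kernels()].
#' @param pheno a `phenotype_table` with a `trait` column (or column named by
#'   `trait`).
#' @param kernels `kernel_set` containing at least the required kernels.
#' @param trait name of the response column.
#' @param design optional prebuilt [build_design()] result; built with
#'   defaults otherwise.
#' @param obs record-to-animal mapping passed to [fit_reml()]; defaults to
#'   `pheno$animal_id`.
#' @param ... further arguments to [fit_reml()].
#' @return An `epigp_fit` with the design metadata attached as
#'   `$design_meta` and the model name as `$model`.
#' @export
fit_model <- function(name, pheno, kernels, trait = "trait", design = NULL,
                      obs = NULL, ...) {
  need <- model_kernels(name)
  absent <- setdiff(need, names(kernels))
  if (length(absent))
    stop("model ", name, " requires missing kernel(s): ",
         paste(absent, collapse = ", "))
  if (is.null(design)) design <- build_design(pheno)
  if (is.null(obs)) obs <- as.character(pheno$animal_id)
  fit <- fit_reml(y = as.numeric(pheno[[trait]]), X = design$X,
                  kernels = kernels[need], obs = obs, ...)
  fit$design_meta <- design
  fit$model <- name
  fit
}

#' Directional-dominance slope from a fitted model
#'
#' The effect of the proportion (%) of heterozygous SNPs on the phenotype.
#' Because covariates are standardized before fitting, the raw coefficient is
#' per SD of heterozygosity; it is back-transformed to the
#' per-percentage-point scale by dividing by the SD of `het_percent`, SE
#' scaled identically. Both scales are returned.
#'
#' @param fit an `epigp_fit` from [fit_model()] whose design included the
#'   heterozygosity covariate.
#' @param covariate name of the heterozygosity covariate.
#' @return List with `slope_per_percent`, `se_per_percent`,
#'   `slope_standardized`, `se_standardized`, `sd_het`.
#' @export
directional_dominance_slope <- function(fit, covariate = "het_percent") {
  meta <- fit$design_meta
  if (is.null(meta) || !(covariate %in% names(meta$covariate_scale)))
    stop("heterozygosity covariate '", covariate, "' absent from the fitted design")
  b <- fit$beta[[covariate]]
  se <- fit$beta_se[[covariate]]
  sdh <- meta$covariate_scale[[covariate]]
  list(slope_per_percent = b / sdh, se_per_percent = se / sdh,
       slope_standardized = b, se_standardized = se, sd_het = sdh)
}

#' Phenotypes adjusted for estimated fixed effects
#'
#' `y_adj = y - X beta_hat`; random (genetic) effects are deliberately NOT
#' removed. These adjusted phenotypes are the comparison target for
#' cross-validated predictions and the response for the subsampling
#' experiment.
#'
#' @param fit an `epigp_fit`.
#' @return Numeric vector of adjusted phenotypes over the fitted records,
#'   named by animal ID when available.
#' @export
adjusted_phenotypes <- function(fit) {
  stopifnot(inherits(fit, "epigp_fit"))
  ya <- fit$y - drop(fit$X %*% fit$beta)
  if (!is.null(fit$animal_ids)) names(ya) <- fit$animal_ids[fit$obs]
  ya
}
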