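# Stratified cross-validation of predictive accuracy and dispersion bias,
# plus the principal-component population-structure check.

#' Build stratified cross-validation folds
#'
#' Randomly partitions the phenotyped animals into `n_folds` folds under the
#' constraint that every level of every stratification factor is represented
#' in every training set (i.e. no level is concentrated in a single fold).
#' Achieved by random assignment followed by deterministic repair passes.
#'
#' @param pheno a `phenotype_table` (or data.frame with the factor columns).
#' @param n_folds number of folds (default 10).
#' @param strat_factors character vector of factor columns to protect; NULL
#'   for unconstrained folds.
#' @param seed integer seed.
#' @return Integer vector of fold labels (1..n_folds), one per row of
#'   `pheno`.
#' @export
make_cv_folds <- function(pheno, n_folds = 10, strat_factors = NULL, seed = NULL) {
  n <- nrow(pheno)
  stopifnot(n_folds >= 2, n >= n_folds)
  if (!is.null(seed)) set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  if (is.null(strat_factors)) return(fold)
  for (f in strat_factors) {
    tab <- table(as.character(pheno[[f]]))
    if (any(tab < 2))
      stop("stratification factor '", f, "' has a level with < 2 animals: ",
           names(tab)[which(tab < 2)[1]], " (merge levels upstream)")
  }
  for (pass in 1:100) {
    ok <- TRUE
    for (f in strat_factors) {
      lv <- split(seq_len(n), as.character(pheno[[f]]))
      for (idx in lv) {
        fl <- fold[idx]
        if (length(unique(fl)) == 1L) {
          # all animals of this level sit in one fold: move one elsewhere
          mv <- idx[sample.int(length(idx), 1)]
          other <- setdiff(seq_len(n_folds), fl[1])
          fold[mv] <- other[sample.int(length(other), 1)]
          ok <- FALSE
        }
      }
    }
    if (ok) return(fold)
  }
  stop("could not satisfy stratification constraints in 100 repair passes")
}

#' Cross-validated accuracy and bias of a genomic prediction model
#'
#' For each fold, the model is refitted on the training animals only (test
#' phenotypes masked; test animals' kernel rows still participate, standard
#' GBLUP extrapolation) and per-component genetic values are predicted for
#' the test animals. Predictive accuracy is the Pearson correlation between
#' phenotypes adjusted for fixed effects (estimated from the full data with
#' the same model) and predicted total genotypic values, pooled over all test
#' predictions; dispersion bias is the slope of the regression of predictions
#' on adjusted phenotypes. Metrics based on the additive component alone are
#' also reported.
#'
#' @param pheno a `phenotype_table` with a `trait` column.
#' @param kernels `kernel_set` over the phenotyped animals (at least).
#' @param model model name, see [model_kernels()].
#' @param trait response column name.
#' @param n_folds number of folds (default 10).
#' @param strat_factors factor columns protected in every training set
#'   (default farm and slaughter date when present).
#' @param design optional prebuilt design; defaults to [build_design()] with
#'   its defaults.
#' @param adjust `"full"` (default) adjusts phenotypes with fixed effects
#'   from the full-data fit; `"fold"` re-estimates fixed effects within each
#'   training fold (no information leak).
#' @param seed integer seed for fold construction.
#' @param ... passed to [fit_reml()].
#' @return An object of class `cv_result`: pooled `accuracy`, `bias`,
#'   `accuracy_additive`, `bias_additive`, `per_fold` data.frame,
#'   `predictions` (per-animal table), `folds`, `model`, `full_fit`.
#' @export
run_cv <- function(pheno, kernels, model = "AA2", trait = "trait",
                   n_folds = 10, strat_factors = NULL, design = NULL,
                   adjust = c("full", "fold"), seed = NULL, ...) {
  adjust <- match.arg(adjust)
  if (is.null(strat_factors))
    strat_factors <- intersect(c("farm", "slaughter_date"), names(pheno))
  if (is.null(design)) design <- build_design(pheno)
  full_fit <- fit_model(model, pheno, kernels, trait = trait, design = design, ...)
  y_adj_full <- adjusted_phenotypes(full_fit)
  folds <- make_cv_folds(pheno, n_folds, strat_factors, seed = seed)

  ids <- as.character(pheno$animal_id)
  gen_kernels <- model_kernels(model)
  pred <- data.frame(animal_id = ids, fold = folds,
                     y_adj = as.numeric(y_adj_full),
                     total = NA_real_, additive = NA_real_,
                     stringsAsFactors = FALSE)
  converged <- logical(n_folds)
  for (fd in seq_len(n_folds)) {
    tr <- which(folds != fd); te <- which(folds == fd)
    # warm start at the full-data estimates: fold optima are close, and this
    # saves most of the iteration cost
    fit_f <- suppressWarnings(
      fit_model(model, pheno[tr, , drop = FALSE], kernels, trait = trait,
                design = local({
                  d <- design; d$X <- design$X[tr, , drop = FALSE]; d
                }), obs = ids[tr], init = full_fit$varcomps, ...))
    converged[fd] <- fit_f$converged
    if (adjust == "fold") {
      Xte <- design$X[te, , drop = FALSE]
      pred$y_adj[te] <- as.numeric(pheno[[trait]][te]) - drop(Xte %*% fit_f$beta)
    }
    pp <- predict_unphenotyped(fit_f, kernels, ids[te])
    pred$total[te] <- pp$total
    pred$additive[te] <- pp$A
  }
  if (!all(converged))
    warning(sum(!converged), " fold fit(s) did not converge; pooled metrics use converged folds only")
  use <- pred$fold %in% which(converged)

  metric <- function(p, ya) {
    if (stats::sd(p) == 0 || stats::sd(ya) == 0) {
      warning("degenerate predictions or adjusted phenotypes; accuracy undefined")
      return(c(r = NA_real_, b = NA_real_))
    }
    c(r = stats::cor(ya, p),
      b = unname(stats::coef(stats::lm(p ~ ya))[2]))
  }
  mt <- metric(pred$total[use], pred$y_adj[use])
  ma <- metric(pred$additive[use], pred$y_adj[use])
  per_fold <- do.call(rbind, lapply(which(converged), function(fd) {
    i <- pred$fold == fd
    m <- metric(pred$total[i], pred$y_adj[i])
    data.frame(fold = fd, accuracy = m["r"], bias = m["b"], row.names = NULL)
  }))
  structure(list(accuracy = unname(mt["r"]), bias = unname(mt["b"]),
                 accuracy_additive = unname(ma["r"]),
                 bias_additive = unname(ma["b"]),
                 per_fold = per_fold, predictions = pred, folds = folds,
                 model = model, full_fit = full_fit,
                 converged_folds = converged),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("10-fold CV (%s): accuracy r = %.3f, bias b = %.3f\n",
              x$model, x$accuracy, x$bias))
  cat(sprintf("  additive component only: r = %.3f, b = %.3f\n",
              x$accuracy_additive, x$bias_additive))
  invisible(x)
}

#' Population-structure check by eigendecomposition of the additive kernel
#'
#' Principal components of the additive relationship matrix: eigenvalues,
#' PC scores (eigenvectors scaled by the square roots of the eigenvalues)
#' and cumulative variance proportions over the positive spectrum.
#'
#' @param A additive `grm` (symmetric).
#' @param n_components number of components to return scores for.
#' @return List with `values`, `scores` (n x n_components), `cumvar`.
#' @export
pca_structure <- function(A, n_components = 10) {
  if (max(abs(A - t(A))) > 1e-8) stop("kernel is not symmetric")
  eg <- eigen(A, symmetric = TRUE)
  pos <- pmax(eg$values, 0)
  k <- min(n_components, ncol(A))
  scores <- eg$vectors[, seq_len(k), drop = FALSE] %*% diag(sqrt(pos[seq_len(k)]), k)
  rownames(scores) <- rownames(A)
  colnames(scores) <- paste0("PC", seq_len(k))
  list(values = eg$values, scores = scores, cumvar = cumsum(pos) / sum(pos))
}
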