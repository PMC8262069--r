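# Multi-kernel REML engine.
#
# Model: y = X b + sum_k u_k[obs] + e,  u_k ~ MVN(0, K_k s2_k),
#        e ~ MVN(0, I s2_E), with K_k dense trace-scaled kernels over the
# full animal index and `obs` mapping phenotype records to animals. All
# computations are on the observed scale, V = sum_k s2_k K_k[obs,obs] + s2_E I.
#
# Algorithm: average-information (AI) REML; an AI step is accepted only if it
# is feasible (after step-halving to the non-negativity boundary) and does not
# decrease the restricted log-likelihood; otherwise an EM step (monotone, and
# positivity-preserving) is taken. Standard errors come from the inverse AI
# matrix at convergence; components pinned at the zero boundary get NA.

# Cholesky with diagonal jitter fallback.
.chol_safe <- function(V) {
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) {
    jit <- 1e-8 * mean(diag(V))
    warning("V factorization failed; adding jitter ", signif(jit, 3))
    ch <- chol(V + diag(jit, nrow(V)))
  }
  ch
}

# Core per-iteration quantities given component variances.
# Ko: list of observed-scale kernel matrices (residual handled implicitly).
.reml_eval <- function(y, X, Ko, theta, want_derivs = TRUE) {
  n <- length(y); p <- ncol(X); K <- length(Ko)
  V <- diag(theta[K + 1], n)
  for (k in seq_len(K)) V <- V + theta[k] * Ko[[k]]
  ch <- .chol_safe(V)
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  chx <- chol(XtViX)
  C <- chol2inv(chx) # (X'V^-1 X)^-1
  beta <- C %*% crossprod(ViX, y)
  r <- y - X %*% beta
  Py <- Vi %*% r
  yPy <- sum(r * Py)
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) + yPy +
                (n - p) * log(2 * pi))
  out <- list(loglik = ll, beta = drop(beta), beta_cov = C, Py = drop(Py),
              Vi = Vi, ViX = ViX)
  if (!want_derivs) return(out)

  trPK <- grad <- numeric(K + 1)
  v <- vector("list", K + 1) # K_k %*% Py
  for (k in seq_len(K)) {
    M <- crossprod(ViX, Ko[[k]] %*% ViX)
    trPK[k] <- sum(Vi * Ko[[k]]) - sum(C * M)
    v[[k]] <- drop(Ko[[k]] %*% Py)
  }
  trPK[K + 1] <- sum(diag(Vi)) - sum(C * crossprod(ViX))
  v[[K + 1]] <- out$Py
  q <- vapply(v, function(vk) sum(out$Py * vk), numeric(1))
  grad <- -0.5 * (trPK - q)
  # average information matrix: AI_ij = 0.5 * v_i' P v_j
  Pv <- lapply(v, function(vk)
    drop(Vi %*% vk - ViX %*% (C %*% crossprod(ViX, vk))))
  AI <- matrix(0, K + 1, K + 1)
  for (i in seq_len(K + 1)) for (j in i:(K + 1))
    AI[i, j] <- AI[j, i] <- 0.5 * sum(v[[i]] * Pv[[j]])
  c(out, list(trPK = trPK, qform = q, grad = grad, AI = AI))
}

#' Restricted log-likelihood of a multi-kernel mixed model
#'
#' Evaluates the REML log-likelihood of `y` given
#' `V = sum_k sigmas[k] K_k + sigma_E I`, with fixed effects profiled out.
#' Mainly useful for grid-search oracles and diagnostics; [fit_reml()]
#' maximizes this function.
#'
#' @param y numeric response vector (phenotyped records).
#' @param X fixed-effect design matrix (full column rank).
#' @param kernels list of observed-scale covariance matrices, one per genetic
#'   component (may be empty).
#' @param sigmas numeric vector of variance components, kernels first,
#'   residual last; residual must be > 0.
#' @return The restricted log-likelihood (includes the -((n-p)/2) log(2 pi)
#'   constant).
#' @export
restricted_loglik <- function(y, X, kernels, sigmas) {
  X <- as.matrix(X)
  stopifnot(length(sigmas) == length(kernels) + 1, all(sigmas >= 0),
            sigmas[length(sigmas)] > 0)
  Ko <- lapply(kernels, unclass)
  .reml_eval(y, X, Ko, sigmas, want_derivs = FALSE)$loglik
}

#' Fit a multi-kernel mixed model by AI-REML
#'
#' Estimates variance components for a single-trait animal model with an
#' arbitrary set of genomic kernels, by average-information REML with
#' monotone EM fallback and non-negativity enforced by step halving to the
#' boundary. Returns BLUPs of every genetic component for all animals in the
#' kernels (phenotyped or not), standard errors from the inverse AI matrix,
#' the restricted log-likelihood and AIC.
#'
#' @param y numeric response over phenotyped records.
#' @param X fixed-effect design matrix (defaults to an intercept).
#' @param kernels `kernel_set` or named list of `grm` kernels over the full
#'   animal index (all sharing one animal ordering).
#' @param obs indices or animal IDs mapping each record to its animal row in
#'   the kernels; default assumes one record per kernel row, in order.
#' @param init optional starting values (kernels first, residual last);
#'   default splits the phenotypic variance equally across all components.
#' @param max_iter maximum number of iterations.
#' @param tol_loglik convergence: relative change in log-likelihood.
#' @param tol_par convergence: maximum relative parameter change.
#' @param verbose print per-iteration progress.
#' @return An object of class `epigp_fit`: `varcomps`, `se`, `beta`,
#'   `beta_se`, `blups` (named list over all animals), `residuals`,
#'   `loglik`, `aic`, `ai` (AI matrix), `ai_cov` (its inverse),
#'   `converged`, `iterations`, `grad_norm`, `boundary` flags, plus the
#'   inputs needed for prediction and adjustment.
#' @export
fit_reml <- function(y, X = NULL, kernels = list(), obs = NULL, init = NULL,
                     max_iter = 200, tol_loglik = 1e-8, tol_par = 1e-6,
                     verbose = FALSE) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  stopifnot(nrow(X) == n)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design X is rank deficient")
  K <- length(kernels)
  knames <- if (K) names(kernels) else character(0)
  if (K && (is.null(knames) || any(knames == "")))
    stop("kernels must be named")

  all_ids <- if (K) rownames(kernels[[1]]) else NULL
  n_all <- if (K) nrow(kernels[[1]]) else n
  if (is.null(obs)) {
    if (K && n_all != n)
      stop("length(y) != kernel dimension; supply `obs` to map records to animals")
    obs <- seq_len(n)
  } else if (is.character(obs)) {
    if (is.null(all_ids)) stop("kernels carry no animal IDs; use integer obs")
    obs <- match(obs, all_ids)
    if (anyNA(obs)) stop("unknown animal ID in obs")
  }
  stopifnot(length(obs) == n)

  Ko <- lapply(kernels, function(Kk) unclass(Kk)[obs, obs, drop = FALSE])
  if (n <= ncol(X) + K)
    warning("few records relative to fixed effects + kernels; estimates may be unidentifiable")

  vp <- stats::var(stats::lm.fit(X, y)$residuals) * (n - 1) / max(1, n - ncol(X))
  theta <- if (!is.null(init)) as.numeric(init) else rep(vp / (K + 1), K + 1)
  stopifnot(length(theta) == K + 1)
  lower_resid <- 1e-8 * vp

  ev <- .reml_eval(y, X, Ko, theta)
  ll <- ev$loglik
  converged <- FALSE
  iter <- 0
  # active-set AI direction with Levenberg-Marquardt damping: components
  # pushed below zero are pinned at the boundary (their delta drives them to
  # exactly 0) and the damped AI system is re-solved for the free components
  ai_direction <- function(theta, grad, AI, lambda = 0) {
    Kp1 <- K + 1
    fixed <- c(theta[seq_len(K)] <= 0 & grad[seq_len(K)] < 0, FALSE)
    for (pass in seq_len(Kp1)) {
      free <- which(!fixed)
      if (length(free) == 0) return(NULL)
      delta <- numeric(Kp1)
      Af <- AI[free, free, drop = FALSE]
      damp <- (lambda + 1e-10) * pmax(diag(Af), 1e-12 * mean(diag(Af)))
      sol <- tryCatch(solve(Af + diag(damp, length(free)), grad[free]),
                      error = function(e) NULL)
      if (is.null(sol)) return(NULL)
      delta[free] <- sol
      delta[fixed] <- -theta[fixed] # pinned components slide to the boundary
      neg <- which(!fixed[seq_len(K)] & theta[seq_len(K)] + delta[seq_len(K)] < 0)
      if (length(neg) == 0) return(delta)
      fixed[neg] <- TRUE
    }
    NULL
  }

  lambda <- 0
  for (iter in seq_len(max_iter)) {
    cand <- NULL
    lam <- lambda
    for (try in 1:8) {
      delta <- ai_direction(theta, ev$grad, ev$AI, lam)
      if (is.null(delta)) break
      trial <- theta + delta
      trial[seq_len(K)] <- pmax(trial[seq_len(K)], 0)
      trial[K + 1] <- max(trial[K + 1], lower_resid)
      ll_trial <- .reml_eval(y, X, Ko, trial, want_derivs = FALSE)$loglik
      if (is.finite(ll_trial) && ll_trial >= ll - 1e-8) {
        cand <- trial
        lambda <- lam / 4 # relax damping after a success
        break
      }
      lam <- if (lam == 0) 1e-3 else lam * 10 # dampen harder and retry
    }
    if (is.null(cand)) {
      # monotone EM step: s2_new = s2 + s2^2 (y'P K P y - tr(P K)) / n
      cand <- theta + theta^2 * (ev$qform - ev$trPK) / n
      cand[K + 1] <- max(cand[K + 1], lower_resid)
    }
    # snap kernel components that have decayed to numerical zero onto the
    # boundary, otherwise they shrink forever without triggering convergence
    snap <- seq_len(K)[cand[seq_len(K)] > 0 & cand[seq_len(K)] < 1e-6 * vp]
    cand[snap] <- 0
    ev_new <- .reml_eval(y, X, Ko, cand)
    dll <- ev_new$loglik - ll
    dpar <- max(abs(cand - theta) / pmax(abs(theta), 1e-12 + vp * 1e-6))
    theta <- cand; ev <- ev_new; ll <- ev$loglik
    if (verbose)
      message(sprintf("iter %3d  logL %.6f  theta: %s", iter, ll,
                      paste(signif(theta, 4), collapse = " ")))
    if (abs(dll) < tol_loglik * max(1, abs(ll)) && dpar < tol_par) {
      converged <- TRUE
      break
    }
  }

  grad_norm <- sqrt(sum(ev$grad^2))
  boundary <- c(theta[seq_len(K)] < 1e-6 * sum(theta), FALSE)
  ai_cov <- tryCatch(solve(ev$AI), error = function(e) matrix(NA_real_, K + 1, K + 1))
  se <- sqrt(pmax(diag(ai_cov), 0))
  se[boundary] <- NA_real_
  comp_names <- c(knames, "residual")

  # BLUPs over ALL animals: U_k = s2_k K_k[., obs] Py
  blups <- list()
  for (k in seq_len(K)) {
    Ufull <- theta[k] * drop(unclass(kernels[[k]])[, obs, drop = FALSE] %*% ev$Py)
    names(Ufull) <- all_ids
    blups[[knames[k]]] <- Ufull
  }
  fitted_g <- if (K) Reduce(`+`, lapply(blups, function(u) u[obs])) else rep(0, n)
  resid <- y - drop(X %*% ev$beta) - fitted_g

  vc <- stats::setNames(theta, comp_names)
  fit <- structure(list(
    varcomps = vc,
    se = stats::setNames(se, comp_names),
    beta = stats::setNames(ev$beta, colnames(X)),
    beta_se = stats::setNames(sqrt(diag(ev$beta_cov)), colnames(X)),
    blups = blups,
    residuals = resid,
    loglik = ll,
    aic = -2 * ll + 2 * (K + 1),
    ai = ev$AI, ai_cov = ai_cov,
    converged = converged, iterations = iter, grad_norm = grad_norm,
    boundary = stats::setNames(boundary, comp_names),
    y = y, X = X, obs = obs, animal_ids = all_ids,
    Py = ev$Py, kernel_names = knames
  ), class = "epigp_fit")
  if (!converged)
    warning("REML did not converge in ", max_iter,
            " iterations (gradient norm ", signif(grad_norm, 3), ")")
  fit
}

#' @export
print.epigp_fit <- function(x, ...) {
  cat("Multi-kernel REML fit\n")
  vc <- data.frame(component = names(x$varcomps),
                   estimate = unname(x$varcomps),
                   se = unname(x$se))
  print(vc, row.names = FALSE, digits = 4)
  cat(sprintf("logLik(REML) %.4f   AIC %.4f   %s in %d iterations\n",
              x$loglik, x$aic,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Akaike information criterion of a REML fit
#'
#' `AIC = -2 logLik + 2 k` where `k` counts the variance components
#' (including the residual); fixed effects are profiled out of the restricted
#' likelihood and are not counted. Comparable only across models with the
#' same fixed-effect design.
#'
#' @param fit an `epigp_fit`.
#' @return Numeric AIC.
#' @export
aic_reml <- function(fit) {
  stopifnot(inherits(fit, "epigp_fit"))
  -2 * fit$loglik + 2 * length(fit$varcomps)
}

#' Variance components as proportions of phenotypic variance
#'
#' `p_k = s2_k / sum_j s2_j`, with delta-method standard errors from the
#' AI covariance matrix of the variance-component estimates. Proportions for
#' components pinned at the zero boundary get NA standard errors.
#'
#' @param fit an `epigp_fit`.
#' @return data.frame with columns `component`, `proportion`, `se`.
#' @export
variance_proportions <- function(fit) {
  th <- fit$varcomps
  tot <- sum(th)
  if (tot <= 0) stop("total variance is not positive")
  p <- th / tot
  Kp1 <- length(th)
  se <- rep(NA_real_, Kp1)
  if (all(is.finite(fit$ai_cov))) {
    for (k in seq_len(Kp1)) {
      g <- rep(-th[k] / tot^2, Kp1)
      g[k] <- g[k] + 1 / tot
      se[k] <- sqrt(max(0, drop(t(g) %*% fit$ai_cov %*% g)))
    }
  }
  se[fit$boundary] <- NA_real_
  data.frame(component = names(th), proportion = unname(p), se = se)
}

#' Predict genetic values for target animals
#'
#' BLUP extrapolation through kernel covariances between target and
#' phenotyped animals: `U_k(target) = s2_k K_k[target, obs] V^-1 (y - X b)`.
#' For phenotyped animals this reproduces their in-fit BLUPs.
#'
#' @param fit an `epigp_fit` whose kernels covered the targets.
#' @param kernels the kernel set used in the fit (full animal index).
#' @param target_ids animal IDs (or indices) to predict.
#' @return data.frame with one row per target: per-kernel predicted effects
#'   and `total` (the total genotypic value, i.e. the sum over genetic
#'   components).
#' @export
predict_unphenotyped <- function(fit, kernels, target_ids) {
  stopifnot(inherits(fit, "epigp_fit"))
  ids <- rownames(kernels[[1]])
  if (is.character(target_ids)) {
    idx <- match(target_ids, ids)
    if (anyNA(idx))
      stop("target ID not in kernels: ", target_ids[which(is.na(idx))[1]])
  } else idx <- target_ids
  out <- data.frame(animal_id = if (!is.null(ids)) ids[idx] else idx)
  total <- rep(0, length(idx))
  for (k in fit$kernel_names) {
    u <- fit$varcomps[k] *
      drop(unclass(kernels[[k]])[idx, fit$obs, drop = FALSE] %*% fit$Py)
    out[[k]] <- u
    total <- total + u
  }
  out$total <- total
  out
}
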