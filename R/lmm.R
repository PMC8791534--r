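#' Three-level linear mixed model by maximum likelihood
#'
#' Fits a Gaussian linear mixed model with random intercepts for study
#' center and for subject nested within center, by full maximum likelihood
#' (not REML, so likelihood-based criteria remain comparable when the fixed
#' part changes). The marginal covariance is
#' `V = sigma2_center Zc Zc' + sigma2_subject Zs Zs' + sigma2_resid I`.
#'
#' The likelihood is profiled: for given variance ratios the GLS fixed
#' effects and the residual variance are available in closed form, and the
#' nested grouping makes `V^{-1}x` an O(n) operation (Sherman-Morrison per
#' subject followed by a rank-one update per center), so only the two log
#' variance ratios are optimized numerically.
#'
#' @param formula fixed-effects formula, e.g. `y ~ 0 + sex + sex:g1 + sex:g2`.
#' @param data data frame containing the response, fixed-effect covariates,
#'   and the grouping columns.
#' @param center,subject names of the center and subject id columns.
#' @param random character vector choosing the random intercepts; default
#'   both `"center"` and `"subject"` (subject is nested within center).
#' @param starts number of extra optimizer restarts on poor convergence.
#' @param par_init optional warm start for the log variance ratios
#'   (subject, center), e.g. from a fit to closely related data; used by the
#'   bootstrap to speed up replicate refits.
#' @return An object of class `nglmm` with components `coefficients`,
#'   `varcomps` (center, subject, resid variances), `loglik`, `AIC`, `BIC`,
#'   `n_obs`, `n_subjects`, `n_centers`, `k_params`, and fitting internals.
#' @export
fit_lmm <- function(formula, data, center = "center_id", subject = "subject_id",
                    random = c("center", "subject"), starts = 3L,
                    par_init = NULL) {
  random <- match.arg(random, c("center", "subject"), several.ok = TRUE)
  mf <- stats::model.frame(formula, data = data, na.action = stats::na.fail)
  y <- stats::model.response(mf)
  trms <- stats::terms(mf)
  X <- stats::model.matrix(trms, mf)
  n <- length(y)
  p <- ncol(X)
  if (qr(X)$rank < p)
    stop("singular fixed-effects design matrix", call. = FALSE)
  subj_f <- interaction(data[[center]], data[[subject]], drop = TRUE)
  cent_f <- factor(data[[center]])
  if (nlevels(subj_f) < 2) stop("need at least 2 subjects", call. = FALSE)
  subj_i <- as.integer(subj_f)
  cent_i <- as.integer(cent_f)
  has_c <- "center" %in% random
  has_s <- "subject" %in% random
  ml <- .lmm_ml(X, y, subj_i, cent_i, has_s = has_s, has_c = has_c,
                starts = starts, par_init = par_init)
  pr <- ml$profile
  lam <- ml$lambdas
  vc <- c(center = unname(lam["c"] * pr$sigma2),
          subject = unname(lam["s"] * pr$sigma2),
          resid = pr$sigma2)
  k_params <- p + 1L + ml$npar
  fit <- list(coefficients = stats::setNames(drop(pr$beta), colnames(X)),
              varcomps = vc,
              loglik = pr$ll,
              AIC = -2 * pr$ll + 2 * k_params,
              BIC = -2 * pr$ll + k_params * log(n),
              n_obs = n,
              n_subjects = nlevels(subj_f),
              n_centers = nlevels(cent_f),
              k_params = k_params,
              formula = formula,
              terms = trms,
              xlevels = stats::.getXlevels(trms, mf),
              converged = ml$converged,
              internals = list(X = X, y = y, subj_i = subj_i, cent_i = cent_i,
                               nj = ml$nj, par = ml$par, has_s = has_s,
                               has_c = has_c, We = pr$We, M = pr$M,
                               sigma2 = pr$sigma2))
  class(fit) <- "nglmm"
  fit
}

# core profiled-ML optimizer over the log variance ratios; subj_i and
# cent_i must be consecutive integer codes (1..S, 1..C)
.lmm_ml <- function(X, y, subj_i, cent_i, has_s = TRUE, has_c = TRUE,
                    starts = 3L, par_init = NULL, reltol = 1e-10) {
  nj <- tabulate(subj_i)
  pre <- list(XY = cbind(X, y), p = ncol(X), n = length(y),
              subj_center = cent_i[match(seq_along(nj), subj_i)])
  obj <- function(par) {
    pr <- .lmm_profile(par, X, y, subj_i, cent_i, nj, has_s, has_c, pre)
    if (!is.finite(pr$ll)) 1e10 else -pr$ll
  }
  npar <- has_s + has_c
  start_list <- list(rep(0, npar), rep(-3, npar), rep(2, npar),
                     seq_len(npar) - 1.5)
  if (!is.null(par_init)) start_list <- c(list(par_init), start_list)
  best <- NULL
  for (k in seq_len(min(length(start_list), 1L + starts))) {
    op <- if (npar > 1) {
      stats::optim(start_list[[k]], obj, method = "Nelder-Mead",
                   control = list(maxit = 500, reltol = reltol))
    } else if (npar == 1) {
      stats::optim(start_list[[k]], obj, method = "Brent",
                   lower = -25, upper = 25, control = list(reltol = reltol))
    } else list(par = numeric(0), value = obj(numeric(0)), convergence = 0L)
    if (is.null(best) || op$value < best$value - 1e-9) best <- op
    if (best$convergence == 0 && is.finite(best$value)) break
  }
  if (is.null(best) || !is.finite(best$value))
    stop("mixed-model fit failed to converge after restarts", call. = FALSE)
  # snap variance ratios to the zero boundary where the profile is flat
  for (i in seq_len(npar)) {
    cand <- best$par
    cand[i] <- -30
    v <- obj(cand)
    if (v <= best$value + 1e-6) best <- list(par = cand, value = v,
                                             convergence = best$convergence)
  }
  pr <- .lmm_profile(best$par, X, y, subj_i, cent_i, nj, has_s, has_c, pre)
  list(profile = pr, par = best$par, lambdas = .lmm_lambdas(best$par, has_s, has_c),
       converged = best$convergence == 0, npar = npar, nj = nj)
}

# Closure drawing one center-stratified subject resample of a fitted model
# and refitting it at the matrix level (rows reused under fresh subject
# codes, optimizer warm-started at the full-data variance ratios). Returns
# the replicate's fixed-effect vector, or NULL on non-convergence.
.boot_engine <- function(fit) {
  it <- fit$internals
  rows <- split(seq_along(it$y), it$subj_i)
  subj_center <- it$cent_i[vapply(rows, `[`, integer(1), 1L)]
  by_center <- split(seq_along(rows), subj_center)
  warm <- it$par
  function() {
    draw <- unlist(lapply(by_center, function(s)
      s[sample.int(length(s), length(s), replace = TRUE)]),
      use.names = FALSE)
    picked <- rows[draw]
    ns <- lengths(picked)
    idx <- unlist(picked, use.names = FALSE)
    subj2 <- rep(seq_along(draw), ns)
    cent2 <- rep(subj_center[draw], ns)
    ml <- tryCatch(
      .lmm_ml(it$X[idx, , drop = FALSE], it$y[idx], subj2, cent2,
              has_s = it$has_s, has_c = it$has_c, starts = 1L,
              par_init = warm, reltol = 1e-9),
      error = function(e) NULL)
    if (is.null(ml)) return(NULL)
    stats::setNames(drop(ml$profile$beta), colnames(it$X))
  }
}

# lambda vector (named s, c) from optimizer parameters
.lmm_lambdas <- function(par, has_s, has_c) {
  lam <- c(s = 0, c = 0)
  i <- 1L
  if (has_s) { lam["s"] <- exp(par[i]); i <- i + 1L }
  if (has_c) lam["c"] <- exp(par[i])
  lam
}

# Apply V0^{-1} (V0 = I + lam_s Zs Zs' + lam_c Zc Zc') to columns of x,
# and return profiled quantities. O(n) via nesting structure.
.lmm_solve_V0 <- function(x, lam, subj_i, cent_i, nj) {
  ks <- lam["s"] / (1 + lam["s"] * nj)       # per-subject shrink
  sx <- rowsum(x, subj_i, reorder = TRUE)    # subject sums
  Ax <- x - ks[subj_i] * sx[subj_i, , drop = FALSE]
  if (lam["c"] <= 0) return(Ax)
  u <- 1 / (1 + lam["s"] * nj[subj_i])       # A^{-1} 1, per observation
  s_c <- rowsum(u, cent_i, reorder = TRUE)   # 1' A^{-1} 1 per center
  kc <- lam["c"] / (1 + lam["c"] * drop(s_c))
  tx <- rowsum(Ax, cent_i, reorder = TRUE)   # 1' A^{-1} x per center
  Ax - (kc[cent_i] * u) * tx[cent_i, , drop = FALSE]
}

.lmm_logdet_V0 <- function(lam, subj_i, cent_i, nj, subj_center = NULL) {
  ld <- sum(log1p(lam["s"] * nj))
  if (lam["c"] > 0) {
    if (is.null(subj_center))  # subjects are nested in centers
      subj_center <- cent_i[match(seq_along(nj), subj_i)]
    u <- nj / (1 + lam["s"] * nj)
    s_c <- rowsum(u, subj_center, reorder = TRUE)
    ld <- ld + sum(log1p(lam["c"] * drop(s_c)))
  }
  ld
}

.lmm_profile <- function(par, X, y, subj_i, cent_i, nj, has_s, has_c,
                         pre = NULL) {
  lam <- .lmm_lambdas(par, has_s, has_c)
  n <- length(y)
  XY <- if (is.null(pre)) cbind(X, y) else pre$XY
  Wxy <- .lmm_solve_V0(XY, lam, subj_i, cent_i, nj)
  p <- ncol(X)
  WX <- Wxy[, seq_len(p), drop = FALSE]
  Wy <- Wxy[, p + 1L]
  M <- crossprod(X, WX)
  v <- crossprod(X, Wy)
  beta <- tryCatch(solve(M, v), error = function(e) NULL)
  if (is.null(beta)) return(list(ll = -Inf))
  e <- y - X %*% beta
  We <- Wy - WX %*% beta
  q <- sum(e * We)
  if (q <= 0) return(list(ll = -Inf))
  sigma2 <- q / n
  ld <- .lmm_logdet_V0(lam, subj_i, cent_i, nj,
                       subj_center = if (!is.null(pre)) pre$subj_center)
  ll <- -0.5 * (n * log(2 * pi) + n * log(sigma2) + n + ld)
  list(ll = ll, beta = beta, sigma2 = sigma2, We = drop(We), M = M)
}

#' @export
print.nglmm <- function(x, ...) {
  cat("Three-level linear mixed model (ML)\n")
  cat("  obs:", x$n_obs, " subjects:", x$n_subjects, " centers:", x$n_centers, "\n")
  cat("  logLik:", format(x$loglik, digits = 8),
      " AIC:", format(x$AIC, digits = 8),
      " BIC:", format(x$BIC, digits = 8), "\n")
  cat("Fixed effects:\n")
  print(x$coefficients)
  cat("Variance components (center / subject / residual):\n")
  print(x$varcomps)
  invisible(x)
}

#' @export
coef.nglmm <- function(object, ...) object$coefficients

#' @export
logLik.nglmm <- function(object, ...) {
  structure(object$loglik, df = object$k_params, nobs = object$n_obs,
            class = "logLik")
}

#' Fixed-effects prediction from a mixed-model fit
#'
#' Population-level prediction: the fixed part evaluated at `newdata`, with
#' all random effects set to zero.
#'
#' @param object an `nglmm` fit.
#' @param newdata data frame with the fixed-effect covariates.
#' @param ... unused.
#' @return Numeric vector of predicted responses.
#' @export
predict.nglmm <- function(object, newdata, ...) {
  tt <- stats::delete.response(object$terms)
  mf <- stats::model.frame(tt, newdata, xlev = object$xlevels,
                           na.action = stats::na.fail)
  X <- stats::model.matrix(tt, mf)
  drop(X %*% object$coefficients[colnames(X)])
}

#' Covariance of the fixed effects
#'
#' Model-based covariance `(X' V^{-1} X)^{-1}` by default, or the
#' center-clustered sandwich via [cluster_robust_cov()].
#'
#' @param object an `nglmm` fit.
#' @param robust logical; cluster-robust (by center) instead of model-based.
#' @param ... unused.
#' @return Covariance matrix over the fixed effects.
#' @export
vcov.nglmm <- function(object, robust = FALSE, ...) {
  if (robust) return(cluster_robust_cov(object))
  it <- object$internals
  V <- solve(it$M / it$sigma2)
  dimnames(V) <- list(names(object$coefficients), names(object$coefficients))
  (V + t(V)) / 2
}

#' Cluster-robust covariance of the fixed effects
#'
#' Sandwich estimator aggregating the marginal score contributions
#' `X_c' V_c^{-1} e_c` by cluster (study center by default), with the
#' small-sample factor G/(G-1) for G clusters. With one observation per
#' cluster this reduces to the heteroscedasticity-robust sandwich.
#'
#' @param fit an `nglmm` fit.
#' @param cluster optional integer/factor vector of cluster ids, one per
#'   observation; defaults to the fit's center grouping.
#' @return Symmetric positive semi-definite covariance matrix over the
#'   fixed effects.
#' @export
cluster_robust_cov <- function(fit, cluster = NULL) {
  stopifnot(inherits(fit, "nglmm"))
  it <- fit$internals
  cl <- if (is.null(cluster)) it$cent_i else as.integer(factor(cluster))
  G <- length(unique(cl))
  if (G < 2)
    stop("cluster-robust covariance needs >= 2 clusters; ",
         "use the model-based covariance instead", call. = FALSE)
  # scores: g_c = X_c' V_c^{-1} e_c = (1/sigma2) * sum_c x_i * (W e)_i
  Gmat <- rowsum(it$X * it$We, cl) / it$sigma2
  meat <- crossprod(Gmat)
  bread <- solve(it$M / it$sigma2)   # (X' V^{-1} X)^{-1}
  V <- bread %*% meat %*% bread * G / (G - 1)
  (V + t(V)) / 2
}
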