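#' Lobe names handled by the pipeline
#' @return Character vector of the four cortical lobes.
#' @export
gm_lobes <- function() c("frontal", "temporal", "parietal", "occipital")

lobe_column <- function(lobe) {
  lobe <- match.arg(lobe, gm_lobes())
  paste0("gm_", lobe, "_mm3")
}

# attach FP basis columns g1/g2 (or g1 only) for a spec, dropping rows
# with missing response
traj_frame <- function(data, lobe, spec) {
  col <- lobe_column(lobe)
  keep <- !is.na(data[[col]]) & !is.na(data$age_months) & !is.na(data$sex)
  d <- data[keep, , drop = FALSE]
  age <- d$age_months / 12
  if (any(age <= 0)) stop("all ages must be positive", call. = FALSE)
  B <- fp_transform(age, spec)
  d$g1 <- B[, 1]
  if (ncol(B) >= 2) d$g2 <- B[, 2]
  d$sex <- factor(d$sex, levels = c("F", "M"))
  d$.y <- d[[col]]
  d$age_years <- age
  d
}

traj_formula <- function() .y ~ 0 + sex + sex:g1 + sex:g2

#' Fit a gray-matter growth trajectory with fractional-polynomial selection
#'
#' Fits the three-level mixed model
#' `volume = f(sex, age) + center + subject + error` for one cortical lobe,
#' where `f` is a second-order fractional polynomial of age fully interacted
#' with sex (sex-specific intercept and two sex-specific age terms, six
#' fixed coefficients). When `powers` is `NULL`, all 36 canonical FP2
#' candidates over the standard power set are fitted on identical rows and
#' the one minimizing the selection criterion is retained; all candidates
#' share the same parameter count, so -2LL, AIC and BIC orderings coincide
#' and this is asserted rather than assumed. Ties are broken by lower -2LL,
#' then by lexicographically smaller powers.
#'
#' @param data long-format scan table (see [read_scan_table()] for the schema).
#' @param lobe one of [gm_lobes()].
#' @param criterion selection criterion: `"BIC"` (default), `"AIC"` or `"m2LL"`.
#' @param powers optional length-2 power vector; if given, selection is
#'   skipped and this basis is fitted directly.
#' @return Object of class `gm_trajectory`: the selected [fp_spec()], the
#'   `nglmm` fit, the criteria of the selected model, a 36-row
#'   `selection_table` (or 1-row when `powers` is fixed), and the observed
#'   age range.
#' @export
gm_trajectory <- function(data, lobe, criterion = c("BIC", "AIC", "m2LL"),
                          powers = NULL) {
  criterion <- match.arg(criterion)
  lobe <- match.arg(lobe, gm_lobes())
  cands <- if (is.null(powers)) fp2_candidates() else list(fp_spec(powers))
  rows <- vector("list", length(cands))
  fits <- vector("list", length(cands))
  for (i in seq_along(cands)) {
    spec <- cands[[i]]
    d <- traj_frame(data, lobe, spec)
    if (length(unique(d$age_years[d$sex == "F"])) < 2 ||
        length(unique(d$age_years[d$sex == "M"])) < 2)
      stop("need >= 2 distinct ages per sex", call. = FALSE)
    fit <- tryCatch(fit_lmm(traj_formula(), d), error = function(e) e)
    ok <- !inherits(fit, "error")
    rows[[i]] <- data.frame(
      p1 = spec$powers[1], p2 = spec$powers[2],
      m2LL = if (ok) -2 * fit$loglik else NA_real_,
      AIC = if (ok) fit$AIC else NA_real_,
      BIC = if (ok) fit$BIC else NA_real_,
      k_params = if (ok) fit$k_params else NA_integer_,
      n_obs = if (ok) fit$n_obs else NA_integer_,
      converged = ok && fit$converged)
    fits[[i]] <- if (ok) fit else NULL
  }
  tab <- do.call(rbind, rows)
  conv <- which(tab$converged)
  if (!length(conv))
    stop("no trajectory candidate converged for lobe ", lobe, call. = FALSE)
  stopifnot(length(unique(tab$n_obs[conv])) == 1L)
  if (length(conv) > 1L) {
    # equal k across candidates makes the three criteria order identically
    stopifnot(length(unique(tab$k_params[conv])) == 1L)
    stopifnot(identical(order(tab$m2LL[conv]), order(tab$BIC[conv])),
              identical(order(tab$m2LL[conv]), order(tab$AIC[conv])))
  }
  best <- conv[.select_best(tab[conv, , drop = FALSE], criterion)]
  fit <- fits[[best]]
  dsel <- traj_frame(data, lobe, cands[[best]])
  obj <- list(lobe = lobe, spec = cands[[best]], fit = fit,
              criterion = criterion,
              criteria = c(m2LL = tab$m2LL[best], AIC = tab$AIC[best],
                           BIC = tab$BIC[best]),
              selection_table = tab,
              age_range = range(dsel$age_years),
              n_obs = fit$n_obs, n_subjects = fit$n_subjects)
  class(obj) <- "gm_trajectory"
  obj
}

# row index of the winning candidate: minimal criterion, ties broken by
# lower -2LL, then lexicographically smaller (p1, p2)
.select_best <- function(tab, criterion) {
  order(tab[[criterion]], tab$m2LL, tab$p1, tab$p2)[1L]
}

# sex-specific FP coefficients (intercept, b1, b2) for a trajectory-style fit
sex_coefs <- function(fit, sex) {
  co <- coef(fit)
  key <- paste0("sex", sex)
  b0 <- co[key]
  b1 <- co[paste0(key, ":g1")]
  b2 <- co[paste0(key, ":g2")]
  if (anyNA(c(b0, b1, b2))) stop("unknown sex level: ", sex, call. = FALSE)
  unname(c(b0, b1, b2))
}

#' @export
print.gm_trajectory <- function(x, ...) {
  cat("Gray-matter growth trajectory:", x$lobe, "lobe\n")
  cat("  FP2 basis powers (", paste(x$spec$powers, collapse = ", "),
      "), selected by ", x$criterion, "\n", sep = "")
  cat("  n =", x$n_obs, "scans from", x$n_subjects, "subjects;",
      "ages", round(x$age_range[1], 2), "-", round(x$age_range[2], 2), "y\n")
  cat("  -2LL:", format(x$criteria["m2LL"], digits = 8),
      " AIC:", format(x$criteria["AIC"], digits = 8),
      " BIC:", format(x$criteria["BIC"], digits = 8), "\n")
  cat("Fixed effects:\n")
  print(x$fit$coefficients)
  invisible(x)
}

#' @export
summary.gm_trajectory <- function(object, ...) {
  pk <- vapply(c("F", "M"), function(s) peak_age(object, s)$age, numeric(1))
  out <- list(trajectory = object, varcomps = object$fit$varcomps,
              peak_ages = pk)
  class(out) <- "summary.gm_trajectory"
  out
}

#' @export
print.summary.gm_trajectory <- function(x, ...) {
  print(x$trajectory)
  cat("Variance components:\n")
  print(x$varcomps)
  cat("Peak ages (years): F =", round(x$peak_ages["F"], 2),
      ", M =", round(x$peak_ages["M"], 2), "\n")
  invisible(x)
}

#' @export
coef.gm_trajectory <- function(object, ...) coef(object$fit)

#' Predict the mean (fixed-effects) volume trajectory
#'
#' Population-level expected volume for given sex and age; random effects
#' are set to zero.
#'
#' @param object a `gm_trajectory`.
#' @param sex `"F"` or `"M"` (recycled against `age`).
#' @param age positive ages in years.
#' @param ... unused.
#' @return Numeric vector of expected volumes (mm^3).
#' @export
predict.gm_trajectory <- function(object, sex, age, ...) {
  n <- max(length(sex), length(age))
  sex <- rep_len(as.character(sex), n)
  age <- rep_len(age, n)
  if (!all(sex %in% c("F", "M")))
    stop("unknown sex level: ", paste(setdiff(sex, c("F", "M")), collapse = ", "),
         call. = FALSE)
  if (any(age <= 0)) stop("age must be positive (years)", call. = FALSE)
  B <- fp_transform(age, object$spec)
  out <- numeric(n)
  for (s in unique(sex)) {
    b <- sex_coefs(object$fit, s)
    i <- sex == s
    out[i] <- b[1] + B[i, , drop = FALSE] %*% b[2:3]
  }
  out
}

#' Population residuals against the mean trajectory
#'
#' Observed volume minus the fixed-effects prediction for the same sex and
#' age. Because random effects are not subtracted, these residuals carry the
#' full between-center, between-subject and scan-level variability -- the
#' population spread a volume-for-age chart must describe.
#'
#' @param object a `gm_trajectory`.
#' @param data scan table on the same lobe (defaults to refusing silently
#'   missing volumes).
#' @param ... unused.
#' @return Data frame with `sex`, `age_years` and `resid` (mm^3).
#' @export
residuals.gm_trajectory <- function(object, data, ...) {
  d <- traj_frame(data, object$lobe, object$spec)
  mu <- predict(object, d$sex, d$age_years)
  data.frame(sex = d$sex, age_years = d$age_years, resid = d$.y - mu)
}

#' @export
plot.gm_trajectory <- function(x, ages = NULL, ...) {
  if (is.null(ages))
    ages <- seq(max(x$age_range[1], 0.05), x$age_range[2], length.out = 200)
  vf <- predict(x, "F", ages)
  vm <- predict(x, "M", ages)
  plot(ages, vm, type = "l", col = "steelblue", lwd = 2,
       xlab = "Age (years)", ylab = paste(x$lobe, "GM volume (mm^3)"),
       ylim = range(vf, vm), ...)
  lines(ages, vf, col = "firebrick", lwd = 2)
  legend("bottomright", c("M", "F"), col = c("steelblue", "firebrick"),
         lwd = 2, bty = "n")
  invisible(x)
}

#' Export a trajectory selection table
#'
#' @param object a `gm_trajectory`.
#' @param path CSV destination.
#' @return The path, invisibly.
#' @export
write_selection_table <- function(object, path) {
  utils::write.csv(object$selection_table, path, row.names = FALSE)
  invisible(path)
}
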