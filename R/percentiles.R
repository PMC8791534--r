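#' Fit an age-varying variance curve to squared residuals
#'
#' Models the squared population residuals as a first-order fractional
#' polynomial of age: for every candidate single power q in the standard
#' power set, ordinary least squares of `resid^2` on `(1, g_q(age))`, with
#' the winner chosen by residual sum of squares. If every candidate's
#' fitted variance dips non-positive somewhere on the age support the
#' fallback chain is the linear-in-age model, then a constant (which always
#' succeeds). A small variance floor (1e-6 times the mean squared residual)
#' keeps the implied SD defined. Fit separately per sex.
#'
#' @param residuals numeric residuals (mm^3), e.g. one sex's rows of
#'   [residuals.gm_trajectory()].
#' @param ages matching ages in years.
#' @param sex label stored on the result.
#' @param lobe label stored on the result.
#' @return Object of class `gm_varcurve`: selected `power` (NA for the
#'   constant model), `delta` = (d0, d1), the floor, and the support.
#' @export
fit_variance_curve <- function(residuals, ages, sex = NA, lobe = NA) {
  stopifnot(length(residuals) == length(ages))
  if (length(residuals) < 20)
    stop("need >= 20 residuals to fit a variance curve", call. = FALSE)
  r2 <- residuals^2
  floor_ <- 1e-6 * mean(r2)
  support <- seq(min(ages), max(ages), length.out = 512)
  cand <- fp_powers()
  best <- NULL
  for (q in cand) {
    g <- fp_term(ages, q)
    fit <- stats::lm.fit(cbind(1, g), r2)
    rss <- sum(fit$residuals^2)
    d <- fit$coefficients
    ok <- all(d[1] + d[2] * fp_term(support, q) > 0)
    rec <- list(power = q, delta = unname(d), rss = rss, positive = ok)
    if (ok && (is.null(best) || rss < best$rss)) best <- rec
  }
  if (is.null(best)) {
    # fallback: linear in age, then constant
    fit <- stats::lm.fit(cbind(1, ages), r2)
    d <- unname(fit$coefficients)
    if (all(d[1] + d[2] * support > 0)) {
      best <- list(power = 1, delta = d, rss = sum(fit$residuals^2),
                   positive = TRUE)
    } else {
      best <- list(power = NA_real_, delta = c(mean(r2), 0), rss = sum((r2 - mean(r2))^2),
                   positive = TRUE)
    }
  }
  out <- list(lobe = lobe, sex = sex, power = best$power, delta = best$delta,
              floor = floor_, age_range = range(ages), n = length(r2))
  class(out) <- "gm_varcurve"
  out
}

#' Age-varying population standard deviation
#'
#' @param varcurve a `gm_varcurve`.
#' @param ages ages in years.
#' @return SD in mm^3 at each age: `sqrt(max(d0 + d1 g_q(age), floor))`.
#' @export
sd_at_age <- function(varcurve, ages) {
  v <- if (is.na(varcurve$power)) {
    rep(varcurve$delta[1], length(ages))
  } else {
    varcurve$delta[1] + varcurve$delta[2] * fp_term(ages, varcurve$power)
  }
  sqrt(pmax(v, varcurve$floor))
}

#' @export
print.gm_varcurve <- function(x, ...) {
  cat("Age-varying variance curve",
      if (!is.na(x$lobe)) paste0("(", x$lobe, ", sex ", x$sex, ")"), "\n")
  if (is.na(x$power)) cat("  constant variance:", x$delta[1], "mm^6\n")
  else cat("  power q =", x$power, "; delta =", x$delta, "\n")
  cat("  SD at support ends:",
      round(sd_at_age(x, x$age_range), 1), "mm^3\n")
  invisible(x)
}

#' Sex-specific volume-for-age percentile chart
#'
#' `P_q(age) = mean(sex, age) + z_{q/100} SD(age)` with z the standard
#' normal quantile: the mean trajectory from the mixed-model fit plus an
#' age-varying normal spread from the variance curve. The 50th percentile
#' is the mean curve itself, and curves are strictly increasing in level.
#'
#' @param model a `gm_trajectory`.
#' @param varcurve a `gm_varcurve` fitted to the same sex's residuals.
#' @param sex `"F"` or `"M"`.
#' @param levels percentile levels, strictly inside (0, 100).
#' @param ages age grid in years.
#' @return Object of class `gm_chart`: data frame of ages by levels.
#' @export
percentile_chart <- function(model, varcurve, sex,
                             levels = c(5, 10, 25, 50, 75, 90, 95),
                             ages = NULL) {
  stopifnot(inherits(model, "gm_trajectory"), inherits(varcurve, "gm_varcurve"))
  if (any(levels <= 0 | levels >= 100))
    stop("percentile levels must lie strictly inside (0, 100)", call. = FALSE)
  if (is.null(ages))
    ages <- seq(max(model$age_range[1], 0.05), model$age_range[2],
                length.out = 100)
  mu <- predict(model, sex, ages)
  sdv <- sd_at_age(varcurve, ages)
  out <- data.frame(lobe = model$lobe, sex = sex, age_years = ages)
  for (lv in sort(levels))
    out[[paste0("p", lv)]] <- mu + stats::qnorm(lv / 100) * sdv
  structure(out, levels = sort(levels),
            class = c("gm_chart", "data.frame"))
}

#' @export
plot.gm_chart <- function(x, ...) {
  lv <- attr(x, "levels")
  cols <- paste0("p", lv)
  matplot(x$age_years, as.matrix(x[cols]), type = "l", lty = 1,
          lwd = ifelse(lv %in% c(5, 50, 95), 2.5, 1), col = "grey30",
          xlab = "Age (years)",
          ylab = paste(x$lobe[1], "GM volume (mm^3)"), ...)
  invisible(x)
}

#' Export a percentile chart as CSV
#' @param chart a `gm_chart`.
#' @param path CSV destination.
#' @return The path, invisibly.
#' @export
write_percentile_chart <- function(chart, path) {
  utils::write.csv(as.data.frame(chart), path, row.names = FALSE)
  invisible(path)
}
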