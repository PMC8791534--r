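#' Household income brackets
#'
#' The categorical income brackets of the study questionnaire, with the
#' midpoints used to compute income-to-poverty ratios. The top bracket's
#' midpoint is the arithmetic midpoint of its range.
#'
#' @return Data frame with `bracket`, `lo`, `hi`, `midpoint` (USD).
#' @export
income_brackets <- function() {
  lo <- c(0, 5001, 10001, 15001, 25001, 35001, 50001, 75001, 100001)
  hi <- c(5000, 10000, 15000, 25000, 35000, 50000, 75000, 100000, 150000)
  data.frame(bracket = paste0("$", formatC(lo, big.mark = ",", format = "d"),
                              "-$", formatC(hi, big.mark = ",", format = "d")),
             lo = lo, hi = hi, midpoint = (lo + hi) / 2,
             stringsAsFactors = FALSE)
}

#' Bundled federal poverty guideline table (2001)
#'
#' HHS poverty guidelines by family size; sizes beyond the table extend by
#' the table's per-person increment. User-replaceable by any data frame
#' with columns `family_size` and `poverty_line_usd`.
#'
#' @return Data frame with `family_size`, `poverty_line_usd`, `year`.
#' @export
default_guidelines <- function() {
  path <- system.file("extdata", "fpl_guidelines_2001.csv",
                      package = "neurogrowth")
  if (!nzchar(path))  # during in-source development
    path <- file.path("inst", "extdata", "fpl_guidelines_2001.csv")
  utils::read.csv(path)
}

# poverty line for a family size, extending beyond the table linearly
fpl_guideline <- function(family_size, guidelines = default_guidelines()) {
  if (is.na(family_size) || family_size < 1) return(NA_real_)
  g <- guidelines[order(guidelines$family_size), ]
  if (family_size <= max(g$family_size))
    return(g$poverty_line_usd[match(family_size, g$family_size)])
  n <- nrow(g)
  step <- g$poverty_line_usd[n] - g$poverty_line_usd[n - 1]
  g$poverty_line_usd[n] + step * (family_size - g$family_size[n])
}

#' Classify a family as low income relative to the poverty line
#'
#' Converts a categorical income report to its bracket midpoint, divides by
#' the poverty guideline for the family size (the income-to-poverty ratio),
#' and flags families whose ratio falls below `threshold_pct` percent of the
#' federal poverty level (default 200%, the common economic-insecurity
#' cutoff; 100% reproduces the strict-poverty variant).
#'
#' @param income_bracket bracket label as in [income_brackets()] (vectorized).
#' @param family_size household size (vectorized).
#' @param guidelines guideline table, see [default_guidelines()].
#' @param threshold_pct threshold as percent of the poverty level.
#' @return Data frame with `fpl_ratio` and logical `low_income`; missing
#'   income or family size yields `NA` in both.
#' @export
classify_low_income <- function(income_bracket, family_size,
                                guidelines = default_guidelines(),
                                threshold_pct = 200) {
  br <- income_brackets()
  n <- max(length(income_bracket), length(family_size))
  income_bracket <- rep_len(as.character(income_bracket), n)
  income_bracket[!is.na(income_bracket) & income_bracket == ""] <- NA
  family_size <- rep_len(family_size, n)
  mid <- br$midpoint[match(income_bracket, br$bracket)]
  bad <- !is.na(income_bracket) & is.na(mid)
  if (any(bad))
    stop("unknown income bracket: ", income_bracket[bad][1], call. = FALSE)
  line <- vapply(family_size, fpl_guideline, numeric(1),
                 guidelines = guidelines)
  ratio <- mid / line
  data.frame(fpl_ratio = ratio, low_income = ratio < threshold_pct / 100)
}

#' Derive the low-income flag for a scan table
#'
#' Uses the bracket + family-size classification when available, falling
#' back on a precomputed `fpl_ratio` column; a subject's first non-missing
#' report is carried to all of their scans.
#'
#' @param data scan table.
#' @param threshold_pct percent-of-FPL threshold (default 200).
#' @param guidelines guideline table.
#' @return The table with `fpl_ratio` filled and a `low_income` column.
#' @export
derive_low_income <- function(data, threshold_pct = 200,
                              guidelines = default_guidelines()) {
  cl <- classify_low_income(data$income_bracket, data$family_size,
                            guidelines, threshold_pct)
  ratio <- ifelse(is.na(cl$fpl_ratio), data$fpl_ratio, cl$fpl_ratio)
  # first non-missing report per subject
  for (s in unique(data$subject_id[is.na(ratio)])) {
    i <- data$subject_id == s
    r <- ratio[i]
    if (any(!is.na(r))) ratio[i] <- r[!is.na(r)][1]
  }
  data$fpl_ratio <- ratio
  data$low_income <- ratio < threshold_pct / 100
  data
}

#' Refit a trajectory with low-income terms
#'
#' Re-estimates the selected trajectory with three additional fixed terms:
#' a low-income indicator and its interactions with the two age transforms
#' (not interacted with sex). Rows with missing income are dropped here --
#' and only here. Optionally adjusts for mean-centered birth weight.
#'
#' @param data scan table with a `low_income` column (see
#'   [derive_low_income()]).
#' @param trajectory a `gm_trajectory`; its FP basis is inherited, not
#'   re-selected.
#' @param birth_weight logical; include a centered birth-weight main effect.
#' @param par_init optional optimizer warm start, see [fit_lmm()].
#' @return List with the augmented `nglmm` fit, the gap coefficients
#'   `gamma` (g0, g1, g2), counts of retained/dropped subjects, and the
#'   trajectory.
#' @export
fit_income_model <- function(data, trajectory, birth_weight = FALSE,
                             par_init = NULL) {
  stopifnot(inherits(trajectory, "gm_trajectory"))
  if (is.null(data$low_income))
    stop("run derive_low_income() first", call. = FALSE)
  d <- traj_frame(data, trajectory$lobe, trajectory$spec)
  drop_n <- length(unique(d$subject_id[is.na(d$low_income)]))
  d <- d[!is.na(d$low_income), , drop = FALSE]
  d$low_income <- as.numeric(d$low_income)
  n_low <- length(unique(d$subject_id[d$low_income == 1]))
  if (n_low == 0) stop("no low-income subjects", call. = FALSE)
  if (n_low < 10)
    warning("only ", n_low, " low-income subjects; estimates will be unstable")
  form <- .y ~ 0 + sex + sex:g1 + sex:g2 + low_income + low_income:g1 +
    low_income:g2
  if (birth_weight) {
    d$bw_c <- d$birth_weight_g - mean(d$birth_weight_g, na.rm = TRUE)
    d <- d[!is.na(d$bw_c), , drop = FALSE]
    form <- stats::update(form, . ~ . + bw_c)
  }
  fit <- fit_lmm(form, d, par_init = par_init)
  co <- coef(fit)
  pick <- function(...) {   # term labels vary with formula manipulation
    nm <- intersect(c(...), names(co))
    unname(co[nm[1]])
  }
  gamma <- c(g0 = pick("low_income"),
             g1 = pick("g1:low_income", "low_income:g1"),
             g2 = pick("g2:low_income", "low_income:g2"))
  list(fit = fit, gamma = gamma, n_low_income = n_low,
       n_dropped_subjects = drop_n, trajectory = trajectory,
       formula = form)
}

# gap curve from an augmented fit: g0 + g1 g1(age) + g2 g2(age)
gap_curve <- function(gamma, spec, ages) {
  B <- fp_transform(ages, spec)
  drop(gamma[1] + B %*% gamma[2:3])
}

#' Resample subjects with replacement, stratified by center
#'
#' The cluster-bootstrap resampling engine: within every center, subjects
#' are drawn with replacement (keeping each drawn subject's full scan
#' history); duplicated subjects receive fresh ids so they enter the refit
#' as distinct children.
#'
#' @param data scan table.
#' @return Resampled scan table.
#' @export
resample_subjects <- function(data) {
  rows <- split(seq_len(nrow(data)), data$subject_id)
  subj_center <- vapply(rows, function(r) data$center_id[r[1]],
                        data$center_id[1])
  idx <- integer(0)
  ids <- character(0)
  for (cid in unique(data$center_id)) {
    subs <- names(rows)[subj_center == cid]
    draw <- sample(subs, length(subs), replace = TRUE)
    r <- rows[draw]
    idx <- c(idx, unlist(r, use.names = FALSE))
    ids <- c(ids, rep(paste0(draw, ".bs", seq_along(draw)), lengths(r)))
  }
  out <- data[idx, , drop = FALSE]
  out$subject_id <- ids
  row.names(out) <- NULL
  out
}

#' Bias-corrected percentile interval
#'
#' BC (not BCa) interval: the median-bias correction
#' `z0 = qnorm(mean(theta_star < theta_hat))` shifts the percentile levels
#' to `pnorm(2 z0 +/- z_alpha)`. With a symmetric bootstrap distribution
#' (z0 = 0) this is the ordinary percentile interval.
#'
#' @param theta_star bootstrap replicates.
#' @param theta_hat point estimate on the original data.
#' @param level confidence level (default 0.95).
#' @return Length-2 vector (lower, upper).
#' @export
bc_interval <- function(theta_star, theta_hat, level = 0.95) {
  B <- length(theta_star)
  prop <- mean(theta_star < theta_hat)
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))  # keep z0 finite
  z0 <- stats::qnorm(prop)
  za <- stats::qnorm(1 - (1 - level) / 2)
  probs <- stats::pnorm(c(2 * z0 - za, 2 * z0 + za))
  stats::quantile(theta_star, probs, names = FALSE, type = 6)
}

#' Bootstrap the age-varying low-income gap
#'
#' Fits the income-augmented model, then resamples subjects with replacement
#' within centers B times, refitting the augmented model with the trajectory
#' basis frozen, and forms bias-corrected 95% intervals of the gap
#' `D(age) = g0 + g1 g1(age) + g2 g2(age)` at every grid age. Replicates
#' that fail to converge are redrawn, up to 5B total draws.
#'
#' @param data scan table with `low_income` derived.
#' @param trajectory a `gm_trajectory` for the lobe of interest.
#' @param B bootstrap replications (default 1000; < 100 draws a warning).
#' @param grid age grid in years (default 0.5 to 20.5 by 0.5).
#' @param seed integer seed making the intervals reproducible.
#' @param level confidence level.
#' @param birth_weight passed to [fit_income_model()].
#' @return Object of class `gm_income_gap`: gap coefficients, the grid,
#'   point estimates and BC intervals, percent gaps by sex at reference
#'   ages, the earliest detection age, `B` and `seed`.
#' @export
bootstrap_gap <- function(data, trajectory, B = 1000,
                          grid = seq(0.5, 20.5, by = 0.5), seed = 1L,
                          level = 0.95, birth_weight = FALSE) {
  if (B < 100) warning("B < 100 gives unstable bias-corrected intervals")
  base <- fit_income_model(data, trajectory, birth_weight = birth_weight)
  spec <- trajectory$spec
  est <- gap_curve(base$gamma, spec, grid)
  set.seed(as.integer(seed))
  # replicates refit the identical augmented model at the matrix level:
  # resampling subjects = reusing their design rows under fresh ids
  engine <- .boot_engine(base$fit)
  gcols <- match(c("low_income", "g1:low_income", "g2:low_income"),
                 names(coef(base$fit)))
  Bgrid <- cbind(1, fp_transform(grid, spec))
  boot <- matrix(NA_real_, B, length(grid))
  draws <- 0L; b <- 1L
  while (b <= B) {
    draws <- draws + 1L
    if (draws > 5L * B)
      stop("bootstrap exceeded ", 5L * B, " draws without ", B,
           " converged replicates", call. = FALSE)
    beta <- engine()
    if (is.null(beta)) next
    boot[b, ] <- drop(Bgrid %*% beta[gcols])
    b <- b + 1L
  }
  ci <- t(vapply(seq_along(grid), function(j)
    bc_interval(boot[, j], est[j], level), numeric(2)))
  res <- list(lobe = trajectory$lobe, spec = spec, gamma = base$gamma,
              grid = grid, estimate = est,
              ci_lo = ci[, 1], ci_hi = ci[, 2],
              level = level, B = B, seed = seed,
              n_low_income = base$n_low_income,
              n_dropped_subjects = base$n_dropped_subjects,
              fit = base$fit, trajectory = trajectory)
  res$earliest_sig_age <- earliest_detection_age(res)
  res$percent_gap <- percent_gap(res, ages = c(6.5, 20))
  class(res) <- "gm_income_gap"
  res
}

#' Earliest age at which the income gap is detectable
#'
#' The smallest grid age whose bias-corrected interval excludes zero, or
#' `NA` when no such age exists.
#'
#' @param result a `gm_income_gap` (or a compatible list with `grid`,
#'   `ci_lo`, `ci_hi`).
#' @return Age in years, or `NA_real_`.
#' @export
earliest_detection_age <- function(result) {
  sig <- result$ci_lo > 0 | result$ci_hi < 0
  if (!any(sig)) NA_real_ else min(result$grid[sig])
}

#' Percent income gap by sex at reference ages
#'
#' `100 |D(age)| / V(sex, age)` where V is the predicted nonpoor volume
#' from the augmented fit. The gap coefficients are shared across sexes, so
#' the female percentage exceeds the male one by exactly the fitted
#' male/female volume ratio.
#'
#' @param result a `gm_income_gap`.
#' @param ages reference ages in years.
#' @return Data frame with `age_years`, `pct_gap_male`, `pct_gap_female`.
#' @export
percent_gap <- function(result, ages = 20) {
  gap <- gap_curve(result$gamma, result$spec, ages)
  B <- fp_transform(ages, result$spec)
  co <- coef(result$fit)
  vf <- co["sexF"] + drop(B %*% co[c("sexF:g1", "sexF:g2")])
  vm <- co["sexM"] + drop(B %*% co[c("sexM:g1", "sexM:g2")])
  data.frame(age_years = ages,
             pct_gap_male = 100 * abs(gap) / vm,
             pct_gap_female = 100 * abs(gap) / vf)
}

#' @export
print.gm_income_gap <- function(x, ...) {
  cat("Low-income gap in", x$lobe, "GM volume (basis powers ",
      paste(x$spec$powers, collapse = ", "), ")\n")
  cat("  gap coefficients g0/g1/g2:", format(x$gamma, digits = 6), "\n")
  cat("  bootstrap: B =", x$B, ", seed =", x$seed,
      ", level =", x$level, "\n")
  if (is.na(x$earliest_sig_age)) {
    cat("  no grid age with interval excluding zero\n")
  } else {
    j <- match(x$earliest_sig_age, x$grid)
    cat(sprintf("  earliest detection at %.1f y: gap %.1f mm^3 (CI %.1f, %.1f)\n",
                x$earliest_sig_age, x$estimate[j], x$ci_lo[j], x$ci_hi[j]))
  }
  print(x$percent_gap)
  invisible(x)
}

#' Export the income-gap grid as CSV
#' @param result a `gm_income_gap`.
#' @param path CSV destination.
#' @return The path, invisibly.
#' @export
write_income_gap <- function(result, path) {
  pg <- percent_gap(result, ages = result$grid)
  utils::write.csv(
    data.frame(lobe = result$lobe, age_years = result$grid,
               gap_mm3 = result$estimate, ci_lo = result$ci_lo,
               ci_hi = result$ci_hi,
               pct_gap_male = pg$pct_gap_male,
               pct_gap_female = pg$pct_gap_female),
    path, row.names = FALSE)
  invisible(path)
}
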