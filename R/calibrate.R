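#' Default calibration targets for the synthetic truth
#'
#' Per-lobe constraints pinning down the true female trajectories and the
#' low-income gap functions of the synthetic cohort: peak age and peak
#' volume of the female curve, relative growth at age 5 months, and the gap
#' value at its detection-onset age together with the percent deficit
#' (relative to the nonpoor female curve) at age 20.
#'
#' @return Data frame with one row per lobe.
#' @export
truth_targets <- function() {
  data.frame(
    lobe = gm_lobes(),
    peak_age = c(9, 7.5, 7, 6),
    peak_volume = c(230000, 170000, 150000, 70000),
    rel_growth_5mo = c(2.1, 2.6, 3.7, 3.2),       # %/month at age 5 months
    gap_onset_age = c(6.5, 4, 2.5, 4),
    gap_at_onset = c(-3574.6, -2406.8, -2489.7, -2114.3),
    gap_pct_at_20 = c(7.1, 5.1, 3.2, 5.0),        # % of nonpoor female V(20)
    stringsAsFactors = FALSE)
}

#' Calibrate the synthetic-cohort truth
#'
#' Solves, for every lobe, for the female trajectory coefficients
#' `V_f(a) = b0 + b1 log(a) + b2 a` (the (0, 1) fractional-polynomial basis)
#' such that (i) the curve peaks at the target age (`-b1/b2` equals it),
#' (ii) the peak volume matches, and (iii) the relative growth rate at age
#' 5 months, `100 * (dV/da) / (12 V)`, matches the target in percent per
#' month. The low-income gap `D(a) = g1 log(a) + g2 a` (no constant: the gap
#' vanishes near birth) is solved so that `D(onset age)` equals the target
#' coefficient and `D(20)` equals `-pct/100 * V_f(20)`. Both systems are
#' linear; solutions are verified to satisfy every constraint to 1e-8.
#'
#' @param targets constraint table as from [truth_targets()].
#' @param male_multiplier multiplicative male/female volume ratio.
#' @param sigma_center_frac,sigma_subject_frac center and subject random
#'   intercept SDs as fractions of the lobe peak volume.
#' @param sigma_resid_frac scan-level residual SD at age 0 as a fraction of
#'   the lobe peak volume; the SD grows mildly with age as
#'   `sigma_resid_frac * peak * (1 + resid_age_slope * age_years)`.
#' @param resid_age_slope proportional residual-SD increase per year.
#' @return Object of class `gm_truth`: per-lobe `beta` (b0, b1, b2), `gamma`
#'   (g1, g2), noise settings and design margins.
#' @export
calibrate_truth <- function(targets = truth_targets(),
                            male_multiplier = 1.10,
                            sigma_center_frac = 0.015,
                            sigma_subject_frac = 0.07,
                            sigma_resid_frac = 0.03,
                            resid_age_slope = 0.01) {
  a0 <- 5 / 12
  beta <- matrix(NA_real_, nrow(targets), 3,
                 dimnames = list(targets$lobe, c("b0", "b1", "b2")))
  gam <- matrix(NA_real_, nrow(targets), 2,
                dimnames = list(targets$lobe, c("g1", "g2")))
  need <- c("lobe", "peak_age", "peak_volume", "rel_growth_5mo",
            "gap_onset_age", "gap_at_onset", "gap_pct_at_20")
  if (!all(need %in% names(targets)))
    stop("targets must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  num <- as.matrix(targets[setdiff(need, "lobe")])
  if (any(!is.finite(num)) || any(targets$peak_age <= 0) ||
      any(targets$peak_volume <= 0) || any(targets$gap_onset_age <= 0))
    stop("infeasible calibration constraints: peak ages, peak volumes and ",
         "gap onset ages must be positive and finite", call. = FALSE)
  for (i in seq_len(nrow(targets))) {
    tg <- targets[i, ]
    r <- tg$rel_growth_5mo
    # rows: derivative zero at peak; value at peak; relative growth at a0
    A <- rbind(c(0, 1 / tg$peak_age, 1),
               c(1, log(tg$peak_age), tg$peak_age),
               c(-12 * r, 100 / a0 - 12 * r * log(a0), 100 - 12 * r * a0))
    b <- c(0, tg$peak_volume, 0)
    bet <- solve(A, b)
    res <- A %*% bet - b
    if (max(abs(res)) > 1e-8 * max(1, tg$peak_volume))
      stop("trajectory calibration failed for lobe ", tg$lobe, call. = FALSE)
    # explicit constraint residuals (belt and braces)
    stopifnot(abs(-bet[2] / bet[3] - tg$peak_age) < 1e-6)
    beta[i, ] <- bet
    v20 <- bet[1] + bet[2] * log(20) + bet[3] * 20
    Ag <- rbind(c(log(tg$gap_onset_age), tg$gap_onset_age),
                c(log(20), 20))
    bg <- c(tg$gap_at_onset, -tg$gap_pct_at_20 / 100 * v20)
    gm <- solve(Ag, bg)
    if (max(abs(Ag %*% gm - bg)) > 1e-8 * max(1, abs(tg$gap_at_onset)))
      stop("gap calibration failed for lobe ", tg$lobe, call. = FALSE)
    gam[i, ] <- gm
  }
  obj <- list(beta = beta, gamma = gam,
              spec = fp_spec(c(0, 1)),
              male_multiplier = male_multiplier,
              targets = targets,
              sigma_center_frac = sigma_center_frac,
              sigma_subject_frac = sigma_subject_frac,
              sigma_resid_frac = sigma_resid_frac,
              resid_age_slope = resid_age_slope,
              design = default_design())
  class(obj) <- "gm_truth"
  obj
}

#' @export
print.gm_truth <- function(x, ...) {
  cat("Calibrated synthetic truth ((0,1) FP basis, female reference)\n")
  print(cbind(as.data.frame(x$beta), as.data.frame(x$gamma)))
  cat("male multiplier:", x$male_multiplier,
      "; noise fracs (center/subject/resid):",
      x$sigma_center_frac, x$sigma_subject_frac, x$sigma_resid_frac, "\n")
  invisible(x)
}

#' Serialize a calibrated truth to JSON
#'
#' Writes the per-lobe trajectory and gap coefficients, the sex multiplier,
#' the noise settings and the design margins, so a simulation's generating
#' truth can be archived next to its outputs.
#'
#' @param truth a `gm_truth`.
#' @param path JSON destination.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(
    list(beta = as.data.frame(cbind(lobe = rownames(truth$beta),
                                    as.data.frame(truth$beta))),
         gamma = as.data.frame(cbind(lobe = rownames(truth$gamma),
                                     as.data.frame(truth$gamma))),
         spec = list(powers = truth$spec$powers),
         male_multiplier = truth$male_multiplier,
         sigma_center_frac = truth$sigma_center_frac,
         sigma_subject_frac = truth$sigma_subject_frac,
         sigma_resid_frac = truth$sigma_resid_frac,
         resid_age_slope = truth$resid_age_slope,
         design = truth$design),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Noiseless true volume
#'
#' Evaluates the calibrated truth: the female curve times the male
#' multiplier for boys, plus the low-income gap for poor/near-poor children.
#'
#' @param truth a `gm_truth` from [calibrate_truth()].
#' @param lobe one of [gm_lobes()].
#' @param sex `"F"` or `"M"`.
#' @param low_income logical.
#' @param age positive age in years.
#' @return Expected volume in mm^3 (vectorized over `age`).
#' @export
truth_volume <- function(truth, lobe, sex, low_income, age) {
  lobe <- match.arg(lobe, gm_lobes())
  if (any(age <= 0)) stop("age must be positive", call. = FALSE)
  sex <- match.arg(sex, c("F", "M"))
  b <- truth$beta[lobe, ]
  v <- b[1] + b[2] * log(age) + b[3] * age
  v <- v * if (sex == "M") truth$male_multiplier else 1
  if (isTRUE(low_income)) v <- v + truth_gap(truth, lobe, age)
  unname(v)
}

#' True low-income gap function
#' @inheritParams truth_volume
#' @return Gap in mm^3 at each age (negative: deficit).
#' @export
truth_gap <- function(truth, lobe, age) {
  lobe <- match.arg(lobe, gm_lobes())
  g <- truth$gamma[lobe, ]
  unname(g[1] * log(age) + g[2] * age)
}

# residual SD at a given age for one lobe (mm^3)
truth_resid_sd <- function(truth, lobe, age) {
  pk <- truth$targets$peak_volume[truth$targets$lobe == lobe]
  truth$sigma_resid_frac * pk * (1 + truth$resid_age_slope * age)
}
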