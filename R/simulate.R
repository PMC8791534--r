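#' Default accelerated-longitudinal design margins
#'
#' Margins of the two-protocol design emulated by the cohort generator:
#' a child/adolescent arm (OBJ1, ages 59-251 months, 1-3 scans at roughly
#' two-year intervals, recruited across six study centers) and an
#' infant/toddler arm (OBJ2, ages 5-102 months, 1-7 scans at 3-12 month
#' intervals, recruited at two of the six centers), an approximately equal
#' sex split, about a quarter of families below 200% of the federal poverty
#' level, and a small share of missing income reports.
#'
#' @return List of design margins.
#' @export
default_design <- function() {
  list(
    n_obj1 = 399L, n_obj2 = 87L,
    n_centers = 6L, obj2_centers = 1:2,
    p_male = 0.481, p_low_income = 0.26, p_missing_income = 0.026,
    obj1_scan_probs = c(0.231, 0.456, 0.311) / sum(c(0.231, 0.456, 0.311)),
    obj2_scan_probs = c(0.287, 0.310, 0.195, 0.100, 0.050, 0.035, 0.023),
    obj1_first_age_months = c(mean = 133.2, sd = 43.2, lo = 59, hi = 243.6),
    obj1_interval_months = c(lo = 20.4, hi = 27.6),
    obj1_max_age_months = 251,
    obj2_first_age_months = c(mean = 15.9, sd = 11.1, lo = 5, hi = 54),
    obj2_interval_months = c(lo = 3, hi = 12),
    obj2_max_age_months = 102,
    family_size_values = 2:6,
    family_size_probs = c(0.12, 0.38, 0.28, 0.14, 0.08),
    birth_weight = c(mean = 3541.2, sd = 472.0, lo = 1500)
  )
}

# inverse-CDF truncated normal draw (deterministic given the RNG stream)
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}

#' Generate a synthetic two-protocol cohort
#'
#' Draws a long-format scan table from the calibrated truth: subjects are
#' assigned to protocol arms, centers, sex, family income bracket and size
#' (consistent with their drawn poverty status), and per-arm scan schedules;
#' volumes are the noiseless truth plus center and subject random intercepts
#' and an age-dependent scan-level residual. The output follows the CSV
#' schema of [read_scan_table()]. A small share of subjects has the income
#' fields masked as missing (their volumes still reflect the underlying
#' drawn status, as in real data).
#'
#' @param truth a `gm_truth` from [calibrate_truth()].
#' @param n_obj1,n_obj2 subjects per arm (defaults: the study margins).
#' @param seed integer seed; the table is byte-identical across runs with
#'   the same inputs.
#' @param design design margins, see [default_design()].
#' @return Data frame of scans (one row per scan).
#' @export
generate_cohort <- function(truth, n_obj1 = NULL, n_obj2 = NULL, seed = 1L,
                            design = truth$design) {
  if (is.null(design)) design <- default_design()
  if (is.null(n_obj1)) n_obj1 <- design$n_obj1
  if (is.null(n_obj2)) n_obj2 <- design$n_obj2
  stopifnot(n_obj1 >= 1, n_obj2 >= 1)
  set.seed(as.integer(seed))
  gl <- default_guidelines()
  br <- income_brackets()

  n_sub <- n_obj1 + n_obj2
  arm <- rep(c("OBJ1", "OBJ2"), c(n_obj1, n_obj2))
  center <- integer(n_sub)
  center[arm == "OBJ1"] <- sample(seq_len(design$n_centers), n_obj1, TRUE)
  center[arm == "OBJ2"] <- sample(design$obj2_centers, n_obj2, TRUE)
  sex <- ifelse(stats::runif(n_sub) < design$p_male, "M", "F")
  low_inc <- stats::runif(n_sub) < design$p_low_income
  missing_inc <- stats::runif(n_sub) < design$p_missing_income
  fam <- sample(design$family_size_values, n_sub, TRUE,
                prob = design$family_size_probs)
  # bracket consistent with the drawn poverty status at the 200% threshold
  bracket <- character(n_sub)
  for (i in seq_len(n_sub)) {
    line <- fpl_guideline(fam[i], gl)
    ok <- if (low_inc[i]) br$midpoint / line < 2 else br$midpoint / line >= 2
    bracket[i] <- sample(br$bracket[ok], 1L)
  }
  fpl_ratio <- br$midpoint[match(bracket, br$bracket)] /
    vapply(fam, fpl_guideline, numeric(1), guidelines = gl)
  bw <- rtnorm(n_sub, design$birth_weight["mean"], design$birth_weight["sd"],
               lo = design$birth_weight["lo"])

  # per-arm scan schedules (months)
  nscan <- integer(n_sub)
  nscan[arm == "OBJ1"] <- sample(seq_along(design$obj1_scan_probs), n_obj1,
                                 TRUE, prob = design$obj1_scan_probs)
  nscan[arm == "OBJ2"] <- sample(seq_along(design$obj2_scan_probs), n_obj2,
                                 TRUE, prob = design$obj2_scan_probs)
  ages <- vector("list", n_sub)
  for (i in seq_len(n_sub)) {
    if (arm[i] == "OBJ1") {
      fa <- design$obj1_first_age_months
      iv <- design$obj1_interval_months
      amax <- design$obj1_max_age_months
    } else {
      fa <- design$obj2_first_age_months
      iv <- design$obj2_interval_months
      amax <- design$obj2_max_age_months
    }
    a <- rtnorm(1, fa["mean"], fa["sd"], fa["lo"], fa["hi"])
    if (nscan[i] > 1)
      a <- cumsum(c(a, stats::runif(nscan[i] - 1, iv["lo"], iv["hi"])))
    ages[[i]] <- round(a[a <= amax], 2)
  }
  nscan <- lengths(ages)

  sid <- sprintf("%s_%04d", arm, seq_len(n_sub))
  idx <- rep(seq_len(n_sub), nscan)
  age_m <- unlist(ages)
  age_y <- age_m / 12
  n_obs <- length(age_m)

  lobes <- gm_lobes()
  pk <- truth$targets$peak_volume[match(lobes, truth$targets$lobe)]
  cent_eff <- matrix(stats::rnorm(design$n_centers * 4), design$n_centers, 4) *
    rep(truth$sigma_center_frac * pk, each = design$n_centers)
  subj_eff <- matrix(stats::rnorm(n_sub * 4), n_sub, 4) *
    rep(truth$sigma_subject_frac * pk, each = n_sub)
  vols <- matrix(NA_real_, n_obs, 4, dimnames = list(NULL, lobes))
  for (k in seq_along(lobes)) {
    b <- truth$beta[lobes[k], ]
    vf <- b[1] + b[2] * log(age_y) + b[3] * age_y
    mu <- vf * ifelse(sex[idx] == "M", truth$male_multiplier, 1) +
      ifelse(low_inc[idx], truth_gap(truth, lobes[k], age_y), 0)
    sdr <- truth_resid_sd(truth, lobes[k], age_y)
    vols[, k] <- round(mu + cent_eff[center[idx], k] + subj_eff[idx, k] +
                         stats::rnorm(n_obs) * sdr, 1)
  }

  out <- data.frame(
    subject_id = sid[idx],
    center_id = center[idx],
    arm = arm[idx],
    sex = sex[idx],
    age_months = age_m,
    income_bracket = ifelse(missing_inc[idx], NA_character_, bracket[idx]),
    family_size = ifelse(missing_inc[idx], NA_integer_, fam[idx]),
    fpl_ratio = ifelse(missing_inc[idx], NA_real_, round(fpl_ratio[idx], 4)),
    birth_weight_g = round(bw[idx], 1),
    gm_frontal_mm3 = vols[, "frontal"],
    gm_temporal_mm3 = vols[, "temporal"],
    gm_parietal_mm3 = vols[, "parietal"],
    gm_occipital_mm3 = vols[, "occipital"],
    stringsAsFactors = FALSE)
  attr(out, "true_low_income") <- low_inc[idx]
  out
}
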