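# Shared fixtures, built in code. The cache avoids regenerating the same
# cohorts across test files within one run.
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, force(expr), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

default_truth <- function() cached("truth", calibrate_truth())

# default-size study cohort with the low-income flag derived
study_cohort <- function(seed) {
  cached(paste0("study", seed),
         derive_low_income(generate_cohort(default_truth(), seed = seed)))
}

# small cohort for bootstrap-heavy checks (100 subjects, ~215 scans)
small_cohort <- function(seed, truth = default_truth()) {
  derive_low_income(generate_cohort(truth, n_obj1 = 80, n_obj2 = 20,
                                    seed = seed))
}

# truth with no income gap and, optionally, no sex effect / scaled noise
modified_truth <- function(gap = TRUE, male_multiplier = 1.10,
                           noise_scale = 1, resid_age_slope = 0.01) {
  tr <- calibrate_truth(male_multiplier = male_multiplier,
                        sigma_center_frac = 0.015 * noise_scale,
                        sigma_subject_frac = 0.07 * noise_scale,
                        sigma_resid_frac = 0.03 * noise_scale,
                        resid_age_slope = resid_age_slope)
  if (!gap) tr$gamma[, ] <- 0
  tr
}

# hand-built multi-center longitudinal toy data with known structure
toy_lmm_data <- function(seed = 1, n_centers = 3, n_subjects = 6, n_scans = 2,
                         sd_center = 2, sd_subject = 3, sd_resid = 1) {
  set.seed(seed)
  subj <- rep(seq_len(n_subjects), each = n_scans)
  cent <- rep(rep_len(seq_len(n_centers), n_subjects), each = n_scans)
  x <- stats::runif(length(subj), 0.5, 20)
  y <- 5 + 2 * x +
    stats::rnorm(n_centers, 0, sd_center)[cent] +
    stats::rnorm(n_subjects, 0, sd_subject)[subj] +
    stats::rnorm(length(subj), 0, sd_resid)
  data.frame(subject_id = subj, center_id = cent, x = x, y = y)
}

# dense multivariate-normal log-likelihood oracle for the three-level model
dense_lmm_loglik <- function(fit) {
  it <- fit$internals
  vc <- fit$varcomps
  n <- length(it$y)
  Zc <- outer(it$cent_i, sort(unique(it$cent_i)), "==") + 0
  Zs <- outer(it$subj_i, sort(unique(it$subj_i)), "==") + 0
  V <- vc["center"] * tcrossprod(Zc) + vc["subject"] * tcrossprod(Zs) +
    vc["resid"] * diag(n)
  e <- it$y - drop(it$X %*% fit$coefficients)
  ch <- chol(V)
  -0.5 * (n * log(2 * pi) + 2 * sum(log(diag(ch))) +
            sum(backsolve(ch, e, transpose = TRUE)^2))
}

# forge a minimal gm_trajectory with prescribed coefficients, for unit
# tests of the analytic growth machinery
forged_trajectory <- function(powers, coefs_f, coefs_m = coefs_f,
                              age_range = c(0.4, 20)) {
  fit <- list(coefficients = c(
    sexF = coefs_f[1], sexM = coefs_m[1],
    `sexF:g1` = coefs_f[2], `sexM:g1` = coefs_m[2],
    `sexF:g2` = coefs_f[3], `sexM:g2` = coefs_m[3]))
  structure(list(lobe = "frontal", spec = fp_spec(powers), fit = fit,
                 age_range = age_range),
            class = "gm_trajectory")
}
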