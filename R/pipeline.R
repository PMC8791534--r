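scan_table_columns <- function() {
  c("subject_id", "center_id", "arm", "sex", "age_months", "income_bracket",
    "family_size", "fpl_ratio", "birth_weight_g", "gm_frontal_mm3",
    "gm_temporal_mm3", "gm_parietal_mm3", "gm_occipital_mm3")
}

#' Read a long-format scan table
#'
#' One row per scan. Required columns: `subject_id`, `center_id`, `arm`,
#' `sex` (F/M), `age_months` (> 0), `income_bracket`, `family_size`,
#' `fpl_ratio`, `birth_weight_g`, and the four `gm_<lobe>_mm3` volumes.
#' Either the bracket + family size or the precomputed `fpl_ratio` may be
#' blank (both only when income is missing). Malformed rows are rejected
#' with their line numbers.
#'
#' @param path CSV file.
#' @return Validated scan table (data frame).
#' @export
read_scan_table <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  miss <- setdiff(scan_table_columns(), names(d))
  if (length(miss))
    stop("scan table is missing required columns: ",
         paste(miss, collapse = ", "), call. = FALSE)
  problems <- character(0)
  bad_age <- which(!is.finite(d$age_months) | d$age_months <= 0)
  if (length(bad_age))
    problems <- c(problems, paste0("non-positive age_months at data row(s) ",
                                   paste(bad_age, collapse = ", ")))
  bad_sex <- which(!d$sex %in% c("F", "M"))
  if (length(bad_sex))
    problems <- c(problems, paste0("unknown sex code at data row(s) ",
                                   paste(bad_sex, collapse = ", ")))
  if (length(problems))
    stop("invalid scan table: ", paste(problems, collapse = "; "),
         call. = FALSE)
  d
}

#' Write a scan table
#' @param data scan table.
#' @param path CSV destination.
#' @return The path, invisibly.
#' @export
write_scan_table <- function(data, path) {
  utils::write.csv(data[scan_table_columns()], path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' @param input path to a scan-table CSV, or `NULL` to simulate a default
#'   synthetic cohort.
#' @param lobes lobes to analyze.
#' @param criterion trajectory selection criterion.
#' @param threshold_pct percent-of-FPL low-income threshold.
#' @param B bootstrap replications.
#' @param grid age grid for the income-gap scan (years).
#' @param seed top-level seed; all stage seeds derive from it.
#' @param out_dir output directory for run artifacts.
#' @param birth_weight include the birth-weight covariate in income models.
#' @param guidelines poverty guideline table.
#' @return A validated `gm_run_config` list.
#' @export
run_config <- function(input = NULL, lobes = gm_lobes(),
                       criterion = "BIC", threshold_pct = 200, B = 1000,
                       grid = seq(0.5, 20.5, by = 0.5), seed = 1L,
                       out_dir = tempfile("ngrun"), birth_weight = FALSE,
                       guidelines = default_guidelines()) {
  lobes <- match.arg(lobes, gm_lobes(), several.ok = TRUE)
  criterion <- match.arg(criterion, c("BIC", "AIC", "m2LL"))
  stopifnot(threshold_pct > 0, B >= 1, all(grid > 0), length(seed) == 1)
  structure(list(input = input, lobes = lobes, criterion = criterion,
                 threshold_pct = threshold_pct, B = B, grid = grid,
                 seed = as.integer(seed), out_dir = out_dir,
                 birth_weight = birth_weight, guidelines = guidelines),
            class = "gm_run_config")
}

#' Run the full growth-curve pipeline
#'
#' Reads (or simulates) a cohort, applies quality control (very low birth
#' weight < 1500 g excluded), derives the low-income flag, and then per
#' lobe: fractional-polynomial trajectory selection, growth curves,
#' sex-specific percentile charts, and the bootstrap income-gap analysis.
#' All artifacts (selection tables, model JSON, CSV exports, run log) are
#' written into the configured output directory; reruns with the same
#' configuration produce identical files.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with the per-lobe fitted objects and the log.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "gm_run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    log <<- c(log, msg)
    message(msg)
  }
  set.seed(config$seed)
  stage_seeds <- sample.int(.Machine$integer.max - 1L, length(config$lobes) + 1L)
  if (is.null(config$input)) {
    truth <- calibrate_truth()
    data <- generate_cohort(truth, seed = stage_seeds[1])
    write_truth(truth, file.path(config$out_dir, "generating_truth.json"))
    say("simulated default cohort: ", nrow(data), " scans, ",
        length(unique(data$subject_id)), " subjects")
  } else {
    data <- read_scan_table(config$input)
    say("read ", nrow(data), " scans from ", config$input)
  }
  qc <- !is.na(data$birth_weight_g) & data$birth_weight_g < 1500
  if (any(qc)) {
    excl <- unique(data$subject_id[qc])
    data <- data[!data$subject_id %in% excl, , drop = FALSE]
    say("excluded ", length(excl),
        " subject(s) with very low birth weight (< 1500 g): ",
        paste(excl, collapse = ", "))
  }
  data <- derive_low_income(data, config$threshold_pct, config$guidelines)
  n_missing <- length(unique(data$subject_id[is.na(data$low_income)]))
  say(n_missing, " subject(s) with missing income excluded from income models")
  results <- list()
  for (i in seq_along(config$lobes)) {
    lobe <- config$lobes[i]
    say("[", lobe, "] selecting trajectory (36 FP2 candidates, ",
        config$criterion, ")")
    traj <- gm_trajectory(data, lobe, criterion = config$criterion)
    say("[", lobe, "] selected powers (",
        paste(traj$spec$powers, collapse = ", "), ")")
    write_selection_table(traj, file.path(config$out_dir,
                                          paste0(lobe, "_selection.csv")))
    jsonlite::write_json(
      list(lobe = lobe, powers = traj$spec$powers,
           coefficients = as.list(coef(traj)),
           varcomps = as.list(traj$fit$varcomps),
           loglik = traj$fit$loglik, AIC = traj$fit$AIC, BIC = traj$fit$BIC,
           n_obs = traj$n_obs, n_subjects = traj$n_subjects),
      file.path(config$out_dir, paste0(lobe, "_model.json")),
      auto_unbox = TRUE, digits = NA)
    ages <- seq(max(traj$age_range[1], 0.45), traj$age_range[2], by = 0.1)
    gc_both <- rbind(growth_curve(traj, "F", ages),
                     growth_curve(traj, "M", ages))
    write_growth_curve(gc_both, file.path(config$out_dir,
                                          paste0(lobe, "_growth.csv")))
    res <- residuals(traj, data)
    charts <- lapply(c("F", "M"), function(s) {
      vc <- fit_variance_curve(res$resid[res$sex == s],
                               res$age_years[res$sex == s], sex = s,
                               lobe = lobe)
      percentile_chart(traj, vc, s)
    })
    write_percentile_chart(do.call(rbind, charts),
                           file.path(config$out_dir, paste0(lobe, "_chart.csv")))
    say("[", lobe, "] bootstrapping income gap (B = ", config$B, ")")
    gap <- bootstrap_gap(data, traj, B = config$B, grid = config$grid,
                         seed = stage_seeds[i + 1L],
                         birth_weight = config$birth_weight)
    write_income_gap(gap, file.path(config$out_dir, paste0(lobe, "_income.csv")))
    say("[", lobe, "] earliest detection age: ",
        ifelse(is.na(gap$earliest_sig_age), "none", gap$earliest_sig_age), " y")
    results[[lobe]] <- list(trajectory = traj, gap = gap)
  }
  jsonlite::write_json(
    list(lobes = config$lobes, criterion = config$criterion,
         threshold_pct = config$threshold_pct, B = config$B,
         grid = config$grid, seed = config$seed,
         birth_weight = config$birth_weight),
    file.path(config$out_dir, "run_config.json"), auto_unbox = TRUE,
    digits = NA)
  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  invisible(list(results = results, log = log, data = data))
}
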