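#' Summary table of the pooled C-peptide follow-up studies
#'
#' Printed summary statistics of the three longitudinal studies whose
#' aggregate plasma C-peptide series the analysis consumes: study-level N,
#' follow-up duration, sampling condition and autoantibody breakdown
#' (`n_aa_pos` + `n_aa_neg` = `n` where the stratification was reported).
#' These counts are inputs to the analysis; the synthetic study generator
#' mirrors them.
#'
#' @return A data.frame with one row per study.
#' @export
cpeptide_study_table <- function() {
  data.frame(
    study = c("study-1", "study-2", "study-3"),
    age_range = c("0.8-14.9", "<15", "7-40"),
    duration_months = c(24L, 12L, 12L),
    n = c(769L, 24L, 41L),
    n_aa_pos = c(732L, NA, 41L),
    n_aa_neg = c(37L, NA, 0L),
    sampling = c("random", "fasting", "fasting"),
    stringsAsFactors = FALSE)
}

#' Size of the pooled autopsy cohort
#'
#' Number of unique histopathology records (one per patient, ages under
#' 25, deaths 0-117 months post-diagnosis) pooled from the three autopsy
#' study series the demand-parameter fit draws on.
#'
#' @return Integer count (102).
#' @export
autopsy_cohort_size <- function() 102L

#' Read autopsy records from CSV
#'
#' Schema: `patient_id,study,age_years,months_since_diagnosis,
#' islets_deficient,islets_total,observed_ebcm` (comma separated, header
#' required, '.' decimal). Either the count pair or the fraction must be
#' present per row; when the fraction is absent it is computed as
#' deficient/total. Rows failing validation are reported with their row
#' numbers.
#'
#' @param path CSV path.
#' @return An [autopsy_records()] data.frame.
#' @export
read_autopsy_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("patient_id", "study", "age_years", "months_since_diagnosis")
  miss <- setdiff(req, names(df))
  if (length(miss) || !nrow(df))
    stop("autopsy CSV schema error (", path, "): ",
         if (length(miss)) paste("missing columns:",
                                 paste(miss, collapse = ", "))
         else "no data rows", call. = FALSE)
  if (!"observed_ebcm" %in% names(df)) df$observed_ebcm <- NA_real_
  has_counts <- all(c("islets_deficient", "islets_total") %in% names(df))
  need <- !is.finite(df$observed_ebcm)
  if (any(need)) {
    if (!has_counts)
      stop("rows without observed_ebcm need islets_deficient/islets_total: ",
           paste(which(need), collapse = ", "), call. = FALSE)
    ok <- is.finite(df$islets_deficient) & is.finite(df$islets_total) &
      df$islets_total > 0
    if (any(need & !ok))
      stop("rows with neither a valid fraction nor valid counts: ",
           paste(which(need & !ok), collapse = ", "), call. = FALSE)
    df$observed_ebcm[need] <-
      df$islets_deficient[need] / df$islets_total[need]
  }
  bad <- which(df$observed_ebcm < 0 | df$observed_ebcm > 1)
  if (length(bad))
    stop("observed_ebcm outside [0, 1] in rows: ",
         paste(bad, collapse = ", "), call. = FALSE)
  out <- data.frame(patient_id = as.character(df$patient_id),
                    study = as.character(df$study),
                    age = df$age_years,
                    time_since_diagnosis = df$months_since_diagnosis,
                    observed_ebcm = df$observed_ebcm,
                    stringsAsFactors = FALSE)
  if (has_counts) {
    out$islets_deficient <- df$islets_deficient
    out$islets_total <- df$islets_total
  }
  autopsy_records(out)
}

#' Write autopsy records to CSV
#'
#' Inverse of [read_autopsy_csv()] (lossless for all fields).
#'
#' @param records Autopsy record data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_autopsy_csv <- function(records, path) {
  df <- data.frame(patient_id = records$patient_id,
                   study = records$study,
                   age_years = records$age,
                   months_since_diagnosis = records$time_since_diagnosis,
                   observed_ebcm = records$observed_ebcm,
                   stringsAsFactors = FALSE)
  for (col in c("islets_deficient", "islets_total"))
    if (col %in% names(records)) df[[col]] <- records[[col]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read aggregate C-peptide series from CSV
#'
#' Schema: `study,months_since_diagnosis,mean_nmol_per_L,se_nmol_per_L,n,
#' stratum,sampling`.
#'
#' @param path CSV path.
#' @return A [cpeptide_aggregates()] data.frame.
#' @export
read_cpeptide_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("study", "months_since_diagnosis", "mean_nmol_per_L",
           "se_nmol_per_L", "n")
  miss <- setdiff(req, names(df))
  if (length(miss) || !nrow(df))
    stop("C-peptide CSV schema error (", path, "): ",
         if (length(miss)) paste("missing columns:",
                                 paste(miss, collapse = ", "))
         else "no data rows", call. = FALSE)
  out <- data.frame(study = as.character(df$study),
                    time_since_diagnosis = df$months_since_diagnosis,
                    mean = df$mean_nmol_per_L,
                    se = df$se_nmol_per_L,
                    n = df$n,
                    stringsAsFactors = FALSE)
  for (col in c("stratum", "sampling"))
    if (col %in% names(df)) out[[col]] <- as.character(df[[col]])
  cpeptide_aggregates(out)
}

#' Write aggregate C-peptide series to CSV
#'
#' Inverse of [read_cpeptide_csv()].
#'
#' @param aggregates A [cpeptide_aggregates()] data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cpeptide_csv <- function(aggregates, path) {
  df <- data.frame(study = aggregates$study,
                   months_since_diagnosis = aggregates$time_since_diagnosis,
                   mean_nmol_per_L = aggregates$mean,
                   se_nmol_per_L = aggregates$se,
                   n = aggregates$n,
                   stringsAsFactors = FALSE)
  for (col in c("stratum", "sampling"))
    if (col %in% names(aggregates)) df[[col]] <- aggregates[[col]]
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize / read model parameters as JSON
#'
#' @param model A `physiology_model`.
#' @param path JSON path.
#' @return For `write_model_json`, `path` invisibly; for
#'   `read_model_json`, the parameter list
#'   (`alpha`, `gamma`, `qmax`, `kclr`, `rho`).
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "physiology_model"))
  jsonlite::write_json(list(alpha = model$alpha, gamma = model$gamma,
                            qmax = model$qmax, kclr = model$kclr,
                            rho = model$rho),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Run the full analysis pipeline
#'
#' Chains every stage on one seed: simulate (or load) the autopsy cohort
#' and the C-peptide study aggregates; fit the demand parameter alpha on
#' the recent-onset under-20 subset; compute predicted-minus-observed EBCM
#' residuals under the fitted model; smooth with the moving average; align
#' with the C-peptide timepoints; run the weighted MCMC regression; and
#' write `autopsy.csv`, `cpeptide.csv`, `residuals.csv`, `pairs.csv`,
#' `posterior.json` and `report.json` under `out_dir`. Every output embeds
#' the master seed and package version.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed (drives simulation and MCMC).
#' @param model A `physiology_model` used to simulate (its alpha is the
#'   simulation ground truth) and whose curves are reused for fitting.
#' @param cohort_cfg,study_cfg Generator configs; their `seed` is
#'   overridden by `seed`. Ignored when CSV paths are given.
#' @param autopsy_csv,cpeptide_csv Optional paths to existing input CSVs
#'   (skips simulation of that stream).
#' @param window Moving-average window (default 9).
#' @param mcmc An [mcmc_config()]; its `seed` is overridden by `seed`.
#' @param onset_cutoff,age_max Recent-onset filter settings for the alpha
#'   fit.
#' @param quiet Suppress stage messages.
#' @return The report, as a list (also written to `report.json`).
#' @export
run_pipeline <- function(out_dir, seed = 1, model = default_model(),
                         cohort_cfg = cohort_config(),
                         study_cfg = study_config(),
                         autopsy_csv = NULL, cpeptide_csv = NULL,
                         window = 9, mcmc = mcmc_config(),
                         onset_cutoff = 0.75, age_max = 20,
                         quiet = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message("[ebcm] ", ...)

  if (is.null(autopsy_csv)) {
    cohort_cfg$seed <- as.integer(seed)
    records <- generate_autopsy_cohort(cohort_cfg, model)
    say("simulated ", nrow(records), " autopsy records")
  } else {
    records <- read_autopsy_csv(autopsy_csv)
    say("read ", nrow(records), " autopsy records from ", autopsy_csv)
  }
  write_autopsy_csv(records, file.path(out_dir, "autopsy.csv"))

  if (is.null(cpeptide_csv)) {
    study_cfg$seed <- as.integer(seed) + 500L
    aggregates <- generate_cpeptide_aggregates(study_cfg, model)
    say("simulated ", nrow(aggregates), " C-peptide timepoints")
  } else {
    aggregates <- read_cpeptide_csv(cpeptide_csv)
    say("read ", nrow(aggregates), " C-peptide timepoints from ",
        cpeptide_csv)
  }
  write_cpeptide_csv(aggregates, file.path(out_dir, "cpeptide.csv"))

  recent <- recent_onset_filter(records, cutoff = onset_cutoff)
  alpha_est <- fit_alpha(recent, model = model, method = "wls",
                         age_max = age_max)
  say(sprintf("alpha = %.1f (95%% CI %.1f-%.1f) from %d recent-onset records",
              alpha_est$alpha_hat, alpha_est$ci_low, alpha_est$ci_high,
              alpha_est$n_used))

  fitted_model <- physiology_model(model$weight_curve, model$bcm_curve,
                                   alpha = alpha_est$alpha_hat,
                                   qmax = model$qmax, kclr = model$kclr,
                                   rho = model$rho, gamma = model$gamma)
  resid <- residual_series(records, fitted_model)
  utils::write.csv(resid, file.path(out_dir, "residuals.csv"),
                   row.names = FALSE)
  smoothed <- moving_average(resid, window = window)
  say(nrow(smoothed), " moving-average windows over [",
      signif(min(smoothed$time), 4), ", ", signif(max(smoothed$time), 4),
      "] months")

  pairs <- align_with_cpeptide(smoothed, aggregates)
  utils::write.csv(pairs, file.path(out_dir, "pairs.csv"),
                   row.names = FALSE)
  say(nrow(pairs), " paired observations")

  mcmc$seed <- as.integer(seed)
  post <- run_regression(regression_data(pairs), mcmc)
  summ <- posterior_summary(post)
  say(sprintf("P(slope > 0) = %.4f (PSRF %.3f/%.3f)",
              post$p_slope_positive, post$psrf[1], post$psrf[2]))

  version <- as.character(utils::packageVersion("ebcm"))
  jsonlite::write_json(
    list(seed = seed, package_version = version,
         parameters = summ,
         p_slope_positive = post$p_slope_positive,
         slope_intercept_correlation = post$slope_intercept_correlation,
         acceptance_fraction = post$acceptance_fraction,
         psrf = as.list(post$psrf),
         burn_in = post$burn_in),
    file.path(out_dir, "posterior.json"), auto_unbox = TRUE, digits = NA)

  report <- list(
    seed = seed,
    package_version = version,
    n_records = nrow(records),
    n_recent_onset_under20 = sum(records$time_since_diagnosis <=
                                   onset_cutoff & records$age < age_max),
    alpha = list(estimate = alpha_est$alpha_hat,
                 ci_low = alpha_est$ci_low, ci_high = alpha_est$ci_high,
                 n_used = alpha_est$n_used, method = alpha_est$method),
    n_pairs = nrow(pairs),
    slope_mean = mean(post$slope_samples),
    intercept_mean = mean(post$intercept_samples),
    psrf = as.list(post$psrf),
    acceptance_fraction = post$acceptance_fraction,
    p_slope_positive = post$p_slope_positive,
    significant = post$p_slope_positive > 0.95)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(report)
}
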