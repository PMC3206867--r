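#' Post-onset recovery/decline kernel
#'
#' Noiseless trajectory of predicted-minus-observed EBCM after diagnosis:
#' a unimodal recovery `A * (t/t_peak) * exp(1 - t/t_peak)` peaking at
#' `t_peak` months with height `A`, followed by a linear late decline
#' `-d * max(0, t - t_peak)`. For `A > 0, d >= 0` the kernel rises to a
#' unique maximum at `t_peak` (about 10 weeks by default) and then
#' declines: a transient partial recovery of beta cell mass after onset
#' followed by progressive loss.
#'
#' @param t Months since diagnosis (>= 0).
#' @param A Recovery amplitude (dimensionless EBCM units; default 0.005:
#'   the post-onset rise is slight relative to the islet-count assay
#'   noise, so predicted and observed EBCM agree closely inside the
#'   three-week recent-onset window the demand-parameter fit relies on).
#' @param t_peak Time of peak recovery in months (default 2.3, ~10 weeks).
#' @param d Late decline rate per month (default 0.005).
#' @return Kernel values, same length as `t`.
#' @export
recovery_kernel <- function(t, A = 0.005, t_peak = 2.3, d = 0.005) {
  stopifnot(t_peak > 0)
  A * (t / t_peak) * exp(1 - t / t_peak) - d * pmax(0, t - t_peak)
}

#' Synthetic autopsy cohort configuration
#'
#' Defaults mirror the published cohort shape: 102 records, ages under 25,
#' deaths between 0 and 117 months after diagnosis, with exactly 60
#' recent-onset (death within three weeks) patients under age 20.
#'
#' @param n_patients Cohort size (default 102).
#' @param n_recent_onset_under20 Records forced into the (age < 20,
#'   time <= `onset_cutoff`) cell (default 60).
#' @param age_range Years (default c(0.5, 25)).
#' @param time_range Months since diagnosis (default c(0, 117)).
#' @param onset_cutoff Recent-onset window in months (default 0.75, i.e.
#'   three weeks).
#' @param ebcm_noise_sd Gaussian noise on observed EBCM (default 0.08).
#' @param A,t_peak,d [recovery_kernel()] parameters.
#' @param seed Integer seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_patients = 102, n_recent_onset_under20 = 60,
                          age_range = c(0.5, 25), time_range = c(0, 117),
                          onset_cutoff = 0.75, ebcm_noise_sd = 0.08,
                          A = 0.005, t_peak = 2.3, d = 0.005, seed = 1) {
  if (n_patients < 1 || n_recent_onset_under20 < 0)
    stop("counts must be positive", call. = FALSE)
  if (n_recent_onset_under20 > n_patients)
    stop("recent-onset quota exceeds the cohort size", call. = FALSE)
  if (ebcm_noise_sd < 0) stop("noise sd must be >= 0", call. = FALSE)
  stopifnot(length(age_range) == 2, age_range[1] < age_range[2],
            length(time_range) == 2, time_range[1] <= time_range[2],
            t_peak > 0)
  structure(list(n_patients = as.integer(n_patients),
                 n_recent_onset_under20 = as.integer(n_recent_onset_under20),
                 age_range = age_range, time_range = time_range,
                 onset_cutoff = onset_cutoff,
                 ebcm_noise_sd = ebcm_noise_sd,
                 A = A, t_peak = t_peak, d = d, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a seeded synthetic autopsy cohort
#'
#' Ages are drawn uniformly (the source studies publish no age
#' distribution); the recent-onset quota is met by sampling exactly
#' `n_recent_onset_under20` records with age below 20 and death within the
#' onset window, while the remaining records are resampled out of that
#' cell. The latent observed EBCM is the model prediction minus the
#' recovery kernel plus Gaussian noise, clamped to [0, 1] (islet fractions
#' are proportions):
#' `observed = clamp01(ebcm_pred(age) - r(t) + e)`, so the
#' predicted-minus-observed residual follows the rise-then-decline kernel.
#'
#' @param cfg A [cohort_config()].
#' @param model A `physiology_model` whose curves cover `age_range`.
#' @return An [autopsy_records()] data.frame with a `recent_onset` flag.
#' @export
generate_autopsy_cohort <- function(cfg = cohort_config(),
                                    model = default_model()) {
  stopifnot(inherits(cfg, "cohort_config"),
            inherits(model, "physiology_model"))
  set.seed(cfg$seed)
  n_r <- cfg$n_recent_onset_under20
  n_o <- cfg$n_patients - n_r
  age_r <- stats::runif(n_r, cfg$age_range[1], min(20, cfg$age_range[2]))
  t_r <- stats::runif(n_r, max(0, cfg$time_range[1]),
                      min(cfg$onset_cutoff, cfg$time_range[2]))
  age_o <- stats::runif(n_o, cfg$age_range[1], cfg$age_range[2])
  t_o <- stats::runif(n_o, cfg$time_range[1], cfg$time_range[2])
  # keep the quota exact: resample any stray draw landing in the
  # recent-onset-under-20 cell
  in_cell <- age_o < 20 & t_o <= cfg$onset_cutoff
  while (any(in_cell)) {
    k <- sum(in_cell)
    age_o[in_cell] <- stats::runif(k, cfg$age_range[1], cfg$age_range[2])
    t_o[in_cell] <- stats::runif(k, cfg$time_range[1], cfg$time_range[2])
    in_cell <- age_o < 20 & t_o <= cfg$onset_cutoff
  }
  age <- c(age_r, age_o)
  tsd <- c(t_r, t_o)
  pred <- excess_bcm(model, age)$ebcm
  eps <- stats::rnorm(cfg$n_patients, 0, cfg$ebcm_noise_sd)
  obs <- pred - recovery_kernel(tsd, cfg$A, cfg$t_peak, cfg$d) + eps
  obs <- pmin(pmax(obs, 0), 1)
  autopsy_records(data.frame(
    patient_id = sprintf("P%03d", seq_len(cfg$n_patients)),
    study = rep(c("synthA", "synthB", "synthC"),
                length.out = cfg$n_patients),
    age = age,
    time_since_diagnosis = tsd,
    observed_ebcm = obs,
    recent_onset = tsd <= cfg$onset_cutoff & age < 20,
    stringsAsFactors = FALSE))
}

#' Synthetic C-peptide study configuration
#'
#' Defaults emulate the three pooled follow-up studies: one large
#' 24-month study of 769 children reporting random C-peptide, and two
#' 12-month studies of 24 and 41 patients reporting fasting C-peptide.
#'
#' @param studies List of study descriptors, each a list with `label`,
#'   `n`, `timepoints` (months), `stratum`, `sampling`.
#' @param gamma nmol/L of plasma C-peptide per set-point insulin unit
#'   (default 0.0012, putting post-onset means near 0.3 nmol/L at the
#'   default model).
#' @param cpep_noise_sd Per-patient C-peptide SD in nmol/L (default 0.3);
#'   study-level SE scales as `cpep_noise_sd / sqrt(n)`.
#' @param baseline_deficit Relative functional deficit at onset (default
#'   0.5) from which the recovery kernel moves the mean.
#' @param A,t_peak,d [recovery_kernel()] parameters (keep equal to the
#'   cohort config so both data streams share one latent trajectory).
#' @param seed Integer seed.
#' @return A list of class `study_config`.
#' @export
study_config <- function(studies = NULL, gamma = 0.0012,
                         cpep_noise_sd = 0.3, baseline_deficit = 0.5,
                         A = 0.005, t_peak = 2.3, d = 0.005, seed = 1) {
  if (is.null(studies))
    studies <- list(
      list(label = "synth-large", n = 769,
           timepoints = c(3, 6, 12, 18, 24),
           stratum = "mixed", sampling = "random"),
      list(label = "synth-small-1", n = 24, timepoints = c(3, 6, 9, 12),
           stratum = "mixed", sampling = "fasting"),
      list(label = "synth-small-2", n = 41, timepoints = c(3, 6, 9, 12),
           stratum = "AA+", sampling = "fasting"))
  for (s in studies)
    if (s$n < 1) stop("study sample sizes must be >= 1", call. = FALSE)
  stopifnot(gamma > 0, cpep_noise_sd >= 0, t_peak > 0)
  structure(list(studies = studies, gamma = gamma,
                 cpep_noise_sd = cpep_noise_sd,
                 baseline_deficit = baseline_deficit,
                 A = A, t_peak = t_peak, d = d, seed = as.integer(seed)),
            class = "study_config")
}

#' Generate seeded synthetic C-peptide study aggregates
#'
#' Per study timepoint, the mean plasma C-peptide is the fasting set-point
#' scaled by the residual functional fraction,
#' `mean = gamma * max(0, setpoint * (1 - deficit(t)))` with
#' `deficit(t) = baseline_deficit - r(t)`, plus Gaussian noise of the
#' study-level standard error `cpep_noise_sd / sqrt(n)`; so C-peptide
#' shares the rise-then-decline latent trajectory of the autopsy residuals.
#'
#' @param cfg A [study_config()].
#' @param model A `physiology_model` (supplies the fasting set-point
#'   `qmax * rho * alpha / kclr`).
#' @return A [cpeptide_aggregates()] data.frame.
#' @export
generate_cpeptide_aggregates <- function(cfg = study_config(),
                                         model = default_model()) {
  stopifnot(inherits(cfg, "study_config"),
            inherits(model, "physiology_model"))
  set.seed(cfg$seed)
  setpoint <- model$qmax * model$rho * model$alpha / model$kclr
  rows <- lapply(cfg$studies, function(s) {
    t <- s$timepoints
    deficit <- cfg$baseline_deficit -
      recovery_kernel(t, cfg$A, cfg$t_peak, cfg$d)
    se <- cfg$cpep_noise_sd / sqrt(s$n)
    mu <- cfg$gamma * pmax(0, setpoint * (1 - deficit))
    data.frame(study = s$label,
               time_since_diagnosis = t,
               mean = mu + stats::rnorm(length(t), 0, se),
               se = se,
               n = s$n,
               stratum = s$stratum,
               sampling = s$sampling,
               stringsAsFactors = FALSE)
  })
  cpeptide_aggregates(do.call(rbind, rows))
}

#' Generate seeded synthetic regression pairs
#'
#' Draws `n` x-values uniformly on `x_range` and
#' `y = slope * x + intercept + e` with
#' `e ~ Normal(0, noise_sd / sqrt(w))`, where the weights are normalized
#' to mean 1 so `noise_sd` is the noise scale of an average-weight point.
#' Used to unit-test the weighted regression engine against known truth.
#'
#' @param slope,intercept True line parameters.
#' @param n Number of pairs (>= 3).
#' @param x_range Length-2 range for x (non-degenerate).
#' @param noise_sd Noise scale (>= 0).
#' @param weights Per-point sample sizes (recycled; default equal).
#' @param seed Integer seed.
#' @return A paired-observation data.frame (`x`, `x_sd`, `y`, `y_se`,
#'   `weight`) suitable for [regression_data()].
#' @export
generate_regression_pairs <- function(slope, intercept, n,
                                      x_range = c(-0.3, 0.5),
                                      noise_sd = 0.02, weights = NULL,
                                      seed = 1) {
  if (n < 3) stop("need n >= 3 pairs", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (length(x_range) != 2 || x_range[1] >= x_range[2])
    stop("x_range must be a non-degenerate interval", call. = FALSE)
  if (is.null(weights)) weights <- rep(1, n)
  weights <- rep_len(weights, n)
  if (any(!is.finite(weights) | weights <= 0))
    stop("weights must be positive", call. = FALSE)
  w_norm <- weights * n / sum(weights)
  set.seed(seed)
  x <- sort(stats::runif(n, x_range[1], x_range[2]))
  sd_i <- noise_sd / sqrt(w_norm)
  data.frame(x = x,
             x_sd = 0,
             y = slope * x + intercept + stats::rnorm(n, 0, sd_i),
             y_se = sd_i,
             weight = weights)
}
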