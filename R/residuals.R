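#' Predicted-minus-observed EBCM residual series
#'
#' For every autopsy record, the model predicts the excess beta cell mass
#' for the patient's age; the residual `delta_ebcm = predicted - observed`
#' tracks how beta cell mass moves after onset. Positive values mean fewer
#' insulin-deficient islets than the age-corrected expectation (recovery of
#' mass after onset); negative values mean further decline.
#'
#' @param records Autopsy record data.frame.
#' @param model A `physiology_model` (typically with the fitted alpha).
#' @return A data.frame with `patient_id`, `time_since_diagnosis` (months),
#'   `delta_ebcm`, sorted by time since diagnosis with ties broken by
#'   `patient_id`.
#' @export
residual_series <- function(records, model) {
  stopifnot(inherits(model, "physiology_model"))
  pred <- excess_bcm(model, records$age)$ebcm
  out <- data.frame(patient_id = records$patient_id,
                    time_since_diagnosis = records$time_since_diagnosis,
                    delta_ebcm = pred - records$observed_ebcm,
                    stringsAsFactors = FALSE)
  out[order(out$time_since_diagnosis, out$patient_id), , drop = FALSE]
}

#' Centered moving average and moving standard deviation
#'
#' Smooths an ordered series with full centered windows of `window`
#' consecutive points (default 9). Only full windows are produced (no edge
#' shrinkage), so `n` points yield `n - window + 1` windows; each window is
#' centered at the time of its middle point and reports the window mean and
#' sample standard deviation (denominator `window - 1`).
#'
#' @param values Ordered numeric series (e.g. `delta_ebcm` sorted by time),
#'   or a `residual_series()` data.frame.
#' @param times Times of the points (months); defaults to the index, or the
#'   `time_since_diagnosis` column when `values` is a residual data.frame.
#' @param window Odd window length, `<= length(values)`. Default 9.
#' @return A data.frame of class `smoothed_series` with `time`, `mean`,
#'   `sd`; attribute `window`.
#' @export
moving_average <- function(values, times = NULL, window = 9) {
  if (is.data.frame(values)) {
    if (is.null(times)) times <- values$time_since_diagnosis
    values <- values$delta_ebcm
  }
  n <- length(values)
  if (is.null(times)) times <- seq_len(n)
  if (length(times) != n)
    stop("times and values must have equal length", call. = FALSE)
  if (window %% 2 != 1 || window < 1)
    stop("window must be a positive odd integer", call. = FALSE)
  if (n < window)
    stop("need at least ", window, " points for a ", window,
         "-point moving average; reduce the window or add data",
         call. = FALSE)
  half <- (window - 1) / 2
  centers <- (half + 1):(n - half)
  out <- data.frame(
    time = times[centers],
    mean = as.numeric(zoo::rollmean(values, window)),
    sd = as.numeric(zoo::rollapply(values, window, stats::sd))
  )
  structure(out, window = window,
            class = c("smoothed_series", class(out)))
}

#' Validate a table of aggregate C-peptide study timepoints
#'
#' One row per study timepoint: `study` label, `time_since_diagnosis`
#' (months), `mean` and `se` (nmol/L), `n` participants, plus optional
#' `stratum` (autoantibody status: "AA+", "AA-", "mixed") and `sampling`
#' ("fasting" or "random").
#'
#' @param df A data.frame with the columns above.
#' @return The validated data.frame.
#' @export
cpeptide_aggregates <- function(df) {
  req <- c("study", "time_since_diagnosis", "mean", "se", "n")
  miss <- setdiff(req, names(df))
  if (length(miss))
    stop("C-peptide table missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(!is.finite(df$se) | df$se < 0))
    stop("standard errors must be non-negative", call. = FALSE)
  if (any(!is.finite(df$n) | df$n < 1))
    stop("sample sizes must be >= 1", call. = FALSE)
  if (any(!is.finite(df$time_since_diagnosis) | df$time_since_diagnosis < 0))
    stop("times since diagnosis must be non-negative", call. = FALSE)
  df
}

#' Pair C-peptide timepoints with the smoothed residual trajectory
#'
#' For each aggregate C-peptide timepoint falling inside the span of the
#' smoothed window centers, reads the smoothed predicted-minus-observed
#' EBCM (and its moving SD) at the same time since diagnosis, by linear
#' interpolation between window centers (or nearest-center lookup).
#' Timepoints outside the span cannot be matched and are dropped with a
#' warning.
#'
#' @param smoothed A [moving_average()] result.
#' @param aggregates A [cpeptide_aggregates()] table.
#' @param method `"linear"` (default) or `"nearest"`.
#' @return A data.frame of paired observations: `study`,
#'   `time_since_diagnosis`, `x` (smoothed delta EBCM), `x_sd`, `y`
#'   (C-peptide mean, nmol/L), `y_se`, `weight` (study sample size), plus
#'   `stratum`/`sampling` when present.
#' @export
align_with_cpeptide <- function(smoothed, aggregates,
                                method = c("linear", "nearest")) {
  method <- match.arg(method)
  if (!nrow(smoothed))
    stop("smoothed series is empty", call. = FALSE)
  aggregates <- cpeptide_aggregates(aggregates)
  lo <- min(smoothed$time); hi <- max(smoothed$time)
  inside <- aggregates$time_since_diagnosis >= lo &
    aggregates$time_since_diagnosis <= hi
  if (!any(inside))
    stop("no C-peptide timepoints fall inside the smoothed residual span [",
         signif(lo, 4), ", ", signif(hi, 4), "] months", call. = FALSE)
  if (any(!inside))
    warning(sum(!inside), " C-peptide timepoint(s) outside the smoothed ",
            "span [", signif(lo, 4), ", ", signif(hi, 4),
            "] months were excluded", call. = FALSE)
  agg <- aggregates[inside, , drop = FALSE]
  interp <- function(v) {
    if (method == "linear")
      stats::approx(smoothed$time, v, xout = agg$time_since_diagnosis,
                    ties = "ordered")$y
    else
      v[vapply(agg$time_since_diagnosis,
               function(t) which.min(abs(smoothed$time - t)), integer(1))]
  }
  out <- data.frame(study = agg$study,
                    time_since_diagnosis = agg$time_since_diagnosis,
                    x = interp(smoothed$mean),
                    x_sd = interp(smoothed$sd),
                    y = agg$mean,
                    y_se = agg$se,
                    weight = agg$n,
                    stringsAsFactors = FALSE)
  for (col in c("stratum", "sampling"))
    if (col %in% names(agg)) out[[col]] <- agg[[col]]
  out
}
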