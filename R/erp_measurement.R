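# Condition-wise ERP averaging and the two measurement types: windowed mean
# amplitude, and negative-peak amplitude/latency over ROIs.

#' Average retained epochs of one condition
#'
#' @param epochs An `erp_epochs` after rejection.
#' @param condition `"own"` or `"stranger"`.
#' @return An `erp_average`: `data` (channels x samples matrix), `channels`,
#'   `times_ms`, `sampling_rate`, `n_trials`, `condition`, `modality`.
#' @export
average_epochs <- function(epochs, condition) {
  idx <- retained_epochs(epochs, condition)
  if (length(idx) == 0) stop("no retained epochs for condition ", condition)
  data <- colMeans(epochs$data[idx, , , drop = FALSE])  # mean over trials
  rownames(data) <- epochs$channels$label
  structure(list(data = data, channels = epochs$channels,
                 times_ms = epochs$times_ms,
                 sampling_rate = epochs$sampling_rate,
                 n_trials = length(idx), condition = condition,
                 modality = epochs$modality),
            class = "erp_average")
}

#' @export
print.erp_average <- function(x, ...) {
  cat(sprintf("<erp_average> %s/%s: %d trials, %d ch x %d samples\n",
              x$modality, x$condition, x$n_trials, nrow(x$data),
              ncol(x$data)))
  invisible(x)
}

roi_channel_rows <- function(erp, roi) {
  idx <- match(roi$channels, rownames(erp$data))
  if (anyNA(idx))
    stop("ROI channel(s) missing from the average: ",
         paste(roi$channels[is.na(idx)], collapse = ", "))
  idx
}

#' Windowed mean amplitude over a ROI
#'
#' Averages all data points of the ROI channels within the half-open window
#' `[t_start, t_end)`.
#'
#' @param erp An `erp_average`.
#' @param roi A [roi_spec()].
#' @param window Numeric `c(t_start, t_end)` in ms.
#' @return Mean amplitude in microvolts.
#' @export
mean_amplitude <- function(erp, roi, window) {
  idx <- roi_channel_rows(erp, roi)
  sel <- erp$times_ms >= window[1] & erp$times_ms < window[2]
  if (!any(sel)) stop("window contains no samples")
  mean(erp$data[idx, sel])
}

#' Negative-peak amplitude and latency over a ROI
#'
#' Per ROI channel, finds the most negative sample within the half-open
#' window (ties resolved to the earliest latency), then averages the
#' per-channel peak amplitudes and latencies ("averaging the peaks").
#'
#' @param erp An `erp_average`.
#' @param roi A [roi_spec()].
#' @param window Numeric `c(t_start, t_end)` in ms.
#' @param peak_of_average If `TRUE`, instead measures the single peak of the
#'   ROI-averaged waveform (sensitivity alternative; default `FALSE`).
#' @return Named numeric `c(amplitude_uV, latency_ms)`.
#' @export
negative_peak <- function(erp, roi, window, peak_of_average = FALSE) {
  idx <- roi_channel_rows(erp, roi)
  sel <- which(erp$times_ms >= window[1] & erp$times_ms < window[2])
  if (!length(sel)) stop("window contains no samples")
  if (peak_of_average) {
    wave <- colMeans(erp$data[idx, sel, drop = FALSE])
    k <- which.min(wave)  # which.min takes the first of tied minima
    return(c(amplitude_uV = wave[k], latency_ms = erp$times_ms[sel][k]))
  }
  amps <- numeric(length(idx)); lats <- numeric(length(idx))
  for (i in seq_along(idx)) {
    wave <- erp$data[idx[i], sel]
    k <- which.min(wave)
    amps[i] <- wave[k]
    lats[i] <- erp$times_ms[sel][k]
  }
  c(amplitude_uV = mean(amps), latency_ms = mean(lats))
}

#' Long-format measurement table for a processed cohort
#'
#' For every included subject, condition, and analysis-plan row, computes the
#' planned measure(s): `mean_amplitude_uV` for mean-amplitude windows,
#' `peak_amplitude_uV` and `peak_latency_ms` for negative-peak windows.
#'
#' @param processed List of per-subject entries, each with `subject_id`,
#'   `group`, and `epochs` (list with `auditory`/`visual` `erp_epochs`).
#' @param plan Analysis plan data.frame (default [default_analysis_plan()]).
#' @param rois Named list of ROIs (default [default_rois()]).
#' @param min_trials Inclusion threshold per condition (default 10).
#' @return List with `measurements` (long data.frame: subject, group,
#'   modality, condition, roi, window, measure, value, n_trials),
#'   `inclusion` (per subject x modality), and `counts`.
#' @export
build_measurement_table <- function(processed, plan = default_analysis_plan(),
                                    rois = default_rois(), min_trials = 10) {
  counts <- do.call(rbind, lapply(processed, function(s) {
    do.call(rbind, lapply(c("auditory", "visual"), function(mod) {
      data.frame(subject = s$subject_id, modality = mod,
                 condition = c("own", "stranger"),
                 n_retained = c(length(retained_epochs(s$epochs[[mod]], "own")),
                                length(retained_epochs(s$epochs[[mod]], "stranger"))))
    }))
  }))
  inclusion <- apply_inclusion(counts, min_trials)

  rows <- list()
  for (s in processed) {
    for (mod in unique(plan$modality)) {
      inc <- inclusion$included[inclusion$subject == s$subject_id &
                                inclusion$modality == mod]
      if (!isTRUE(inc[1])) next
      pl <- plan[plan$modality == mod, ]
      for (cond in c("own", "stranger")) {
        erp <- average_epochs(s$epochs[[mod]], cond)
        for (r in seq_len(nrow(pl))) {
          roi <- rois[[pl$roi[r]]]
          win <- c(pl$t_start[r], pl$t_end[r])
          vals <- if (pl$measure[r] == "mean_amplitude") {
            c(mean_amplitude_uV = mean_amplitude(erp, roi, win))
          } else {
            pk <- negative_peak(erp, roi, win)
            c(peak_amplitude_uV = unname(pk["amplitude_uV"]),
              peak_latency_ms = unname(pk["latency_ms"]))
          }
          for (mname in names(vals)) {
            rows[[length(rows) + 1L]] <- data.frame(
              subject = s$subject_id, group = s$group, modality = mod,
              condition = cond, roi = pl$roi[r], window = pl$window[r],
              measure = mname, value = unname(vals[mname]),
              n_trials = erp$n_trials)
          }
        }
      }
    }
  }
  measurements <- if (length(rows)) do.call(rbind, rows) else
    data.frame(subject = character(0), group = character(0),
               modality = character(0), condition = character(0),
               roi = character(0), window = character(0),
               measure = character(0), value = numeric(0),
               n_trials = integer(0))
  list(measurements = measurements, inclusion = inclusion, counts = counts)
}

#' Grand-average waveform across subjects
#'
#' Unweighted mean across subject averages (not trial-count-weighted), per
#' condition, optionally within one group.
#'
#' @param processed As in [build_measurement_table()].
#' @param modality `"auditory"` or `"visual"`.
#' @param condition `"own"` or `"stranger"`.
#' @param group Optional group filter (`"ten"`/`"one"`).
#' @param min_trials Inclusion threshold (default 10).
#' @return An `erp_average` with `n_trials` = number of subjects averaged.
#' @export
grand_average <- function(processed, modality, condition, group = NULL,
                          min_trials = 10) {
  mats <- list()
  proto <- NULL
  for (s in processed) {
    if (!is.null(group) && s$group != group) next
    ep <- s$epochs[[modality]]
    n_own <- length(retained_epochs(ep, "own"))
    n_str <- length(retained_epochs(ep, "stranger"))
    if (n_own < min_trials || n_str < min_trials) next
    erp <- average_epochs(ep, condition)
    mats[[length(mats) + 1L]] <- erp$data
    proto <- erp
  }
  if (!length(mats)) stop("no included subjects for the grand average")
  proto$data <- Reduce(`+`, mats) / length(mats)
  proto$n_trials <- length(mats)
  proto
}
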