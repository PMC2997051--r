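# Continuous EEG -> clean epochs: zero-phase FIR band-pass, linked-mastoid
# re-reference, epoching, baseline correction, gliding-window artifact
# rejection, subject inclusion.

#' Band-pass filter specification
#'
#' The default is the offline filter applied as the first editing step on the
#' continuous EEG: 0.3-20 Hz, 1501 points, zero phase. The online acquisition
#' low-pass (0.27 x sampling rate = 67.5 Hz at 250 Hz) precedes digitization
#' and is recorded here as a constant for documentation/consistency checks
#' only; it is not re-applied offline.
#'
#' @param low_cut_Hz High-pass edge (default 0.3).
#' @param high_cut_Hz Low-pass edge (default 20).
#' @param n_taps Odd FIR length (default 1501).
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(low_cut_Hz = 0.3, high_cut_Hz = 20, n_taps = 1501) {
  stopifnot(low_cut_Hz >= 0, low_cut_Hz < high_cut_Hz, n_taps %% 2 == 1)
  structure(list(low_cut_Hz = low_cut_Hz, high_cut_Hz = high_cut_Hz,
                 n_taps = n_taps, phase = "zero_phase"),
            class = "filter_spec")
}

#' Online acquisition low-pass cutoff
#'
#' @param sampling_rate Hz (default 250).
#' @param fraction Cutoff as a fraction of the sampling rate (default 0.27).
#' @return Cutoff in Hz (67.5 at the defaults).
#' @export
acquisition_lowpass_Hz <- function(sampling_rate = 250, fraction = 0.27) {
  fraction * sampling_rate
}

#' Hamming windowed-sinc band-pass FIR taps
#'
#' @param spec A [filter_spec()].
#' @param sampling_rate Hz.
#' @return Numeric vector of `n_taps` symmetric (linear-phase) coefficients.
#' @export
design_fir <- function(spec, sampling_rate) {
  if (spec$high_cut_Hz >= sampling_rate / 2)
    stop("high cutoff must be below the Nyquist frequency")
  m <- (spec$n_taps - 1) / 2
  k <- (-m):m
  sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))
  f1 <- spec$low_cut_Hz / sampling_rate
  f2 <- spec$high_cut_Hz / sampling_rate
  h <- 2 * f2 * sinc(2 * f2 * k) - 2 * f1 * sinc(2 * f1 * k)
  h * (0.54 + 0.46 * cos(pi * k / m))
}

#' Frequency response magnitude of a designed filter
#'
#' @param taps FIR coefficients.
#' @param freq_Hz Frequencies to evaluate.
#' @param sampling_rate Hz.
#' @return Magnitude of the response at each frequency.
#' @export
filter_response <- function(taps, freq_Hz, sampling_rate) {
  n <- length(taps)
  vapply(freq_Hz, function(f)
    Mod(sum(taps * exp(-2i * pi * f / sampling_rate * (0:(n - 1))))), 0)
}

# Zero-phase application of a symmetric linear-phase FIR to the rows of a
# matrix: reflection-pad by the group delay on both ends, FFT-convolve all
# channels at once, compensate the delay exactly.
zero_phase_filter <- function(x, taps) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  m <- (length(taps) - 1) / 2
  n <- ncol(x)
  if (n <= length(taps)) stop("recording shorter than the filter")
  pad_l <- 2 * x[, 1] - x[, (m + 1):2, drop = FALSE]
  pad_r <- 2 * x[, n] - x[, (n - 1):(n - m), drop = FALSE]
  xp <- cbind(pad_l, x, pad_r)
  nc <- n + 2 * m + length(taps) - 1L
  L <- stats::nextn(nc, c(2, 3, 5))
  H <- stats::fft(c(taps, rep(0, L - length(taps))))
  X <- stats::mvfft(t(cbind(xp, matrix(0, nrow(x), L - ncol(xp)))))
  y <- Re(stats::mvfft(X * H, inverse = TRUE)) / L
  t(y)[, (2 * m + 1):(2 * m + n), drop = FALSE]
}

#' Zero-phase FIR band-pass of a continuous recording
#'
#' Applies the designed filter to every channel with no phase shift at any
#' frequency (symmetric FIR, exact group-delay compensation, reflection
#' padding at the edges). Events are unchanged. This is the first editing
#' step on the continuous data, before re-referencing and epoching.
#'
#' @param recording An `eeg_recording`.
#' @param spec A [filter_spec()].
#' @return The filtered recording.
#' @export
fir_bandpass <- function(recording, spec = filter_spec()) {
  taps <- design_fir(spec, recording$montage$sampling_rate)
  labels <- rownames(recording$data)
  recording$data <- zero_phase_filter(recording$data, taps)
  rownames(recording$data) <- labels
  recording
}

#' Re-reference to the linked mastoids
#'
#' Subtracts mean(M1, M2) from every scalp and mastoid channel, and recovers
#' the original reference Cz as a data channel equal to -mean(M1, M2)
#' (its potential relative to the recording reference is identically zero).
#' Bipolar EOG channels are untouched.
#'
#' @param recording An `eeg_recording` whose montage has two mastoids.
#' @return The re-referenced recording; Cz's role becomes `"scalp_recovered"`.
#' @export
rereference_linked_mastoids <- function(recording) {
  ch <- recording$montage$channels
  mi <- which(ch$role == "mastoid")
  if (length(mi) != 2) stop("montage must contain two mastoid channels")
  ref <- colMeans(recording$data[mi, , drop = FALSE])
  target <- ch$role %in% c("scalp", "mastoid")
  recording$data[target, ] <-
    sweep(recording$data[target, , drop = FALSE], 2, ref)
  ri <- which(ch$role == "reference")
  recording$data[ri, ] <- -ref
  recording$montage$channels$role[ri] <- "scalp_recovered"
  recording
}

# ---- Epoching --------------------------------------------------------------

marker_sets <- list(
  auditory = c("name_own", "name_stranger"),
  visual   = c("object_after_own", "object_after_stranger")
)

condition_of_marker <- function(marker) {
  ifelse(marker %in% c("name_own", "object_after_own"), "own", "stranger")
}

#' Cut stimulus-locked epochs from a continuous recording
#'
#' One epoch per event of the requested modality, spanning the half-open
#' interval `[t_min, t_max)` around the event onset (time zero at onset).
#' At 250 Hz the default -200..+1500 ms span yields 425 samples. Events too
#' close to the recording edge are dropped with a logged reason, as are
#' visual trials flagged not-looking (when `not_looking` is supplied).
#'
#' @param recording An `eeg_recording`.
#' @param marker_type `"auditory"` or `"visual"`.
#' @param t_min,t_max Epoch span in ms relative to the event (default
#'   -200 and 1500).
#' @param not_looking Optional logical vector indexed by trial: visual trials
#'   flagged `TRUE` are excluded (video-coded looking screen).
#' @return An `erp_epochs` object: `data` (trials x channels x samples
#'   array), `channels`, `times_ms`, `sampling_rate`, `trials` (trial index,
#'   condition), `dropped` (data.frame of excluded events with reasons), and
#'   an all-`FALSE` rejection mask.
#' @export
extract_epochs <- function(recording, marker_type = c("auditory", "visual"),
                           t_min = -200, t_max = 1500, not_looking = NULL) {
  marker_type <- match.arg(marker_type)
  fs <- recording$montage$sampling_rate
  ev <- recording$events[recording$events$marker %in% marker_sets[[marker_type]], ]
  k0 <- round(t_min / 1000 * fs)
  k1 <- round(t_max / 1000 * fs) - 1L   # half-open [t_min, t_max)
  n_samp <- k1 - k0 + 1L
  n_total <- ncol(recording$data)

  dropped <- data.frame(trial = integer(0), reason = character(0))
  keep <- logical(nrow(ev))
  for (i in seq_len(nrow(ev))) {
    if (ev$sample[i] + k0 < 1 || ev$sample[i] + k1 > n_total) {
      dropped <- rbind(dropped, data.frame(trial = ev$trial[i],
                                           reason = "edge"))
    } else if (marker_type == "visual" && !is.null(not_looking) &&
               isTRUE(not_looking[ev$trial[i]])) {
      dropped <- rbind(dropped, data.frame(trial = ev$trial[i],
                                           reason = "not_looking"))
    } else keep[i] <- TRUE
  }
  ev <- ev[keep, ]
  data <- array(0, c(nrow(ev), nrow(recording$data), n_samp))
  for (i in seq_len(nrow(ev)))
    data[i, , ] <- recording$data[, (ev$sample[i] + k0):(ev$sample[i] + k1)]
  structure(list(
    data = data,
    channels = recording$montage$channels,
    times_ms = (k0:k1) * 1000 / fs,
    sampling_rate = fs,
    modality = marker_type,
    trials = data.frame(trial = ev$trial,
                        condition = condition_of_marker(ev$marker)),
    dropped = dropped,
    rejection = data.frame(trial = ev$trial, rejected = FALSE,
                           reason = NA_character_, channel = NA_character_,
                           window_start_ms = NA_real_, sd_uV = NA_real_)
  ), class = "erp_epochs")
}

#' @export
print.erp_epochs <- function(x, ...) {
  cat(sprintf("<erp_epochs> %s: %d trials x %d ch x %d samples (%g..%g ms), %d rejected\n",
              x$modality, dim(x$data)[1], dim(x$data)[2], dim(x$data)[3],
              min(x$times_ms), max(x$times_ms), sum(x$rejection$rejected)))
  invisible(x)
}

#' Baseline-correct epochs
#'
#' Subtracts, per epoch and channel, the mean over the pre-stimulus baseline
#' window (default the 200 ms before onset, `[-200, 0)`).
#'
#' @param epochs An `erp_epochs`.
#' @param window Numeric `c(start, end)` in ms, half-open.
#' @return The corrected `erp_epochs`.
#' @export
baseline_correct <- function(epochs, window = c(-200, 0)) {
  sel <- epochs$times_ms >= window[1] & epochs$times_ms < window[2]
  if (!any(sel)) stop("baseline window contains no samples")
  bl <- rowMeans(epochs$data[, , sel, drop = FALSE], dims = 2)
  epochs$data <- epochs$data - array(bl, dim(epochs$data))
  epochs$baseline <- window
  epochs
}

# ---- Artifact rejection ----------------------------------------------------

# Population SD over every length-w window (step 1) of x, via running sums.
running_sd <- function(x, w) {
  cs <- cumsum(c(0, x))
  cs2 <- cumsum(c(0, x^2))
  n <- length(x) - w + 1L
  i <- seq_len(n)
  s <- cs[i + w] - cs[i]
  s2 <- cs2[i + w] - cs2[i]
  v <- s2 / w - (s / w)^2
  sqrt(pmax(v, 0))
}

#' Gliding-window artifact rejection
#'
#' Marks an epoch rejected if, on any channel, the standard deviation within
#' any 200 ms window — slid sample by sample across the whole epoch span
#' including the baseline — exceeds the channel-role threshold: 80 uV on EOG
#' channels, 50 uV on every other channel (scalp, recovered reference,
#' mastoids). The SD is the population SD over the window's samples. The
#' mask records the first offending channel and window.
#'
#' @param epochs An `erp_epochs`.
#' @param window_ms Gliding window length in ms (default 200; 50 samples at
#'   250 Hz).
#' @param sd_eog_uV EOG threshold in uV (default 80).
#' @param sd_scalp_uV Threshold for all non-EOG channels (default 50).
#' @return The `erp_epochs` with an updated rejection mask.
#' @export
reject_artifacts <- function(epochs, window_ms = 200, sd_eog_uV = 80,
                             sd_scalp_uV = 50) {
  w <- round(window_ms / 1000 * epochs$sampling_rate)
  n_samp <- dim(epochs$data)[3]
  if (w > n_samp) stop("gliding window longer than the epoch")
  role <- epochs$channels$role
  thresh <- ifelse(role == "eog", sd_eog_uV, sd_scalp_uV)
  for (i in seq_len(dim(epochs$data)[1])) {
    for (j in seq_len(dim(epochs$data)[2])) {
      # channel mean subtracted first for numerical stability of running sums
      x <- epochs$data[i, j, ]
      sds <- running_sd(x - mean(x), w)
      hit <- which(sds > thresh[j])
      if (length(hit)) {
        epochs$rejection$rejected[i] <- TRUE
        epochs$rejection$reason[i] <- "gliding_window_sd"
        epochs$rejection$channel[i] <- epochs$channels$label[j]
        epochs$rejection$window_start_ms[i] <- epochs$times_ms[hit[1]]
        epochs$rejection$sd_uV[i] <- sds[hit[1]]
        break
      }
    }
  }
  epochs
}

#' Retained-epoch selector
#'
#' @param epochs An `erp_epochs`.
#' @param condition Optional condition filter ("own"/"stranger").
#' @return Integer indices of retained (non-rejected) epochs.
#' @export
retained_epochs <- function(epochs, condition = NULL) {
  keep <- !epochs$rejection$rejected
  if (!is.null(condition)) keep <- keep & epochs$trials$condition == condition
  which(keep)
}

#' Subject inclusion rule
#'
#' A subject enters a modality's analyses only with at least `min_trials`
#' artifact-free trials in each of the two conditions for that modality.
#'
#' @param counts Data.frame with columns `subject`, `modality`, `condition`,
#'   `n_retained` (one row per cell).
#' @param min_trials Minimum per condition (default 10).
#' @return Data.frame with one row per subject x modality: retained counts
#'   per condition and an `included` flag.
#' @export
apply_inclusion <- function(counts, min_trials = 10) {
  out <- do.call(rbind, lapply(split(counts, counts[c("subject", "modality")],
                                     drop = TRUE), function(d) {
    n_own <- sum(d$n_retained[d$condition == "own"])
    n_str <- sum(d$n_retained[d$condition == "stranger"])
    data.frame(subject = d$subject[1], modality = d$modality[1],
               n_own = n_own, n_stranger = n_str,
               included = n_own >= min_trials && n_str >= min_trials)
  }))
  rownames(out) <- NULL
  out
}

#' Preprocess one subject's recording
#'
#' The fixed order of operations: zero-phase band-pass on the continuous
#' data, linked-mastoid re-reference, epoching per modality, baseline
#' correction, gliding-window rejection.
#'
#' @param recording An `eeg_recording`.
#' @param fspec A [filter_spec()].
#' @param not_looking Optional looking flags for visual trials.
#' @param window_ms,sd_eog_uV,sd_scalp_uV Rejection parameters.
#' @return List with elements `auditory` and `visual`, each an `erp_epochs`.
#' @export
preprocess_subject <- function(recording, fspec = filter_spec(),
                               not_looking = NULL, window_ms = 200,
                               sd_eog_uV = 80, sd_scalp_uV = 50) {
  rec <- fir_bandpass(recording, fspec)
  rec <- rereference_linked_mastoids(rec)
  out <- list()
  for (mod in c("auditory", "visual")) {
    ep <- extract_epochs(rec, mod, not_looking = not_looking)
    ep <- baseline_correct(ep)
    out[[mod]] <- reject_artifacts(ep, window_ms, sd_eog_uV, sd_scalp_uV)
  }
  out
}
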