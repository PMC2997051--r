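# Synthetic infant-EEG cohort generator: 1/f background noise, Hann-bump ERP
# components with group/condition effect structure, blink/movement artifacts.

#' ERP component specification
#'
#' Describes one simulated ERP component: a Hann-shaped bump injected at every
#' event of the matching modality, with a per-(group, condition) amplitude and
#' peak-latency shift and a fixed scalp topography.
#'
#' Amplitude and latency-shift maps are 2x2 matrices with rownames
#' `c("ten", "one")` (group) and colnames `c("own", "stranger")` (condition).
#'
#' @param name Component name (unique within a configuration).
#' @param marker `"auditory"` (name onset) or `"visual"` (object onset).
#' @param window Numeric `c(t_start, t_end)` in ms post-stimulus: the bump's
#'   support; zero outside.
#' @param peak_latency_ms Nominal peak latency (within `window`).
#' @param topography Named numeric vector of channel weights (unitless,
#'   signed); channels not named get weight 0.
#' @param amplitude_uV 2x2 matrix (group x condition) of peak amplitudes in
#'   microvolts; sign carried here (negative components get negative values).
#' @param latency_shift_ms 2x2 matrix (group x condition) of peak shifts in ms
#'   (default all zero).
#' @return A `component_spec` list.
#' @export
component_spec <- function(name, marker, window, peak_latency_ms, topography,
                           amplitude_uV, latency_shift_ms = NULL) {
  marker <- match.arg(marker, c("auditory", "visual"))
  stopifnot(length(window) == 2, window[1] < window[2],
            peak_latency_ms > window[1], peak_latency_ms < window[2],
            all(is.finite(topography)))
  dn <- list(c("ten", "one"), c("own", "stranger"))
  amp <- matrix(as.numeric(amplitude_uV), 2, 2, dimnames = dn)
  if (is.null(latency_shift_ms)) latency_shift_ms <- 0
  shift <- matrix(as.numeric(latency_shift_ms), 2, 2, dimnames = dn)
  structure(list(name = name, marker = marker, window = window,
                 peak_latency_ms = peak_latency_ms, topography = topography,
                 amplitude_uV = amp, latency_shift_ms = shift),
            class = "component_spec")
}

#' Default effect template: the four simulated components
#'
#' Mirrors the qualitative effect structure under study:
#' \itemize{
#'   \item `anterior_shift` (auditory, fronto-central, positive, measured as
#'     100-380 ms mean amplitude): own-name amplitude larger than stranger
#'     only in the one-control-name group (+6 uV difference).
#'   \item `n200_600` (auditory, parietal, negative peak 200-600 ms): own name
#'     more negative than stranger only in the ten-control-names group
#'     (-7 uV difference).
#'   \item `nc` (visual, fronto-central, negative peak 450-700 ms): own-name
#'     peak 40 ms later than stranger in both groups, equal amplitude.
#'   \item `extended_nc` (visual, fronto-central, mean amplitude 890-1000 ms):
#'     own more negative than stranger in both groups (-3 uV), with left
#'     weights larger than right (left-lateralized).
#' }
#'
#' Effect directions mirror the findings under study; magnitudes are free
#' simulation parameters, sized a priori as large effects so that the
#' planned analyses reach >= 80% power at n = 15/group with ~20 retained
#' trials per condition (see the methods vignette for the calculation).
#'
#' @return Named list of [component_spec()] objects.
#' @export
default_components <- function() {
  fc <- c(F3 = 1, FC3 = 1, C3 = 1, F4 = 1, FC4 = 1, C4 = 1)
  fc_left <- c(F3 = 1.3, FC3 = 1.3, C3 = 1.3, F4 = 0.7, FC4 = 0.7, C4 = 0.7)
  par <- c(P3 = 1, Pz = 1, P4 = 1)
  list(
    anterior_shift = component_spec(
      "anterior_shift", "auditory", c(80, 400), 240, fc,
      amplitude_uV = matrix(c(4, 10, 4, 4), 2, 2)  # own: ten 4, one 10; stranger 4
    ),
    n200_600 = component_spec(
      "n200_600", "auditory", c(200, 600), 400, par,
      amplitude_uV = matrix(c(-12, -5, -5, -5), 2, 2)  # own: ten -12; else -5
    ),
    nc = component_spec(
      "nc", "visual", c(420, 730), 550, fc,
      amplitude_uV = matrix(-8, 2, 2),
      latency_shift_ms = matrix(c(40, 40, 0, 0), 2, 2)  # own peaks 40 ms later
    ),
    extended_nc = component_spec(
      "extended_nc", "visual", c(700, 1200), 945, fc_left,
      amplitude_uV = matrix(c(-6, -6, -3, -3), 2, 2)  # own -6, stranger -3
    )
  )
}

#' Background-noise and artifact specification
#'
#' @param spectral_exponent Exponent beta of the 1/f^beta background spectrum
#'   (default 1, pink noise).
#' @param rms_uV Per-channel background RMS in microvolts (default 15, a
#'   realistic figure for band-limited infant scalp EEG).
#' @param blink_rate_per_min Blink events per minute on the EOG (default 14).
#' @param blink_amp_uV Blink peak amplitude on VEOG (default 200).
#' @param movement_rate_per_min Broadband movement bursts per minute
#'   (default 70; infant recordings are movement-dominated). The default
#'   rates are calibrated so mean retained auditory trials per subject fall
#'   near the reported retention (range 20-79, mean ~33 of 200).
#' @param movement_amp_uV Movement burst RMS scale on scalp channels
#'   (default 120).
#' @return A `noise_spec` list.
#' @export
noise_spec <- function(spectral_exponent = 1, rms_uV = 15,
                       blink_rate_per_min = 14, blink_amp_uV = 200,
                       movement_rate_per_min = 70, movement_amp_uV = 120) {
  stopifnot(rms_uV >= 0, blink_rate_per_min >= 0, movement_rate_per_min >= 0)
  structure(list(spectral_exponent = spectral_exponent, rms_uV = rms_uV,
                 blink_rate_per_min = blink_rate_per_min,
                 blink_amp_uV = blink_amp_uV,
                 movement_rate_per_min = movement_rate_per_min,
                 movement_amp_uV = movement_amp_uV),
            class = "noise_spec")
}

#' Cohort simulation configuration
#'
#' @param n_subjects_per_group Subjects per group (default 15).
#' @param components List of [component_spec()]s (default
#'   [default_components()]); names must be unique.
#' @param noise A [noise_spec()].
#' @param seed Master seed; all subject/schedule seeds derive from it.
#' @param n_trials Trials per subject (default 200).
#' @param subject_sd Between-subject SD of the amplitude multiplier
#'   (mean 1, truncated at 0; default 0.3).
#' @param artifacts Logical: inject blink/movement artifacts (default TRUE).
#' @param not_looking_rate Per-trial probability that the infant is coded as
#'   not looking during the object (that visual epoch is dropped downstream);
#'   default 0.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_subjects_per_group = 15,
                              components = default_components(),
                              noise = noise_spec(), seed = 1,
                              n_trials = 200, subject_sd = 0.3,
                              artifacts = TRUE, not_looking_rate = 0) {
  stopifnot(n_subjects_per_group >= 1)
  if (anyDuplicated(vapply(components, `[[`, "", "name")))
    stop("component names must be unique")
  structure(list(n_subjects_per_group = n_subjects_per_group,
                 components = components, noise = noise, seed = seed,
                 n_trials = n_trials, subject_sd = subject_sd,
                 artifacts = artifacts, not_looking_rate = not_looking_rate),
            class = "simulation_config")
}

# ---- Continuous recordings -------------------------------------------------

new_recording <- function(montage, data, events) {
  stopifnot(nrow(data) == nrow(montage$channels))
  rownames(data) <- montage$channels$label
  if (nrow(events) > 1 && any(diff(events$sample) <= 0))
    stop("event samples must be strictly increasing")
  if (nrow(events) && (min(events$sample) < 1 || max(events$sample) > ncol(data)))
    stop("event sample out of bounds")
  structure(list(montage = montage, data = data, events = events),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d ch x %d samples (%.1f s @ %g Hz), %d events\n",
              nrow(x$data), ncol(x$data), ncol(x$data) / x$montage$sampling_rate,
              x$montage$sampling_rate, nrow(x$events)))
  invisible(x)
}

# 1/f^beta noise, channels x samples: shape white Gaussian spectra by
# f^(-beta/2), then rescale each channel to the target RMS. Generated at a
# power-of-two FFT length and truncated, so arbitrary n stays O(n log n).
one_over_f_noise <- function(n, beta, rms, n_channels = 1) {
  if (rms == 0) return(matrix(0, n_channels, n))
  L <- stats::nextn(n, c(2, 3, 5))
  x <- matrix(stats::rnorm(L * n_channels), L, n_channels)
  if (beta != 0) {
    X <- stats::mvfft(x)
    f <- c(1e-12, seq_len(floor(L / 2)), rev(seq_len(ceiling(L / 2) - 1)))
    X <- X * f^(-beta / 2)
    x <- Re(stats::mvfft(X, inverse = TRUE)) / L
  }
  x <- t(x[seq_len(n), , drop = FALSE])
  x <- x - rowMeans(x)
  x * rms / sqrt(rowMeans(x^2))
}

#' Simulate 1/f background EEG
#'
#' Independent per-channel 1/f^beta Gaussian noise at the requested RMS; no
#' events.
#'
#' @param n_samples Number of samples (> 0).
#' @param montage An `eeg_montage`.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @return An `eeg_recording` with an empty event list.
#' @export
simulate_background <- function(n_samples, montage = build_montage(),
                                noise = noise_spec(), seed = 1) {
  stopifnot(n_samples > 0)
  with_seed(seed, {
    nch <- nrow(montage$channels)
    data <- one_over_f_noise(n_samples, noise$spectral_exponent,
                             noise$rms_uV, nch)
    new_recording(montage, data,
                  data.frame(sample = integer(0), marker = character(0),
                             trial = integer(0)))
  })
}

# ---- Component waveforms ---------------------------------------------------

# Asymmetric Hann bump on a time grid (ms): rises as half a Hann window from
# t0 to the peak, falls from the peak to t1; zero outside [t0, t1]. Each half
# averages A/2, so the mean over the full support is A/2 for any peak
# placement.
hann_bump <- function(times_ms, t0, t1, peak, amplitude) {
  y <- numeric(length(times_ms))
  rise <- times_ms >= t0 & times_ms < peak
  fall <- times_ms >= peak & times_ms <= t1
  y[rise] <- 0.5 * (1 - cos(pi * (times_ms[rise] - t0) / (peak - t0)))
  y[fall] <- 0.5 * (1 + cos(pi * (times_ms[fall] - peak) / (t1 - peak)))
  amplitude * y
}

#' Single-channel waveform of a component for one design cell
#'
#' The Hann bump of the configured (group, condition) amplitude, with its
#' peak at `peak_latency_ms + latency_shift`, zero outside the component
#' window. Topography weights are applied at injection time, not here.
#'
#' @param spec A [component_spec()].
#' @param group `"ten"` or `"one"`.
#' @param condition `"own"` or `"stranger"`.
#' @param sampling_rate Hz.
#' @param times_ms Optional time grid (ms post-stimulus); defaults to the
#'   component window sampled at `sampling_rate`.
#' @return Numeric vector over `times_ms` in microvolts.
#' @export
component_waveform <- function(spec, group, condition, sampling_rate = 250,
                               times_ms = NULL) {
  amp <- spec$amplitude_uV[group, condition]
  peak <- spec$peak_latency_ms + spec$latency_shift_ms[group, condition]
  if (peak <= spec$window[1] || peak >= spec$window[2])
    stop("peak latency outside component window after shift")
  if (is.null(times_ms))
    times_ms <- seq(spec$window[1], spec$window[2], by = 1000 / sampling_rate)
  hann_bump(times_ms, spec$window[1], spec$window[2], peak, amp)
}

# ---- Subject simulation ----------------------------------------------------

# Per-trial event timing in ms from recording start. The name window is fixed
# at 1500 ms; the object follows after the ISI and lasts 1000 ms; the ITI
# separates trials. A lead-in/out pad leaves room for epoch baselines and
# filter edges.
schedule_event_times <- function(schedule, lead_in_ms = 4000) {
  n <- nrow(schedule)
  name_on <- numeric(n); object_on <- numeric(n)
  t <- lead_in_ms
  for (i in seq_len(n)) {
    name_on[i] <- t
    object_on[i] <- t + 1500 + schedule$isi_ms[i]
    t <- object_on[i] + 1000 + schedule$iti_ms[i]
  }
  list(name_on = name_on, object_on = object_on, total_ms = t + lead_in_ms)
}

#' Simulate one subject's continuous recording
#'
#' Generates 1/f background noise over the full session implied by the trial
#' schedule, then injects every configured ERP component at each matching
#' event (auditory components at name onsets, visual components at object
#' onsets) scaled by the subject's amplitude multiplier and the component's
#' topography. Events are emitted for name onset (`name_own`/`name_stranger`)
#' and object onset (`object_after_own`/`object_after_stranger`).
#'
#' @param config A [simulation_config()].
#' @param schedule A `trial_schedule`.
#' @param group `"ten"` or `"one"`.
#' @param seed Integer seed for this subject's noise and multiplier.
#' @return An `eeg_recording`; attribute `not_looking` holds the per-trial
#'   looking-drop flags (all `FALSE` at rate 0), attribute `multiplier` the
#'   subject amplitude multiplier.
#' @export
simulate_subject <- function(config, schedule, group, seed) {
  montage <- build_montage()
  fs <- montage$sampling_rate
  tim <- schedule_event_times(schedule)
  n_samples <- ceiling(tim$total_ms / 1000 * fs)
  rec <- simulate_background(n_samples, montage, config$noise, seed)
  with_seed(derive_seed(seed, 1), {
    mult <- 0
    while (mult <= 0) mult <- stats::rnorm(1, 1, config$subject_sd)
    not_looking <- stats::runif(nrow(schedule)) < config$not_looking_rate

    name_samp <- floor(tim$name_on / 1000 * fs) + 1L
    obj_samp <- floor(tim$object_on / 1000 * fs) + 1L
    lab <- montage$channels$label
    for (comp in config$components) {
      ev_samp <- if (comp$marker == "auditory") name_samp else obj_samp
      w_idx <- match(names(comp$topography), lab)
      if (anyNA(w_idx)) stop("topography channel not in montage")
      # waveform support relative to the event sample
      k0 <- floor(comp$window[1] / 1000 * fs)
      k1 <- ceiling(comp$window[2] / 1000 * fs)
      rel_t <- (k0:k1) * 1000 / fs
      for (cond in c("own", "stranger")) {
        wave <- mult * component_waveform(comp, group, cond, fs, rel_t)
        patch <- outer(comp$topography, wave)  # channels-in-topo x samples
        for (ev in ev_samp[schedule$condition == cond]) {
          idx <- (ev + k0):(ev + k1)
          keep <- idx >= 1 & idx <= n_samples
          rec$data[w_idx, idx[keep]] <-
            rec$data[w_idx, idx[keep]] + patch[, keep, drop = FALSE]
        }
      }
    }
    marker <- ifelse(schedule$condition == "own", "name_own", "name_stranger")
    obj_marker <- ifelse(schedule$condition == "own",
                         "object_after_own", "object_after_stranger")
    ev <- rbind(
      data.frame(sample = name_samp, marker = marker, trial = schedule$index),
      data.frame(sample = obj_samp, marker = obj_marker, trial = schedule$index)
    )
    ev <- ev[order(ev$sample), ]
    rec$events <- ev
    attr(rec, "multiplier") <- mult
    attr(rec, "not_looking") <- not_looking
    rec
  })
}

#' Inject blink and movement artifacts
#'
#' Adds blink transients (a ~300 ms Hann bump, full amplitude on VEOG, 30% on
#' HEOG, attenuated spread to frontal scalp sites) and broadband movement
#' bursts (~500 ms Hann-enveloped white noise on all scalp/mastoid channels)
#' at Poisson-distributed times. Events are preserved.
#'
#' @param recording An `eeg_recording`.
#' @param noise A [noise_spec()] (rates and amplitudes).
#' @param seed Integer seed.
#' @return A modified copy of `recording`.
#' @export
inject_artifacts <- function(recording, noise = noise_spec(), seed = 1) {
  fs <- recording$montage$sampling_rate
  n <- ncol(recording$data)
  dur_min <- n / fs / 60
  lab <- recording$montage$channels$label
  role <- recording$montage$channels$role
  with_seed(seed, {
    # blinks
    n_blink <- stats::rpois(1, noise$blink_rate_per_min * dur_min)
    if (n_blink > 0 && noise$blink_amp_uV != 0) {
      spread <- c(VEOG = 1, HEOG = 0.3, Fp1 = 0.5, Fp2 = 0.5,
                  F3 = 0.25, F4 = 0.25, F7 = 0.25, F8 = 0.25, Fz = 0.25)
      idx <- match(names(spread), lab)
      len <- round(0.3 * fs)
      bump <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))
      for (s in sample.int(n - len, n_blink)) {
        amp <- noise$blink_amp_uV * stats::runif(1, 0.7, 1.3)
        recording$data[idx, s:(s + len - 1)] <-
          recording$data[idx, s:(s + len - 1)] + outer(spread * amp, bump)
      }
    }
    # movement bursts
    n_move <- stats::rpois(1, noise$movement_rate_per_min * dur_min)
    if (n_move > 0 && noise$movement_amp_uV != 0) {
      idx <- which(role %in% c("scalp", "mastoid"))
      len <- round(0.5 * fs)
      env <- 0.5 * (1 - cos(2 * pi * seq_len(len) / (len + 1)))
      for (s in sample.int(n - len, n_move)) {
        scale <- noise$movement_amp_uV * stats::runif(length(idx), 0.5, 1)
        burst <- matrix(stats::rnorm(length(idx) * len), length(idx), len)
        recording$data[idx, s:(s + len - 1)] <-
          recording$data[idx, s:(s + len - 1)] +
          burst * outer(scale, env)
      }
    }
    recording
  })
}

#' Simulate a full two-group cohort
#'
#' Simulates `2 * n_subjects_per_group` subjects, each with their own
#' constrained trial schedule; the first `n_subjects_per_group` belong to the
#' ten-control-names group, the rest to the one-control-name group. All
#' per-subject seeds derive deterministically from the master seed.
#'
#' @param config A [simulation_config()].
#' @return List of subject entries: `subject_id`, `group`, `schedule`,
#'   `recording`, `not_looking`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  n <- config$n_subjects_per_group
  groups <- rep(c("ten", "one"), each = n)
  lapply(seq_len(2 * n), function(i) {
    sched_seed <- derive_seed(config$seed, 1000 + i)
    sub_seed <- derive_seed(config$seed, 2000 + i)
    schedule <- generate_schedule(sched_seed, n_trials = config$n_trials)
    rec <- simulate_subject(config, schedule, groups[i], sub_seed)
    if (config$artifacts)
      rec <- inject_artifacts(rec, config$noise, derive_seed(config$seed, 3000 + i))
    list(subject_id = sprintf("S%02d", i), group = groups[i],
         schedule = schedule, recording = rec,
         not_looking = attr(rec, "not_looking"))
  })
}
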