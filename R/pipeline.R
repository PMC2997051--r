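# Orchestration: simulate -> preprocess -> measure -> stats -> report, with
# plain-text artifacts (CSV + JSON sidecars) and a provenance manifest.

#' Full-run configuration
#'
#' @param simulation A [simulation_config()].
#' @param filter A [filter_spec()].
#' @param window_ms,sd_eog_uV,sd_scalp_uV Rejection parameters (defaults
#'   200 ms, 80 uV, 50 uV).
#' @param min_trials Inclusion minimum per condition (default 10).
#' @param out_dir Output directory for artifacts.
#' @param seed Master seed; overrides `simulation$seed`.
#' @param write_recordings Write per-subject continuous data CSVs (large;
#'   default FALSE — events and schedules are always written).
#' @return A `run_config` list.
#' @export
run_config <- function(simulation = simulation_config(),
                       filter = filter_spec(), window_ms = 200,
                       sd_eog_uV = 80, sd_scalp_uV = 50, min_trials = 10,
                       out_dir = "infanterp_run", seed = simulation$seed,
                       write_recordings = FALSE) {
  simulation$seed <- seed
  structure(list(simulation = simulation, filter = filter,
                 window_ms = window_ms, sd_eog_uV = sd_eog_uV,
                 sd_scalp_uV = sd_scalp_uV, min_trials = min_trials,
                 out_dir = out_dir, seed = seed,
                 write_recordings = write_recordings),
            class = "run_config")
}

#' Write a continuous recording as CSV + JSON events sidecar
#'
#' Plain-text stand-in for an EDF export: a channels-as-columns CSV of the
#' data in microvolts, and a JSON sidecar with the sampling rate, channel
#' roles and the event list (0-based sample indices, the usual convention of
#' EEG sidecar formats).
#'
#' @param recording An `eeg_recording`.
#' @param path Base path without extension; writes `<path>.csv` and
#'   `<path>_events.json`.
#' @return Invisibly the two file paths.
#' @export
write_recording <- function(recording, path) {
  df <- as.data.frame(t(recording$data))
  names(df) <- recording$montage$channels$label
  utils::write.csv(df, paste0(path, ".csv"), row.names = FALSE)
  sidecar <- list(
    sampling_rate_Hz = recording$montage$sampling_rate,
    units = "uV",
    channels = recording$montage$channels,
    events = data.frame(sample_index = recording$events$sample - 1L,
                        marker = recording$events$marker,
                        trial = recording$events$trial)
  )
  jsonlite::write_json(sidecar, paste0(path, "_events.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(paste0(path, ".csv"), paste0(path, "_events.json")))
}

#' Read a recording written by [write_recording()]
#'
#' @param path Base path without extension.
#' @param montage Montage to attach (default [build_montage()]).
#' @return An `eeg_recording`.
#' @export
read_recording <- function(path, montage = build_montage()) {
  df <- utils::read.csv(paste0(path, ".csv"), check.names = FALSE)
  sidecar <- jsonlite::read_json(paste0(path, "_events.json"),
                                 simplifyVector = TRUE)
  stopifnot(identical(names(df), montage$channels$label))
  ev <- data.frame(sample = sidecar$events$sample_index + 1L,
                   marker = sidecar$events$marker,
                   trial = sidecar$events$trial)
  new_recording(montage, t(as.matrix(df)), ev)
}

# Extract the per-plan long data used by each reported ANOVA. The balanced
# decomposition needs equal group sizes; if subject exclusions unbalanced the
# cohort, the larger group is trimmed deterministically (highest subject IDs
# first) with a message.
anova_input <- function(measurements, window, measure) {
  d <- measurements[measurements$window == window &
                    measurements$measure == measure, ]
  subj <- unique(d[c("subject", "group")])
  gtab <- table(subj$group)
  if (length(gtab) == 2 && gtab[1] != gtab[2]) {
    big <- names(gtab)[which.max(gtab)]
    drop <- sort(subj$subject[subj$group == big], decreasing = TRUE)
    drop <- drop[seq_len(max(gtab) - min(gtab))]
    message(window, "/", measure, ": trimming ", length(drop),
            " subject(s) from group '", big, "' for a balanced design (",
            paste(drop, collapse = ", "), ")")
    d <- d[!(d$subject %in% drop), ]
  }
  d$name <- d$condition
  d$hemisphere <- ifelse(d$roi == "left_fc", "left",
                         ifelse(d$roi == "right_fc", "right", NA))
  d
}

#' The statistical battery on a measurement table
#'
#' Runs the four planned analyses: 2x2x2 mixed ANOVA on the anterior-shift
#' mean amplitude, 2x2 on the N200-600 peak amplitude (and latency), 2x2x2
#' on the Nc peak latency (and amplitude), and 2x2x2 on the extended-Nc
#' mean amplitude; plus the per-group Wilcoxon "k out of n" summaries for
#' the two auditory effects and the collapsed ones for the visual effects.
#'
#' @param measurements Long measurement data.frame from
#'   [build_measurement_table()]. Only subjects included for a modality
#'   appear; the ANOVAs require the remaining design to be complete and
#'   balanced.
#' @return List of `anova` (named list of `anova_table`s) and `nonparam`
#'   (named list of [wilcoxon_effect()] results).
#' @export
run_statistics <- function(measurements) {
  # a cohort too depleted by exclusions for a given analysis yields an
  # explanatory note rather than aborting the whole battery
  try_anova <- function(fn, window, measure) {
    tryCatch(fn(anova_input(measurements, window, measure)),
             error = function(e) structure(conditionMessage(e),
                                           class = "anova_unavailable"))
  }
  anovas <- list(
    anterior_shift = try_anova(mixed_anova_2x2x2, "anterior_shift",
                               "mean_amplitude_uV"),
    n200_600_amplitude = try_anova(mixed_anova_2x2, "n200_600",
                                   "peak_amplitude_uV"),
    n200_600_latency = try_anova(mixed_anova_2x2, "n200_600",
                                 "peak_latency_ms"),
    nc_amplitude = try_anova(mixed_anova_2x2x2, "nc", "peak_amplitude_uV"),
    nc_latency = try_anova(mixed_anova_2x2x2, "nc", "peak_latency_ms"),
    extended_nc = try_anova(mixed_anova_2x2x2, "extended_nc",
                            "mean_amplitude_uV")
  )

  subject_diff <- function(window, measure) {
    d <- measurements[measurements$window == window &
                      measurements$measure == measure, ]
    if (nrow(d) == 0)
      return(data.frame(subject = character(0), group = character(0),
                        diff = numeric(0)))
    agg <- stats::aggregate(value ~ subject + group + condition, d, mean)
    wide <- merge(agg[agg$condition == "own", c("subject", "group", "value")],
                  agg[agg$condition == "stranger", c("subject", "value")],
                  by = "subject", suffixes = c("_own", "_stranger"))
    wide$diff <- wide$value_own - wide$value_stranger
    wide
  }
  # all-zero difference vectors (possible in noise-free simulations) are
  # reported as degenerate rather than erroring the whole battery
  safe_wilcoxon <- function(d, direction) {
    if (length(d) == 0 || all(d == 0))
      return(list(n_positive = 0L, n_total = length(d), z = 0, p = 1,
                  method = "degenerate"))
    wilcoxon_effect(d, direction)
  }
  np <- list()
  as_d <- subject_diff("anterior_shift", "mean_amplitude_uV")
  for (g in c("ten", "one"))
    np[[paste0("anterior_shift_", g)]] <-
      safe_wilcoxon(as_d$diff[as_d$group == g], "positive")
  n2_d <- subject_diff("n200_600", "peak_amplitude_uV")
  for (g in c("ten", "one"))
    np[[paste0("n200_600_", g)]] <-
      safe_wilcoxon(n2_d$diff[n2_d$group == g], "negative")
  nc_d <- subject_diff("nc", "peak_latency_ms")
  np$nc_latency <- safe_wilcoxon(nc_d$diff, "positive")
  ext_d <- subject_diff("extended_nc", "mean_amplitude_uV")
  np$extended_nc <- safe_wilcoxon(ext_d$diff, "negative")

  list(anova = anovas, nonparam = np)
}

#' Run the full pipeline
#'
#' simulate -> preprocess -> measure -> stats -> report, writing a
#' deterministic plain-text artifact tree under `config$out_dir`:
#' per-subject schedules and event sidecars (and data CSVs on request), the
#' rejection log, inclusion report, long measurement table, ANOVA and
#' non-parametric reports, grand-average waveforms, and a provenance
#' manifest.
#'
#' @param config A [run_config()].
#' @return Invisibly a list with `processed`, `measurement` (table +
#'   inclusion), `stats`, and `out_dir`.
#' @export
run_all <- function(config = run_config()) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- simulate_cohort(config$simulation)

  processed <- lapply(cohort, function(s) {
    base <- file.path(config$out_dir, s$subject_id)
    utils::write.csv(s$schedule, paste0(base, "_schedule.csv"),
                     row.names = FALSE)
    if (config$write_recordings) write_recording(s$recording, base)
    ep <- preprocess_subject(s$recording, config$filter,
                             not_looking = s$not_looking,
                             window_ms = config$window_ms,
                             sd_eog_uV = config$sd_eog_uV,
                             sd_scalp_uV = config$sd_scalp_uV)
    message(sprintf("%s [%s]: auditory %d/%d retained, visual %d/%d retained",
                    s$subject_id, s$group,
                    sum(!ep$auditory$rejection$rejected),
                    nrow(ep$auditory$rejection),
                    sum(!ep$visual$rejection$rejected),
                    nrow(ep$visual$rejection)))
    list(subject_id = s$subject_id, group = s$group, epochs = ep)
  })

  rejlog <- do.call(rbind, lapply(processed, function(s)
    do.call(rbind, lapply(c("auditory", "visual"), function(mod) {
      r <- s$epochs[[mod]]$rejection
      cbind(subject = s$subject_id, modality = mod, r)
    }))))
  utils::write.csv(rejlog[rejlog$rejected, ],
                   file.path(config$out_dir, "rejection_log.csv"),
                   row.names = FALSE)

  mt <- build_measurement_table(processed, min_trials = config$min_trials)
  utils::write.csv(mt$measurements,
                   file.path(config$out_dir, "measurements.csv"),
                   row.names = FALSE)
  utils::write.csv(mt$inclusion,
                   file.path(config$out_dir, "inclusion.csv"),
                   row.names = FALSE)

  st <- run_statistics(mt$measurements)
  report <- character(0)
  for (nm in names(st$anova)) {
    a <- st$anova[[nm]]
    report <- c(report, paste0("== ", nm, " =="),
                if (inherits(a, "anova_unavailable"))
                  paste("unavailable:", unclass(a))
                else utils::capture.output(print(a)))
  }
  for (nm in names(st$nonparam)) {
    w <- st$nonparam[[nm]]
    report <- c(report, sprintf("%s: %d out of %d showed the effect, Z = %.2f, P = %.3g",
                                nm, w$n_positive, w$n_total, w$z, w$p))
  }
  writeLines(report, file.path(config$out_dir, "statistics.txt"))
  avail <- names(st$anova)[!vapply(st$anova, inherits, TRUE,
                                   "anova_unavailable")]
  anova_csv <- do.call(rbind, lapply(avail, function(nm)
    cbind(analysis = nm, st$anova[[nm]])))
  utils::write.csv(anova_csv, file.path(config$out_dir, "anova.csv"),
                   row.names = FALSE)

  for (mod in c("auditory", "visual")) for (cond in c("own", "stranger")) {
    ga <- tryCatch(grand_average(processed, mod, cond,
                                 min_trials = config$min_trials),
                   error = function(e) NULL)
    if (is.null(ga)) next
    df <- data.frame(time_ms = ga$times_ms, t(ga$data))
    utils::write.csv(df, file.path(config$out_dir,
                                   sprintf("grand_average_%s_%s.csv", mod, cond)),
                     row.names = FALSE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("infanterp")),
    r_version = R.version.string,
    seed = config$seed,
    n_subjects_per_group = config$simulation$n_subjects_per_group,
    n_trials = config$simulation$n_trials,
    filter = config$filter[c("low_cut_Hz", "high_cut_Hz", "n_taps")],
    rejection = list(window_ms = config$window_ms,
                     sd_eog_uV = config$sd_eog_uV,
                     sd_scalp_uV = config$sd_scalp_uV),
    min_trials = config$min_trials,
    acquisition_lowpass_Hz = acquisition_lowpass_Hz()
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(processed = processed, measurement = mt, stats = st,
                 out_dir = config$out_dir))
}
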