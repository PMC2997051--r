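# ---- Montage ---------------------------------------------------------------

#' Standard infant 10-20 recording montage
#'
#' Builds the fixed recording montage: 23 scalp electrodes of the 10-20
#' system referenced to the vertex (Cz), two mastoids (M1/M2) for offline
#' linked-mastoid re-referencing, and bipolar horizontal/vertical EOG
#' channels, sampled at 250 Hz.
#'
#' The nine electrodes entering any analysis ROI (F3, FC3, C3, F4, FC4, C4,
#' P3, Pz, P4) are always present; the remaining scalp sites are a standard
#' 10-20 complement (frontal pole, temporal, centro-parietal, occipital).
#'
#' @param sampling_rate Sampling rate in Hz (default 250).
#' @return An object of class `eeg_montage`: a list with `channels`
#'   (data.frame of `label`, `role` in scalp/eog/mastoid/reference) and
#'   `sampling_rate`.
#' @export
#' @examples
#' m <- build_montage()
#' sum(m$channels$role == "scalp")  # 23
build_montage <- function(sampling_rate = 250) {
  scalp <- c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
             "FC3", "FC4", "T3", "C3", "C4", "T4",
             "CP3", "CP4", "T5", "P3", "Pz", "P4", "T6",
             "O1", "Oz", "O2")
  channels <- data.frame(
    label = c(scalp, "Cz", "M1", "M2", "HEOG", "VEOG"),
    role  = c(rep("scalp", length(scalp)), "reference",
              "mastoid", "mastoid", "eog", "eog"),
    stringsAsFactors = FALSE
  )
  m <- structure(list(channels = channels, sampling_rate = sampling_rate),
                 class = "eeg_montage")
  validate_montage(m)
  m
}

#' @export
print.eeg_montage <- function(x, ...) {
  tab <- table(x$channels$role)
  cat(sprintf("<eeg_montage> %d channels @ %g Hz (%s)\n",
              nrow(x$channels), x$sampling_rate,
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

validate_montage <- function(m) {
  stopifnot(inherits(m, "eeg_montage"))
  ch <- m$channels
  if (anyDuplicated(ch$label)) stop("montage labels must be unique")
  if (sum(ch$role == "scalp") != 23L) stop("montage must have exactly 23 scalp channels")
  if (sum(ch$role == "reference") != 1L || ch$label[ch$role == "reference"] != "Cz")
    stop("montage must have exactly one reference channel, Cz")
  if (sum(ch$role == "mastoid") != 2L) stop("montage must have exactly two mastoid channels")
  if (sum(ch$role == "eog") < 2L) stop("montage must have at least two EOG channels")
  invisible(m)
}

#' Region of interest over montage channels
#'
#' @param name ROI name.
#' @param channel_labels Character vector of montage channel labels.
#' @param montage Optional `eeg_montage` to validate labels against.
#' @return A `roi_spec` list with `name` and `channels`.
#' @export
roi_spec <- function(name, channel_labels, montage = NULL) {
  if (length(channel_labels) == 0) stop("ROI must contain at least one channel")
  if (!is.null(montage)) {
    missing <- setdiff(channel_labels, montage$channels$label)
    if (length(missing))
      stop("ROI channels not in montage: ", paste(missing, collapse = ", "))
  }
  structure(list(name = name, channels = as.character(channel_labels)),
            class = "roi_spec")
}

#' The three analysis regions of interest
#'
#' Left and right fronto-central triplets (F3/FC3/C3 and F4/FC4/C4) and the
#' parietal triplet (P3/Pz/P4).
#'
#' @return Named list of [roi_spec()] objects: `left_fc`, `right_fc`,
#'   `parietal`.
#' @export
default_rois <- function() {
  m <- build_montage()
  list(
    left_fc  = roi_spec("left_fc",  c("F3", "FC3", "C3"), m),
    right_fc = roi_spec("right_fc", c("F4", "FC4", "C4"), m),
    parietal = roi_spec("parietal", c("P3", "Pz", "P4"), m)
  )
}

# ---- Analysis plan ---------------------------------------------------------

#' The four component analysis windows
#'
#' The default analysis plan pairs each measured component with its ROIs,
#' post-stimulus time window and measurement type:
#' \itemize{
#'   \item anterior positive shift: auditory, 100-380 ms mean amplitude on
#'     the left and right fronto-central ROIs;
#'   \item N200-600: auditory, 200-600 ms negative peak (amplitude and
#'     latency) on the parietal ROI;
#'   \item Nc: visual, 450-700 ms negative peak on left/right fronto-central
#'     ROIs;
#'   \item extended Nc: visual, 890-1000 ms mean amplitude on left/right
#'     fronto-central ROIs.
#' }
#'
#' @return A data.frame with one row per (window, ROI): columns `window`,
#'   `modality`, `t_start`, `t_end`, `measure`, `roi`.
#' @export
default_analysis_plan <- function() {
  plan <- rbind(
    data.frame(window = "anterior_shift", modality = "auditory",
               t_start = 100, t_end = 380, measure = "mean_amplitude",
               roi = c("left_fc", "right_fc")),
    data.frame(window = "n200_600", modality = "auditory",
               t_start = 200, t_end = 600, measure = "negative_peak",
               roi = "parietal"),
    data.frame(window = "nc", modality = "visual",
               t_start = 450, t_end = 700, measure = "negative_peak",
               roi = c("left_fc", "right_fc")),
    data.frame(window = "extended_nc", modality = "visual",
               t_start = 890, t_end = 1000, measure = "mean_amplitude",
               roi = c("left_fc", "right_fc"))
  )
  stopifnot(all(plan$t_start < plan$t_end))
  plan
}

# ---- Trial schedule --------------------------------------------------------

#' Generate a constrained 200-trial schedule
#'
#' One experimental block of 200 trials, 100 per condition (own vs stranger
#' name). The presentation order is pseudo-randomized under two constraints:
#' no more than two identical conditions in a row (checked across the whole
#' sequence), and within each consecutive block of 20 trials every one of the
#' 10 objects appears exactly twice, once per condition. Per-trial timing is
#' drawn as: name duration uniform on [396, 989] ms (unless `name_lengths`
#' supplies a per-subject pair), inter-stimulus interval (name offset window
#' to object) uniform on [750, 850] ms, inter-trial interval uniform on
#' [800, 1200] ms.
#'
#' Each 20-trial block is rejection-sampled: the 10 objects x 2 conditions
#' are shuffled until the run-length constraint holds, including across the
#' boundary with the previous block, bounded at `max_retries` shuffles.
#'
#' @param seed Integer seed; the schedule is deterministic given the seed.
#' @param n_trials Total trials (default 200; must be a multiple of 20).
#' @param name_lengths Optional numeric length-2 vector `c(own_ms, control_ms)`
#'   used as fixed name durations instead of uniform draws.
#' @param max_retries Shuffle bound per block before aborting (default 1e4).
#' @return A `trial_schedule` data.frame with columns `index`, `condition`
#'   ("own"/"stranger"), `object_id` (1-10), `name_duration_ms`, `isi_ms`,
#'   `iti_ms`.
#' @export
generate_schedule <- function(seed, n_trials = 200, name_lengths = NULL,
                              max_retries = 1e4) {
  if (n_trials %% 20 != 0) stop("n_trials must be a multiple of 20")
  with_seed(seed, {
    n_blocks <- n_trials / 20
    cond <- character(0)
    obj <- integer(0)
    base <- data.frame(object_id = rep(1:10, 2),
                       condition = rep(c("own", "stranger"), each = 10))
    for (b in seq_len(n_blocks)) {
      ok <- FALSE
      for (try in seq_len(max_retries)) {
        perm <- base[sample.int(20), ]
        cand <- c(utils::tail(cond, 2), perm$condition)
        if (max_run_length(cand) <= 2) { ok <- TRUE; break }
      }
      if (!ok) stop("schedule constraint satisfaction failed after ",
                    max_retries, " retries (bad sampler)")
      cond <- c(cond, perm$condition)
      obj <- c(obj, perm$object_id)
    }
    dur <- if (is.null(name_lengths)) {
      round(stats::runif(n_trials, 396, 989))
    } else {
      ifelse(cond == "own", name_lengths[1], name_lengths[2])
    }
    sched <- data.frame(
      index = seq_len(n_trials),
      condition = cond,
      object_id = obj,
      name_duration_ms = dur,
      isi_ms = round(stats::runif(n_trials, 750, 850)),
      iti_ms = round(stats::runif(n_trials, 800, 1200))
    )
    class(sched) <- c("trial_schedule", "data.frame")
    sched
  })
}

#' Check all schedule invariants
#'
#' Brute-force validation of a [generate_schedule()] result: trial count,
#' 100 trials per condition, maximum run length 2, exact 20-trial block
#' balance (each object twice, once per condition), and timing ranges.
#'
#' @param schedule A `trial_schedule`.
#' @return Invisibly `TRUE`; stops with a message on the first violation.
#' @export
validate_schedule <- function(schedule) {
  n <- nrow(schedule)
  if (n %% 20 != 0) stop("trial count not a multiple of 20")
  counts <- table(schedule$condition)
  if (length(counts) != 2 || counts[["own"]] != n / 2 || counts[["stranger"]] != n / 2)
    stop("conditions not balanced")
  if (max_run_length(schedule$condition) > 2)
    stop("more than two identical conditions in a row")
  for (b in seq_len(n / 20)) {
    blk <- schedule[((b - 1) * 20 + 1):(b * 20), ]
    tab <- table(factor(blk$object_id, levels = 1:10), blk$condition)
    if (!all(tab == 1L)) stop("block ", b, " violates object/condition balance")
  }
  if (any(schedule$name_duration_ms < 396 | schedule$name_duration_ms > 989))
    stop("name duration out of [396, 989] ms")
  if (any(schedule$isi_ms < 750 | schedule$isi_ms > 850)) stop("ISI out of range")
  if (any(schedule$iti_ms < 800 | schedule$iti_ms > 1200)) stop("ITI out of range")
  invisible(TRUE)
}

max_run_length <- function(x) {
  if (length(x) == 0) return(0L)
  max(rle(as.character(x))$lengths)
}

# ---- Geometry and Table 1 --------------------------------------------------

#' Visual angle subtended by a stimulus
#'
#' @param extent_cm Stimulus extent in cm (>= 0).
#' @param distance_cm Viewing distance in cm (> 0).
#' @return Subtended angle in degrees: `2 * atan(extent / (2 * distance))`.
#' @export
#' @examples
#' visual_angle(7.09, 70)  # 5.80 deg, the vertical angle of the object photos
visual_angle <- function(extent_cm, distance_cm) {
  if (any(distance_cm <= 0)) stop("distance must be positive")
  if (any(extent_cm < 0)) stop("extent must be non-negative")
  2 * atan(extent_cm / (2 * distance_cm)) * 180 / pi
}

#' Per-infant name lengths (packaged table)
#'
#' Reads the packaged per-infant name-length table: for each of the 30
#' infants (15 per group), the duration in ms of the infant's own name and of
#' the control name (for the ten-control-names group, the printed average of
#' the 10 control names).
#'
#' @return Data.frame with columns `group` ("ten"/"one"), `own_ms`,
#'   `control_ms`; 15 rows per group.
#' @export
name_length_table <- function() {
  path <- system.file("extdata", "table1_name_lengths.csv",
                      package = "infanterp", mustWork = TRUE)
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tbl) != 30L) stop("name length table must have 30 rows")
  if (any(tbl$own_ms <= 0) || any(tbl$control_ms <= 0))
    stop("name lengths must be positive")
  tbl
}

#' Summary means of presented name lengths
#'
#' Equal-weight means over the 30 own-name durations, the 30 control-name
#' durations, and all 60 values, rounded to integer ms.
#'
#' @param table A name-length table as from [name_length_table()].
#' @return Named numeric vector `c(own_mean_ms, control_mean_ms,
#'   overall_mean_ms)`.
#' @export
summarize_name_lengths <- function(table = name_length_table()) {
  if (nrow(table) != 30L) stop("expected 30 rows (15 per group)")
  c(own_mean_ms = round(mean(table$own_ms)),
    control_mean_ms = round(mean(table$control_ms)),
    overall_mean_ms = round(mean(c(table$own_ms, table$control_ms))))
}

# ---- RNG helper ------------------------------------------------------------

# Run expr under a local RNG state seeded with `seed`, restoring the global
# state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a bounded child seed from a master seed and a stream index.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + as.numeric(stream) * 104729) %% 2147483647
}
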