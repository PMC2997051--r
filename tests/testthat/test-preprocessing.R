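# Filtering, re-referencing, epoching, baseline correction, gliding-window
# rejection, inclusion.

test_that("designed band-pass meets its response contracts", {
  taps <- design_fir(filter_spec(), 250)
  expect_equal(length(taps), 1501)
  expect_equal(taps, rev(taps))  # linear phase
  H <- filter_response(taps, c(0, 10, 20), 250)
  expect_lt(H[1], 10^(-20 / 20))          # DC attenuated by >= 20 dB
  expect_lt(abs(H[2] - 1), 0.01)          # 10 Hz passband within 1%
  expect_error(design_fir(filter_spec(high_cut_Hz = 130), 250), "Nyquist")
})

test_that("acquisition low-pass constant is 0.27 x fs", {
  expect_equal(acquisition_lowpass_Hz(), 67.5)
})

test_that("zero-phase filtering: null, amplitude and phase behaviour", {
  m <- build_montage()
  n <- 10000
  zero <- infanterp:::new_recording(
    m, matrix(0, nrow(m$channels), n),
    data.frame(sample = integer(0), marker = character(0), trial = integer(0)))
  expect_true(all(fir_bandpass(zero)$data == 0))

  t <- (0:(n - 1)) / 250
  sine <- zero; sine$data[4, ] <- sin(2 * pi * 10 * t)
  out <- fir_bandpass(sine)$data[4, 4000:6000]
  expect_lt(abs(max(out) - 1), 0.01)
  # zero phase: filtered 10 Hz sine stays in phase with the input
  expect_gt(stats::cor(out, sine$data[4, 4000:6000]), 0.9999)

  dc <- zero; dc$data[4, ] <- 100
  expect_lt(max(abs(fir_bandpass(dc)$data[4, 4000:6000])), 10)  # >= 20 dB down
})

test_that("filtering is linear", {
  m <- build_montage()
  set.seed(1)
  mk <- function(x) infanterp:::new_recording(
    m, matrix(rep(x, each = nrow(m$channels)), nrow(m$channels)),
    data.frame(sample = integer(0), marker = character(0), trial = integer(0)))
  a <- stats::rnorm(8000); b <- stats::rnorm(8000)
  fa <- fir_bandpass(mk(a))$data[1, ]
  fb <- fir_bandpass(mk(b))$data[1, ]
  fab <- fir_bandpass(mk(a + b))$data[1, ]
  expect_lt(max(abs(fab - (fa + fb))), 1e-6)
})

make_rec <- function(data, events = NULL) {
  m <- build_montage()
  if (is.null(events))
    events <- data.frame(sample = integer(0), marker = character(0),
                         trial = integer(0))
  infanterp:::new_recording(m, data, events)
}

test_that("linked-mastoid re-reference arithmetic", {
  m <- build_montage()
  nch <- nrow(m$channels)
  mi <- which(m$channels$role == "mastoid")
  ei <- which(m$channels$role == "eog")
  ci <- which(m$channels$role == "reference")

  # M1 = M2 = 0: scalp unchanged
  set.seed(2)
  d <- matrix(stats::rnorm(nch * 100), nch, 100)
  d[mi, ] <- 0
  r <- rereference_linked_mastoids(make_rec(d))
  expect_equal(r$data[1, ], d[1, ])
  # idempotence on mastoid-zeroed data
  r2 <- rereference_linked_mastoids(r)
  expect_equal(r2$data, r$data)

  # constant mastoids 2 and 4 uV: every scalp channel shifted by -3
  d2 <- matrix(5, nch, 10)
  d2[mi[1], ] <- 2; d2[mi[2], ] <- 4
  r <- rereference_linked_mastoids(make_rec(d2))
  expect_equal(r$data[1, ], rep(5 - 3, 10))
  expect_equal(r$data[ci, ], rep(-3, 10))        # recovered Cz
  expect_equal(r$data[ei[1], ], rep(5, 10))      # EOG untouched
  expect_equal(r$montage$channels$role[ci], "scalp_recovered")

  # channel differences are reference-invariant
  set.seed(3)
  d3 <- matrix(stats::rnorm(nch * 50), nch, 50)
  r3 <- rereference_linked_mastoids(make_rec(d3))
  i3 <- which(m$channels$label == "C3"); i4 <- which(m$channels$label == "C4")
  expect_equal(r3$data[i3, ] - r3$data[i4, ], d3[i3, ] - d3[i4, ])
})

test_that("epoch extraction: span, counts, edge drops", {
  m <- build_montage()
  nch <- nrow(m$channels)
  ev <- data.frame(sample = c(10L, 500L, 1200L),
                   marker = c("name_own", "name_stranger", "name_own"),
                   trial = 1:3)
  rec <- make_rec(matrix(0, nch, 2000), ev)
  ep <- extract_epochs(rec, "auditory")
  expect_equal(dim(ep$data), c(2, nch, 425))  # 1700 ms at 250 Hz
  expect_equal(ep$dropped$trial, 1L)          # event at sample 10: no baseline
  expect_equal(ep$dropped$reason, "edge")
  expect_equal(ep$trials$condition, c("stranger", "own"))
  expect_equal(range(ep$times_ms), c(-200, 1496))  # half-open [t_min, t_max)

  # visual markers + not-looking flag
  ev2 <- data.frame(sample = c(500L, 1200L),
                    marker = c("object_after_own", "object_after_stranger"),
                    trial = 1:2)
  rec2 <- make_rec(matrix(0, nch, 2000), ev2)
  ep2 <- extract_epochs(rec2, "visual", not_looking = c(TRUE, FALSE))
  expect_equal(dim(ep2$data)[1], 1)
  expect_equal(ep2$dropped$reason, "not_looking")
})

test_that("baseline correction zeroes the baseline and leaves bumps alone", {
  nch <- nrow(build_montage()$channels)
  d <- array(7, c(3, nch, 425))
  ep <- baseline_correct(make_epochs(d))
  expect_true(all(abs(ep$data) < 1e-12))

  # post-stimulus bump with silent baseline is unchanged
  d2 <- array(0, c(1, nch, 425))
  bump <- sin(seq(0, pi, length.out = 100))
  d2[1, 3, 101:200] <- bump  # starts after t=0 (sample 51)
  ep2 <- baseline_correct(make_epochs(d2))
  expect_equal(ep2$data[1, 3, 101:200], bump)
  # baseline mean is zero for every channel after correction
  set.seed(4)
  d3 <- array(stats::rnorm(2 * nch * 425), c(2, nch, 425))
  ep3 <- baseline_correct(make_epochs(d3))
  bl <- ep3$times_ms >= -200 & ep3$times_ms < 0
  expect_lt(max(abs(apply(ep3$data[, , bl], c(1, 2), mean))), 1e-9)
})

test_that("gliding-window rejection: exact thresholds per channel role", {
  ch <- build_montage()$channels
  nch <- nrow(ch)
  flat <- array(0, c(1, nch, 425))
  expect_false(reject_artifacts(make_epochs(flat))$rejection$rejected)

  # alternating +/-a segment has population SD exactly a
  seg <- rep(c(1, -1), 25)
  c3 <- which(ch$label == "C3")
  over <- flat; over[1, c3, 101:150] <- 51 * seg
  r <- reject_artifacts(make_epochs(over))$rejection
  expect_true(r$rejected)
  expect_equal(r$channel, "C3")
  # first offending window may only partially overlap the segment
  expect_gt(r$sd_uV, 50)
  under <- flat; under[1, c3, 101:150] <- 49 * seg
  expect_false(reject_artifacts(make_epochs(under))$rejection$rejected)

  # EOG rule: 85 uV rejected, 75 uV retained on VEOG only
  veog <- which(ch$label == "VEOG")
  eog_hi <- flat; eog_hi[1, veog, 201:250] <- 85 * seg
  expect_true(reject_artifacts(make_epochs(eog_hi))$rejection$rejected)
  eog_lo <- flat; eog_lo[1, veog, 201:250] <- 75 * seg
  expect_false(reject_artifacts(make_epochs(eog_lo))$rejection$rejected)
})

test_that("optimized rejection equals the brute-force scan on random epochs", {
  ch <- build_montage()$channels
  nch <- nrow(ch)
  set.seed(11)
  n_ep <- 100
  d <- array(stats::rnorm(n_ep * nch * 425, sd = 18), c(n_ep, nch, 425))
  # salt some epochs with borderline segments
  for (i in seq(2, n_ep, by = 7))
    d[i, sample(nch, 1), 150:199] <- stats::rnorm(50, sd = stats::runif(1, 40, 90))
  ep <- reject_artifacts(make_epochs(d))
  oracle <- vapply(seq_len(n_ep), function(i)
    oracle_reject_epoch(d[i, , ], ch$role, 50, 80, 50), TRUE)
  expect_identical(ep$rejection$rejected, oracle)
  expect_gt(sum(oracle), 0)
  expect_gt(sum(!oracle), 0)
})

test_that("event conservation: retained + rejected + dropped = total", {
  cfg <- simulation_config(n_trials = 40, seed = 13)
  sch <- generate_schedule(13, n_trials = 40)
  rec <- simulate_subject(cfg, sch, "ten", seed = 14)
  rec <- inject_artifacts(rec, cfg$noise, seed = 15)
  ep <- preprocess_subject(rec)$auditory
  expect_equal(sum(!ep$rejection$rejected) + sum(ep$rejection$rejected) +
                 nrow(ep$dropped), 40)
})

test_that("inclusion requires >= 10 artifact-free trials in both conditions", {
  counts <- data.frame(
    subject = rep(c("a", "b", "c"), each = 2), modality = "auditory",
    condition = rep(c("own", "stranger"), 3),
    n_retained = c(10, 10, 9, 40, 30, 25))
  inc <- apply_inclusion(counts)
  expect_equal(inc$included[inc$subject == "a"], TRUE)
  expect_equal(inc$included[inc$subject == "b"], FALSE)
  expect_equal(inc$included[inc$subject == "c"], TRUE)
  inc5 <- apply_inclusion(counts, min_trials = 5)
  expect_true(all(inc5$included))
})
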