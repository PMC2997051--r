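---
title: "infanterp: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{infanterp: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(infanterp)
```

This vignette is the package's own account of what it computes and why. It
documents the simulation model, the preprocessing conventions, the
statistical decomposition, every tunable parameter that matters, and the
design decisions taken where the design was genuinely open. It states no
empirical result that the test suite or acceptance script does not itself
compute.

## 1. The experiment the package encodes

A two-group infant ERP design: 5-month-olds hear their own name or a
stranger's name (one block, 200 trials, 100 per condition), and 750–850 ms
after the fixed 1500 ms name window see a novel object for 1000 ms, with an
800–1200 ms blank inter-trial interval. One group hears ten different
control names, the other a single control name. Presentation order is
pseudo-random with two hard constraints: never three identical conditions in
a row, and every consecutive block of 20 trials contains each of the 10
objects exactly twice, once per condition. `generate_schedule()`
rejection-samples each 20-trial block (shuffling the 10 objects × 2
conditions until the run-length constraint holds across the block boundary,
bounded at 10⁴ retries — an effectively impossible bound to hit for this
constraint density, so hitting it signals a broken sampler).

EEG: 23 scalp sites of the 10-20 system at 250 Hz referenced to Cz, two
mastoids, bipolar HEOG/VEOG. The 23 labels are not fully dictated by the
design; the package fixes a standard complement (`build_montage()`)
containing the nine electrodes that enter any analysis (F3, FC3, C3, F4,
FC4, C4, P3, Pz, P4) plus frontal-pole, temporal, centro-parietal and
occipital sites. Only the analysis nine, the EOG and the mastoids can affect
any reported number.

## 2. The synthetic cohort model

Real infant EEG for this design is not publicly available, so the package
generates it. The generator is a *stated world*, not a tuning knob: its
defaults are fixed once, documented here, and the tests interrogate the
pipeline against that world.

**Background activity.** Per-channel independent Gaussian 1/f^β noise
(`noise_spec()`, β = 1, RMS 15 µV). Band-limited infant scalp EEG commonly
shows tens of µV; 15 µV RMS per channel is a realistic middle figure. The
1/f spectrum reproduces the dominance of slow activity that makes infant
baselines wander; it deliberately omits rhythmic (alpha-range) components
and inter-channel correlation — see §7.

**ERP components.** Each component (`component_spec()`) is a Hann bump:
amplitude A at the peak, rising from the window start as half a Hann window
and falling to the window end as another half. Because each half-cosine
lobe averages A/2, the mean over the full support is A/2 regardless of peak
placement, which gives closed-form expectations for the windowed
mean-amplitude measure. Peaks may shift per group × condition
(`latency_shift_ms`) within the fixed support; a shift that pushes the peak
outside the support is an error, not a silent clamp.

The default template (`default_components()`) mirrors the qualitative
finding structure of own-name studies:

| Component | Support (ms) | Peak | Topography | Effect structure |
|---|---|---|---|---|
| anterior_shift | 80–400 | 240 | fronto-central, +| own − stranger = +6 µV in the one-name group only |
| n200_600 | 200–600 | 400 | parietal, − | own − stranger = −7 µV in the ten-name group only |
| nc | 420–730 | 550 | fronto-central, − | own peak 40 ms later, both groups |
| extended_nc | 700–1200 | 945 | fronto-central, left 1.3 / right 0.7, − | own − stranger = −3 µV, both groups |

Directions are the scientific content; magnitudes are free simulation
parameters. They were sized **a priori** as *large* effects by a standard
power argument: at the test scale (15 subjects/group, ~20 retained trials
per condition), the subject-level SD of a fronto-central windowed-mean
condition difference under the default noise is about 2 µV, so a 6 µV
configured amplitude difference (≈3.4 µV after the Hann window-mean factor)
gives a between-group interaction noncentrality above 4 — power well above
0.9 for the planned tests. The power property in the acceptance suite then
verifies this by direct simulation, not by the formula.

**Between-subject variability.** Each subject scales all component
amplitudes by a multiplier drawn from N(1, 0.3²) truncated at 0 — enough
heterogeneity for realistic subject-level statistics without changing any
expectation's sign.

**Artifacts.** Blinks are ~300 ms Hann transients (full amplitude on VEOG,
30% HEOG, 25–50% frontal spread); movements are ~500 ms Hann-enveloped
broadband bursts on all scalp/mastoid channels; both occur at Poisson times.
The rates are the one calibration the design itself prescribes: they were
set (blink 14/min at 200 µV, movement 70/min at 120 µV) so that the mean
number of auditory trials surviving the rejection rule falls where such
infant experiments report it — a handful of dozens out of 200 — and then
frozen. This is a statement about how messy infant sessions are, not about
any analysis outcome.

**Determinism.** Every random draw descends from the master seed through
`derive_seed()` (a fixed affine map mod 2³¹ − 1); all generator functions
run under a local RNG state and restore the caller's.

## 3. Preprocessing conventions

The order is fixed: band-pass filter on the *continuous* data first, then
linked-mastoid re-reference, epoching, baseline correction, rejection.

**Filter.** 0.3–20 Hz, 1501 taps, zero phase (`filter_spec()`). With no
filter-design package assumed present, the design is the textbook
Hamming-windowed sinc; its realized response is verified in the tests
(10 Hz within 1% of unity, DC below −20 dB — the design achieves about
−55 dB). Zero phase is exact, not approximate: the taps are symmetric
(linear phase), applied by a single FFT convolution with the group delay
removed and reflection padding at the edges, so no frequency is phase
shifted. The alternative-filter analyses some labs prefer are supported by
making `filter_spec` an argument everywhere rather than a constant. The
online acquisition low-pass at 0.27 × fs = 67.5 Hz precedes digitization
and is represented only as the documented constant
`acquisition_lowpass_Hz()`; re-applying it offline would be wrong.

A consequence worth knowing: a 0.3 Hz high-pass removes a few percent of
the slow content of a 300 ms monophasic bump, so noise-free end-to-end
checks recover configured amplitudes to within ~5–10%, not machine
precision. The tests budget for exactly this and nothing more; the
epoch-identity test on *unfiltered* data is exact to 1e-12.

**Re-reference.** Every scalp and mastoid channel gets mean(M1, M2)
subtracted; bipolar EOG is untouched. Cz — identically zero relative to the
recording reference — is recovered as −mean(M1, M2) and kept as a data
channel (role `scalp_recovered`). It sits in no analysis ROI, so this
cannot change a reported number, but it makes the rejection rule see the
full montage.

**Epochs.** Half-open [−200, 1500) ms around each event, time zero at
onset: 425 samples at 250 Hz. Events without full data coverage are
dropped with reason `edge`; visual trials flagged by the optional
"not-looking" per-trial indicator (the stand-in for video-coded looking)
are dropped with reason `not_looking`. Internally sample indices are
1-based, as is idiomatic in R; exported JSON sidecars use 0-based indices,
the convention of EEG sidecar formats.

**Baseline.** Mean over [−200, 0) per epoch and channel, subtracted.

**Rejection.** An epoch is rejected iff any channel has any 200 ms
(50-sample) window — slid sample by sample over the whole epoch span,
baseline included — whose *population* SD (divide by n, not n−1; the
difference at n = 50 is 1%) exceeds 80 µV (EOG) or 50 µV (every other
channel). The implementation uses running sums after centering each
channel; a brute-force all-window two-pass scan must agree exactly, and the
test suite enforces that on random epochs. The first offending channel and
window are logged per rejected trial. The original workflow also included
offline visual inspection; that is irreproducible and is deliberately
replaced by the automatic rule alone.

**Inclusion.** A subject enters a modality's analyses only with ≥ 10
artifact-free trials in each condition, evaluated separately for auditory
and visual averages.

## 4. Measurement

Two measure types, matching how components with and without a clear peak
are treated:

* `mean_amplitude()` — mean of all data points of the ROI channels within
  the half-open window.
* `negative_peak()` — per ROI channel, the most negative sample in the
  window (ties to the earliest latency), then the *average of the
  per-channel peaks* (amplitude and latency). "Averaging the peaks" is
  implemented per-electrode-then-average; the alternative
  (peak of the ROI-averaged waveform) is available behind
  `peak_of_average = TRUE` for sensitivity analyses. The peak is the global
  window minimum with no local-minimum requirement — robust on noisy
  infant averages.

Grand averages are unweighted means across subject averages (not
trial-count-weighted), conventional in ERP work.

A property users of peak latencies should know (the tests document it
rather than hide it): under realistic noise, the argmin of a broad bump is
pulled toward the bump's flatter side and condition differences in peak
latency *attenuate toward zero*. The latency-recovery acceptance check
therefore runs at high SNR, where it verifies the measurement path to
within the 2-sample discretization allowance; the moderate-noise behaviour
is visible in the power test, which still detects the 40 ms shift reliably
at n = 15/group.

## 5. Statistics

**Mixed ANOVA.** `mixed_anova()` implements the balanced two-group
repeated-measures decomposition from scratch via cell means: the between
effect is tested against subjects-within-groups; each within effect and its
Group interaction against its own factor × subject-within-group stratum;
with two within factors the three-way stratum is obtained by subtraction
from the total. All within factors have two levels, so sphericity (and any
Greenhouse–Geisser machinery) is moot by construction. Partial eta squared
is SS_effect / (SS_effect + SS_error_of_its_stratum). Degenerate inputs are
defined, not crashed: zero effect SS gives F = 0, p = 1; zero error SS with
nonzero effect gives F = ∞, p = 0, ηp² = 1. The implementation is checked
two independent ways: an explicit textbook cell-means oracle, and base R's
`aov()` with an `Error(subject/(name*hemisphere))` stratum specification.
For a single 2-level within factor and one group, F equals the squared
paired t — asserted numerically.

When subject exclusions leave the groups unequal, the reporting layer
(`run_statistics()`) trims the larger group deterministically (highest
subject IDs first, with a message naming the trimmed subjects) before
fitting; an analysis that remains impossible (for example, a group
eliminated entirely at very small scale) is reported as unavailable with
the reason instead of aborting the battery.

**Post hocs.** Classic equal-variance paired/independent t
(`posthoc_tests()`; identical samples give t = 0, p = 1, and a constant
nonzero difference is flagged degenerate rather than reported as t = ∞
without warning) and Scheffé-adjusted cell-mean contrasts
(`scheffe_test()`). Which error term a mixed-design Scheffé should use is
genuinely underdetermined; the package takes the pooled error supplied by
the caller and documents that the conventional choice here is the pooled
within-cell mean square. The adjustment can only increase p, and the tests
assert that monotonicity.

**Wilcoxon.** `wilcoxon_effect()` reports "k out of n showed the effect"
with k the count of strictly predicted-sign subject differences (zeros
count as not showing — the only reading under which k + complementary
counts partition n), drops zeros before ranking (Wilcoxon's original
procedure, matching the classic implementations of that era), uses the
exact signed-rank distribution for n ≤ 25 without ties and a tie- and
continuity-corrected normal approximation otherwise, and reports Z from the
smaller rank sum so it is ≤ 0, the classic reporting convention. Exactness
is verified against full 2⁶ sign enumeration.

**Controls.** `split_half_analysis()` re-measures each subject's first and
second experiment half (by original trial index) and adds a 2-level
within factor Half: a time-stationary effect shows no Half interaction,
a fast-learning artifact would. Subjects lacking the configurable minimum
(default 5) trials per half × condition are excluded; if that unbalances
the groups, the larger group is trimmed (highest subject IDs first, a
deterministic rule) because the balanced decomposition requires equal n.
`median_split_snr_check()` splits the cohort at the median retained-trial
count and t-tests the component measure between halves: a null result
argues the effect is not a low-SNR artifact.

p-values are reported exact, never as thresholds; any comparison against
conventional cutoffs happens in the reporting layer.

## 6. Reduced-scale testing worlds

Simulating 30 subjects × 200 trials with ~84% artifact rejection for every
property test would spend the time budget on realism the statistics never
see. The heavy properties therefore run on cohorts of 15 subjects/group
with 40–60 *clean* trials per subject: the retained trial counts per
condition (~20–30) then match what the full-scale world retains after
rejection, so the subject-level measurement noise — the quantity that
matters for the statistics — is comparable, at a fraction of the cost. The
full-scale world (200 trials, artifacts on) is exercised end-to-end by the
single-subject conservation test and the pipeline determinism test.

## 7. What the generator does not emulate — and what a green test means

The synthetic world omits: volume-conduction correlation between channels;
rhythmic (alpha/theta) activity; non-Gaussian heavy-tailed noise; realistic
blink morphology and saccades; drifts in attention or arousal across the
session (components are time-stationary by default, which is exactly what
the split-half control should find); and any head-model forward physics —
topographies are set directly as weights. Green tests therefore establish
that the *pipeline* is correct: that the filter, rejection rule,
measurement and ANOVA recover known ground truth injected into realistic
noise and survive the design's constraints. They do not establish that real
5-month-olds show these effects, nor validate the component model itself
against biology.

## 8. Known limitations

* The rejection rule replaces (and cannot reproduce) manual visual
  inspection; retention statistics are calibrated to the reported range
  but per-trial agreement with a human editor is undefined.
* Peak-latency measures attenuate under noise (§4); between-condition
  latency differences are conservative, not inflated.
* The balanced ANOVA requires equal group sizes and complete within-cells;
  unbalanced cohorts must be trimmed (the split-half control does this
  deterministically) rather than fitted with Type-III machinery.
* Recordings are serialized as CSV + JSON sidecar rather than EDF: no EDF
  writer is available in the supported dependency set, and the plain-text
  container keeps artifacts diffable and platform-neutral. The sidecar
  carries everything an EDF header would (fs, units, channel roles,
  events).
* Scheffé for mixed designs uses a caller-supplied pooled error; other
  software may choose a different stratum and disagree numerically.
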