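# infanterp

Simulation and analysis pipeline for an infant own-name event-related
potential (ERP) experiment, built as a tested R package.

## The scientific problem

By five months of age, infants recognize the sound of their own name. The
question this kind of experiment asks is whether the own name also works as a
*social cue*: does hearing it change how the infant processes what they see
next? In the design encoded here, 5-month-olds hear either their own name or
a stranger's name (200 trials, 100 per condition), and after each name see a
novel object. EEG is recorded from 23 scalp electrodes of the 10-20 system
(250 Hz, referenced to Cz, bipolar EOG, mastoids), and four ERP components
are measured on region-of-interest averages:

| Component | Modality | Window | Measure | ROI |
|---|---|---|---|---|
| anterior positive shift | auditory | 100–380 ms | mean amplitude | F3/FC3/C3, F4/FC4/C4 |
| N200-600 | auditory | 200–600 ms | negative peak (amplitude + latency) | P3/Pz/P4 |
| Nc | visual | 450–700 ms | negative peak (amplitude + latency) | F3/FC3/C3, F4/FC4/C4 |
| extended Nc | visual | 890–1000 ms | mean amplitude | F3/FC3/C3, F4/FC4/C4 |

The statistics are mixed-design ANOVAs — 2 (Group: ten vs one control name,
between subjects) × 2 (Name: own vs stranger) × 2 (Hemisphere) on
fronto-central measures, 2 × 2 on parietal measures — with F, p, and partial
eta squared ηp² = SS_effect / (SS_effect + SS_error) per effect, Scheffé and
t post hocs, and Wilcoxon signed-rank "k out of n infants showed the effect"
summaries. Raw infant EEG for such studies is not public, so the package
includes a first-class synthetic cohort generator: 1/f background noise,
Hann-bump ERP components with a configurable group/condition effect
structure, and blink/movement artifacts calibrated so that the gliding-window
rejection rule (SD over a 200 ms sliding window > 80 µV on EOG or > 50 µV on
any other electrode) retains trial counts in the reported range.

## Pipeline

```
simulate_cohort()  ->  preprocess_subject()        ->  build_measurement_table()  ->  run_statistics()
  schedules, EEG        0.3-20 Hz zero-phase FIR        per-subject ERP averages        mixed ANOVAs,
  + artifacts           (1501 taps), linked-mastoid     mean amplitude / negative       post hocs,
                        re-reference, epoching,         peak over ROIs                  Wilcoxon
                        baseline, gliding-window
                        rejection, >= 10-trial inclusion
```

`run_all(run_config(...))` ties the stages into one deterministic run with a
plain-text artifact tree (schedules, rejection log, inclusion report,
measurement CSV, ANOVA/non-parametric reports, grand averages, manifest).
A command-line entry point lives in `inst/cli/infanterp.R`.

## Worked example

```r
library(infanterp)

summarize_name_lengths(name_length_table())
#>     own_mean_ms control_mean_ms overall_mean_ms
#>             648             651             650

round(visual_angle(7.09, 70), 2)   # vertical angle of the object photos
#> [1] 5.8

sched <- generate_schedule(seed = 1)
table(sched$condition); max(rle(sched$condition)$lengths)
#>      own stranger
#>      100      100
#> [1] 2

cfg <- simulation_config(n_subjects_per_group = 15, n_trials = 40,
                         artifacts = FALSE, seed = 2026)
cohort <- simulate_cohort(cfg)
processed <- lapply(cohort, function(s) list(subject_id = s$subject_id,
  group = s$group, epochs = preprocess_subject(s$recording)))
mt <- build_measurement_table(processed, min_trials = 10)
st <- run_statistics(mt$measurements)

st$anova$anterior_shift
#> group                        F(1,28) = 18.47, P = 0.0001882, eta_p^2 = 0.397
#> name                         F(1,28) = 15.09, P = 0.0005722, eta_p^2 = 0.350
#> group:name                   F(1,28) = 14.27, P = 0.0007604, eta_p^2 = 0.338
#> hemisphere                   F(1,28) = 7.67, P = 0.009843, eta_p^2 = 0.215
#> group:hemisphere             F(1,28) = 4.19, P = 0.05007, eta_p^2 = 0.130
#> name:hemisphere              F(1,28) = 0.18, P = 0.674, eta_p^2 = 0.006
#> group:name:hemisphere        F(1,28) = 0.05, P = 0.8244, eta_p^2 = 0.002

w <- st$nonparam$anterior_shift_one
sprintf("%d out of %d showed the effect, Z = %.2f, P = %.4f",
        w$n_positive, w$n_total, w$z, w$p)
#> [1] "13 out of 15 showed the effect, Z = -3.10, P = 0.0006"
```

Reading the output: the simulated cohort was configured with an own-name
anterior positivity only in the one-control-name group, and the Group × Name
interaction (F(1,28) = 14.27, ηp² = .34) together with the per-group Wilcoxon
count (13 of 15 one-name infants show own > stranger) recovers exactly that
structure from the raw simulated EEG. The Name main effect on Nc peak latency
(`st$anova$nc_latency`: F(1,28) = 20.99) recovers the configured 40 ms later
Nc peak after the own name.

## Documentation

The methods vignette (`vignettes/infanterp-methods.Rmd`) describes the
simulation model and its assumptions, the preprocessing conventions
(zero-phase filtering, rejection rule, coordinate conventions), the ANOVA
decomposition, parameter defaults with their rationale, and known
limitations — including what a green synthetic-cohort test does and does not
establish about real infant EEG.
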