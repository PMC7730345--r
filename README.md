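# etspan

Eye-Time Span measurement for metronome-synchronized music sight reading.

## What this is for

During sight reading, skilled musicians keep their eyes ahead of the music
they are producing.  Classic *eye-hand span* measures quantify this lead
relative to the performer's hands, which makes them hostages of the motor
performance: a hesitated note onset inflates the span, and unplayed symbols
cannot be measured.  When the performance is paced by a metronome, musical
time is observable on its own, and the score itself — quarter notes engraved
at equal distances — can be read as a graph of that time.

The **Eye-Time Span (ETS)** of a fixation *F* is the backward-projected
distance, in beats, between the fixation's landing position on the score and
the position of the metrical cursor at fixation onset:

    ETS(F) = b(x_F) − m(t_F)

where `b(·)` maps horizontal pixels to beat positions and `m(·)` maps
recording time to metrical time (anchored to the metronome clicks).  An ETS
of 1.5 beats means the reader is looking at material the music will reach
1.5 beats later.  The package is for eye-movement researchers who want this
measure end to end:

* **score model** — monotone pixel↔beat mapping, note AOIs with the
  midway-cut / 35-px-margin conventions (`score_layout`, `x_to_beat`,
  `assign_aoi`);
* **synchronization** — circular-median click-phase estimation from
  metronome-aligned timestamps, metrical indexing of fixation onsets
  (`estimate_click_phase`, `tempo_spec`, `metrical_time`);
* **spans** — first-fixation extraction, ETS, incoming saccades converted to
  beats, the three standard exclusion rules, and the single-item-lag /
  forward-projective baseline spans (`compute_spans`, `apply_exclusions`);
* **simulator** — stimulus melodies built by the five-bar and multi-staff
  construction rules, mechanical or jittered performances, and scanpaths
  with gamma look-ahead, injectable attraction effects, landing noise and
  note skipping (`generate_melody`, `sim_config`, `simulate_experiment`);
* **analysis** — GEE with gamma variance, inverse link, exchangeable working
  correlation and cluster-robust Wald tests, post hoc contrasts with
  Tukey-style multiplicity adjustment, Spearman ETS–saccade association
  (`fit_gee`, `posthoc_contrasts`, `spearman_association`);
* **I/O + CLI** — fixation TSV and JSON/YAML trial configs in, span CSVs
  with exclusion-summary sidecars out, plus an `inst/cli/etspan` script with
  `simulate | compute-spans | analyze | report` subcommands.

## Worked example

Simulate a 30-participant experiment (6 trials at each of 60 and 100 bpm,
three melodic conditions) with a 1.3-fold *early attraction* effect at the
skip-target notes, run the measurement chain, and test for it:

```r
library(etspan)

cfg <- sim_config(seed = 42, attraction_multiplier = 1.3)
rec <- measure_experiment(simulate_experiment(cfg))

mean(rec$ets_beats[rec$excluded == "none"])
#> [1] 2.266418

fit <- fit_gee(ets_beats ~ condition * factor(note_pos) +
                 factor(tempo_bpm) + expertise,
               rec, id = "participant_id")
fit$wald
#>                         term df chisq        p  p_asymp
#> 1                  condition  2  28.4 7.11e-05 6.90e-07
#> 2           factor(note_pos)  3  33.3 1.04e-04 2.73e-07
#> 3          factor(tempo_bpm)  1  61.9 1.13e-08 3.70e-15
#> 4                  expertise  1  57.5 2.35e-08 3.46e-14
#> 5 condition:factor(note_pos)  6  45.3 4.65e-04 4.05e-08

subset(posthoc_contrasts(fit, rec, across = "condition",
                         within = "note_pos"), p_adj < 0.05)
#>   within           contrast estimate     se     z    p_adj
#> 1      1   barline - midbar    0.277 0.0664  4.17 8.60e-05
#> 2      1 barline - stepwise    0.350 0.0726  4.82 3.78e-06
#> 7      3   barline - midbar   -0.380 0.1201 -3.17 4.31e-03
#> 9      3  midbar - stepwise    0.454 0.1321  3.43 1.70e-03
```

Read the output the way a condition analysis is read: the mean ETS sits
around 2.3 beats; the condition-by-note interaction is significant (Wald
χ² = 45.3, small-sample-calibrated p < .001); and the adjusted contrasts
localize the effect exactly where it was injected — in the bar-line
condition the span peaks on the first beat of the bar (the note after the
bar-line skip, +0.28 to +0.35 beats against the other conditions), in the
mid-bar condition on the third beat (+0.38 to +0.45 beats).  Tempo and
expertise shift the span overall.  With `attraction_multiplier = 1` the
interaction test holds its nominal 5% size, which the test suite verifies
over 200 replicate experiments.

The same chain runs from files via the CLI:

```sh
Rscript inst/cli/etspan simulate --seed 7 --out run/
Rscript inst/cli/etspan compute-spans --fixations run/fixations.tsv \
        --config run/dataset.json --out run/spans.csv
Rscript inst/cli/etspan analyze --spans run/spans.csv --out run/analysis
Rscript inst/cli/etspan report --spans run/spans.csv \
        --analysis run/analysis --out run/report.md
```

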