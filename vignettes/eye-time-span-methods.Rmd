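---
title: "Measuring the Eye-Time Span: model, simulator and analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the Eye-Time Span: model, simulator and analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(etspan)
```

## The measurement problem

How far ahead of the music do the eyes run during sight reading?  Classic
eye-hand span measures anchor the answer to the performer's hands: either
forward, asking where the eyes are when a note is struck, or by pairing the
first fixation on a note with the later execution of that same note
(single-item lag).  Both entangle the oculomotor question with the motor
performance: a deliberately delayed note onset lengthens the measured span
without any change in visual behaviour, and notes that are never played
(rests, errors) cannot be measured at all.

When the performance is paced by a metronome, musical time itself becomes
observable.  The **Eye-Time Span (ETS)** of a fixation \(F\) is defined
backwards from the eyes:

\[
\mathrm{ETS}(F) \;=\; b(x_F)\; -\; m(t_F),
\]

where \(b(x_F)\) is the beat position corresponding to the fixation's
horizontal landing coordinate on the score, and \(m(t_F)\) is the metrical
time (in beats) at the fixation's onset.  A span of 1.5 beats means the eyes
landed on material that the metrical cursor will only reach 1.5 beats later.
No performance data enter the definition; with a perfectly mechanical
performance the ETS (converted to seconds) coincides with the single-item
lag, which the test suite verifies as an exact identity.

The package implements the full measurement chain for this quantity, a
synthetic-data generator that can inject *early attraction* (longer
look-ahead at designated complex notes) and *distant attraction* (longer
incoming saccades), and the marginal-model analysis used to detect those
effects.

## The score as a metrical time scale

A simply engraved score -- quarter notes at equal horizontal distances --
can be read as a visual graph of metrical time.  `score_layout()` holds an
ordered set of `(beat, x-pixel)` anchor pairs; `x_to_beat()` interpolates
piecewise-linearly through them and extrapolates beyond the first/last
anchor with the adjacent segment's slope.  Non-uniform engraving (wider
spacing across bar lines, as in realistic layouts) is handled
segment-locally, which matters for saccade amplitudes: a 15-px saccade over
a 15-px-per-beat region is one beat regardless of how the neighbouring bar
is spaced.  `beat_to_x()` is the exact inverse; the suite checks the
round-trip to 1e-9 and strict monotonicity on random anchor sets.

Fixations are assigned to notes by rectangular areas of interest (AOIs):
vertical cuts midway between note stems (or note heads, in the
`head_midpoint` dialect), half-open `[left, right)` with boundary ties going
right so the AOIs partition the region deterministically.  Vertically an
AOI extends 35 px beyond the outermost staff lines by default -- a
tolerance that keeps staff-directed fixations while discarding glances at
fingering digits or away from the score.  The 35-px default is taken from
the single-staff dialect; the multi-staff dialect does not pin this value
down, so the same default is used there without claiming more than
plausibility, and it is a constructor argument throughout.

## Anchoring metrical time to the recording clock

The metronome click recurs every \(60/\mathrm{bpm}\) seconds.  Events
produced on clicks (the experimenter's screen-switch key presses) leave
timestamps in the recording; their residues modulo the beat period estimate
the click phase.  A plain median of the residues fails when they straddle
the wrap point (residues 0.999 and 0.001 should average to the boundary,
not to 0.5), so `estimate_click_phase()` takes the **circular median**, the
observed residue minimizing the summed circular distance.  Away from the
boundary this equals the ordinary median, and a property test confirms
invariance under shifting any timestamp by whole periods.  As a quality
check the circular standard deviation of the residues is compared against a
quarter period; larger dispersion triggers a warning (the phase is still
returned -- the measurements are then suspect, and no correction is
attempted).

`tempo_spec()` snaps the configured performance start to the nearest click
(performances begin on a click) and `metrical_time()` is then plain
affine arithmetic: clicks 300 ms after each full second at 60 bpm, a
performance starting 12.3 s into the recording, and a fixation onset at
14.5 s give \(m = 2.2\) beats.

## First fixations, exclusions, baseline spans

`first_fixations()` maps each note to the earliest fixation inside its AOI,
keeping the immediately preceding raw fixation as the saccade launch site;
notes never fixated are simply absent (skipping is data, not an error).
`compute_ets()` uses the fixation's actual landing x, not the AOI centre.
Three exclusion rules flag first fixations that are irrelevant or
artifactual for span analysis, applied in order with first match winning:

1. negative ETS (`neg_ets`),
2. regressive (leftward) incoming saccades (`regressive`); a zero-length
   displacement is *not* regressive,
3. incoming saccades longer than the ETS plus two beats
   (`sacc_gt_ets_plus2`), discarding long re-entries after glancing back.

Exclusion never promotes a later fixation to "first", and a first fixation
with no preceding fixation keeps its ETS with an undefined saccade; both
choices keep the record set a pure annotation of the raw stream
(idempotence is property-tested).  The two baseline measures --
`single_item_lag()` and `forward_projective_span()` -- are computed only
when a performance log is supplied; within a fixation the forward span
falls linearly as the cursor advances, which the suite uses to demonstrate
how the approaches differ.

## What the simulator generates, and what it does not

`simulate_scanpath()` draws, for each note \(n\) with beat \(\beta_n\)
(unless skipped with probability `p_skip`), a look-ahead distance

\[
L_n \sim \mathrm{Gamma}\!\left(k,\; \mathrm{mean} = \mu\, a_n\, c\right),
\]

places the first-fixation onset so that \(m(t) = \beta_n - L_n\), and lands
it at \(b^{-1}(\beta_n + \varepsilon_n)\) with
\(\varepsilon_n \sim N(0, \sigma^2)\).  Here \(a_n\) is the attraction
multiplier at notes tagged `skip_target` (optionally extended
`attraction_window` notes backwards, mirroring anticipatory effects on the
notes preceding a skip), and \(c\) collects participant- and tempo-level
multipliers.  Onsets are forced to stay strictly increasing and after the
score display onset; affected notes are flagged `clipped` in the `truth`
attribute, because truncation changes what the measurement chain can see.
Everything is driven by one RNG substream per (participant, trial), so any
trial is reproducible in isolation.

Defaults are chosen once to represent a plausible controlled melody-reading
session: mean look-ahead $\mu = 2.1$ beats and shape $k = 6$ (SD about 0.86
beats, clearly right-skewed, matching the regime in which gamma marginal
models are the natural choice); landing noise $\sigma = 0.1$ beats (small
relative to the half-beat AOI width); 5% skipped notes; 30 participants
with 6 trials at each of 60 and 100 bpm; a 1.15 look-ahead multiplier at
the faster tempo (look-ahead in beats grows, but far less than
proportionally to tempo); and a 0.3-beat additive offset for the expert
half of the participants.

The generator's core correctness property is *round-trip recovery*: for
every non-clipped, non-skipped note whose landing stayed inside its own
AOI, the measured ETS equals \(L_n + \varepsilon_n\) to float precision.
The suite checks this at \(10^4\) notes, and the chain identity
\(\mathrm{ETS}(F) = \mathrm{ETS}(F_{prev}) - \Delta m + s\) (with \(s\) the
incoming saccade in beats) on every simulated trial.

What the simulator deliberately does not emulate: oculomotor realism
(main-sequence velocities, refixations, realistic fixation durations --
durations simply tile the inter-onset gaps), vertical gaze structure,
performance errors, and spontaneous regressions (the analysis excludes
them; an optional `regression_rate` injects far-ahead preview fixations
solely to exercise rule 2).  Passing tests therefore certify the
measurement algebra and the analysis calibration under a clean generative
model -- they do not certify robustness to messy empirical scanpaths.

## The marginal model

Span measurements are positive, right-skewed and correlated within
participants.  `fit_gee()` fits a population-average model with gamma
variance \(V(\mu) = \phi\mu^2\), the canonical inverse link
\(1/\mu = X\beta\) (the response stays on its natural beat scale; no log
transform), an exchangeable working correlation estimated from Pearson
residual cross-products, and the cluster-robust sandwich covariance.  The
dispersion \(\phi\) is estimated by Pearson moments and reported.  No GEE
solver dependency is used; the estimator is ~100 lines of IRLS with an
analytic exchangeable inverse, and the suite pins it against an
independent route (`glm` with gamma family plus clustered sandwich
standard errors) in the independence case, where the two must agree to
numerical precision.

### Small-sample calibration of the term tests

Term significance uses Wald statistics on coefficient blocks of the robust
covariance.  That covariance is the empirical covariance of \(G\)
per-cluster score contributions; when a term's dimension \(q\) is not
small relative to \(G\) (here \(q = 6\) interaction contrasts from
\(G = 30\) participants), referring \(W\) to \(\chi^2_q\) rejects far too
often -- a Hotelling-\(T^2\) situation.  The reported `p` therefore refers

\[
W \cdot \frac{G - q}{q\,(G - 1)} \;\sim\; F(q,\; G - q),
\]

which converges to the \(\chi^2\) reference as \(G\) grows (kept as
`p_asymp`).  The acceptance suite verifies the consequence directly: under
the simulator null the condition-by-note test rejects at the nominal 5%
level in 3--7% of 200 replicates of a 30-participant, 12-trial experiment,
while a 1.3-fold attraction multiplier is detected in essentially every
replicate.

`model_selection_expertise()` implements the screening step of dropping
expertise-involving interaction terms with \(p \ge .05\) and refitting
once.  `posthoc_contrasts()` compares model predictions on the response
(beats) scale pairwise across condition levels within each note position,
averaging the remaining factors with equal weights on the linear-predictor
scale, delta-method standard errors on the robust covariance, and a
single-step multivariate-normal (Tukey-style) adjustment over each
within-note family of pairwise contrasts.  `spearman_association()` gives
the rank correlation between ETS and incoming saccade length with
average-rank ties.

## Numerical choices and degenerate inputs

* IRLS stops at \(\max|\Delta\beta| < 10^{-10}\) (cap 50 iterations;
  non-convergence is an error carrying the step-size trace).  The
  exchangeable \(\alpha\) is clamped to \([-1/(\max_i n_i - 1) +
  10^{-6},\, 0.95]\) to keep the working inverse defined.
* The inverse link requires a positive linear predictor; leaving the
  positive range aborts with a diagnostic rather than silently stepping.
* AOI boundary ties go right; anchors, boundaries and onsets must be
  strictly increasing and are validated at construction.
* An all-skipped scanpath, an empty record set, a note never fixated, and
  a first fixation without predecessor are all representable and tested.
* Problem sizes in the shipped suite: \(10^4\)-note recovery runs, 100-trial
  lag-equivalence runs, and 2 x 200 replicates of the 30 x 12 calibration
  study (the whole suite runs in a few minutes on one core).

## Known limitations

* The measurement chain assumes fixation detection has already happened
  upstream; no velocity thresholding is provided.
* Multi-staff scores are handled per staff (each staff is its own monotone
  beat-pixel map); saccades across staff breaks are not converted.
* The exchangeable structure is a working assumption only; inference
  robustness comes from the sandwich, at the usual price in small-sample
  efficiency.
* Simulator fidelity bounds what green tests mean for real recordings (see
  above); in particular, exclusion rates in simulated data are near zero
  unless regressions are injected, whereas empirical data shows a
  several-percent regressive rate.
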