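# run expr under a fixed RNG state without disturbing the caller's stream
.with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(expr)
}

# deterministic per-(participant, trial) substream seed, kept below 2^31
.trial_seed <- function(seed, participant, trial) {
  ((seed %% 100000) * 16381 + participant * 1009 + trial * 31) %% 2147483647L
}

#' Simulation configuration
#'
#' Generative parameters for synthetic scanpaths.  Look-ahead distances are
#' drawn per note from a gamma distribution (right-skewed, like empirical
#' eye-time spans), with a multiplicative attraction effect at tagged notes,
#' Gaussian landing noise on the score surface, and occasional note skipping.
#'
#' Defaults emulate a temporally controlled melody-reading session: mean
#' look-ahead 2.1 beats with gamma shape 6 (SD about 0.86 beats, positive
#' skew), landing noise 0.1 beats, 5% skipped notes, 30 participants playing
#' 6 trials at each of 60 and 100 bpm, a 1.15 look-ahead multiplier at the
#' faster tempo, and a 0.3-beat additive offset for the expert group.
#'
#' @param seed Integer master seed.
#' @param n_participants,trials_per_tempo,tempi_bpm Design size.
#' @param lookahead_mean_beats Baseline mean look-ahead mu (beats, > 0).
#' @param lookahead_shape Gamma shape k (> 0); smaller is more skewed.
#' @param attraction_multiplier Multiplier a on the mean look-ahead at notes
#'   tagged `skip_target` (a = 1 is the null of no attraction).
#' @param attraction_window Number of notes before a tagged note to which the
#'   multiplier also applies (0 = target only).
#' @param landing_sd_beats Gaussian landing noise sigma (beats, >= 0).
#' @param p_skip Per-note probability of never receiving a first fixation.
#' @param expertise_offset_beats Additive mean shift for the expert half of
#'   the participants.
#' @param tempo_lookahead_mult Look-ahead multiplier at tempi above the
#'   slowest (spans grow sub-proportionally with tempo).
#' @param regression_rate Probability of injecting a far-ahead preview
#'   fixation right before a note's first fixation, which makes that incoming
#'   saccade regressive (for exercising exclusion rule ii); 0 by default.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_participants = 30L,
                       trials_per_tempo = 6L,
                       tempi_bpm = c(60, 100),
                       lookahead_mean_beats = 2.1,
                       lookahead_shape = 6,
                       attraction_multiplier = 1,
                       attraction_window = 0L,
                       landing_sd_beats = 0.1,
                       p_skip = 0.05,
                       expertise_offset_beats = 0.3,
                       tempo_lookahead_mult = 1.15,
                       regression_rate = 0) {
  cfg <- list(seed = as.integer(seed), n_participants = as.integer(n_participants),
              trials_per_tempo = as.integer(trials_per_tempo),
              tempi_bpm = as.numeric(tempi_bpm),
              lookahead_mean_beats = lookahead_mean_beats,
              lookahead_shape = lookahead_shape,
              attraction_multiplier = attraction_multiplier,
              attraction_window = as.integer(attraction_window),
              landing_sd_beats = landing_sd_beats,
              p_skip = p_skip,
              expertise_offset_beats = expertise_offset_beats,
              tempo_lookahead_mult = tempo_lookahead_mult,
              regression_rate = regression_rate)
  with(cfg, {
    stopifnot(lookahead_mean_beats > 0, lookahead_shape > 0,
              attraction_multiplier > 0, landing_sd_beats >= 0,
              p_skip >= 0, p_skip < 1, regression_rate >= 0,
              n_participants >= 1, trials_per_tempo >= 1)
  })
  structure(cfg, class = "sim_config")
}

# fixed five-bar melody templates (scale degrees 1..5 of the key, 16 quarter
# notes + final whole note); skips of a perfect fourth (3 steps) and fifth
# (4 steps) sit at the bar lines of bar 3, or two quarter-note beats after
.exp1_templates <- list(
  stepwise = c(1, 2, 3, 2, 3, 4, 5, 5, 4, 3, 2, 3, 2, 3, 4, 3, 3),
  barline  = c(1, 2, 3, 2, 3, 4, 5, 5, 1, 2, 3, 2, 5, 4, 3, 4, 3),
  midbar   = c(1, 2, 3, 2, 3, 4, 5, 4, 5, 5, 1, 2, 1, 1, 4, 3, 3))
.exp1_skip_targets <- list(stepwise = integer(0), barline = c(9L, 13L),
                           midbar = c(11L, 15L))

#' Generate a stimulus melody as a note-event table
#'
#' Two stimulus dialects are supported.  `"exp1"`: a five-bar melody on the
#' first five diatonic degrees -- four bars of quarter notes plus a final
#' whole note (17 notes), with note stems engraved at equal pixel distances.
#' In the `barline` condition a perfect fifth and a perfect fourth cross the
#' bar lines surrounding bar 3; in `midbar` the same skips sit two
#' quarter-note beats later; `stepwise` melodies move entirely by step (with
#' the note repetitions the skip conditions require).  The six notes around
#' the skip region (bar 2 note 4 through bar 4 note 1) carry the
#' `"analysis"` tag.  `"exp2"`: a multi-staff quarter-note melody (default 4
#' staves of 6 bars) in which each staff hides one minor-sixth skip in bars
#' 3-5; the chromatically altered target is always the last note of its bar,
#' reached by reversing stepwise motion and left by stepwise motion filling
#' the gap.  Matched stepwise-control bars are tagged `stepwise_control`.
#'
#' Skip landing notes are tagged `skip_target` and their predecessors
#' `pre_skip`.  Output is deterministic given `seed` (the exp1 templates are
#' fixed stimuli; exp2 filler voice-leading is seeded).
#'
#' @param dialect `"exp1"` or `"exp2"`.
#' @param condition exp1 melodic condition: `"stepwise"`, `"barline"` or
#'   `"midbar"` (ignored for exp2, whose bars embed both skip and control).
#' @param inversion Mirror the melody's contour (exp1).
#' @param seed Integer seed (exp2 filler).
#' @param bars_per_staff,n_staves exp2 geometry.
#' @param px_per_beat,x0 exp1 engraving: anchor spacing and left origin (px).
#' @param staff_y_top,staff_y_bottom Staff band of the (first) staff (px).
#' @return A [note_events()] table; exp2 adds `staff_index`, `midi`,
#'   `altered` columns and a `staff_geom` attribute
#'   (`data.frame(staff_index, y_top, y_bottom)`).
#' @export
generate_melody <- function(dialect = c("exp1", "exp2"),
                            condition = c("stepwise", "barline", "midbar"),
                            inversion = FALSE, seed = 1L,
                            bars_per_staff = 6L, n_staves = 4L,
                            px_per_beat = 57, x0 = 150,
                            staff_y_top = 500, staff_y_bottom = 534) {
  dialect <- match.arg(dialect)
  if (dialect == "exp1") {
    condition <- match.arg(condition)
    deg <- as.integer(.exp1_templates[[condition]])
    if (inversion) deg <- 6L - deg
    n <- length(deg)                       # 17: 16 quarters + whole note
    targets <- .exp1_skip_targets[[condition]]
    tags <- rep(list(character(0)), n)
    for (i in targets) {
      tags[[i]] <- c(tags[[i]], "skip_target")
      tags[[i - 1L]] <- c(tags[[i - 1L]], "pre_skip")
    }
    for (i in 8:13) tags[[i]] <- c(tags[[i]], "analysis")
    beat <- 0:16
    note_events(note_id = sprintf("b%dn%d", (beat %/% 4) + 1, (beat %% 4) + 1),
                beat_onset = beat,
                bar_index = (beat %/% 4) + 1L,
                pos_in_bar = as.integer(beat %% 4) + 1L,
                x_anchor = x0 + px_per_beat * beat,
                tags = tags,
                degree = deg,
                midi = c(60, 62, 64, 65, 67)[deg])
  } else {
    .generate_melody_exp2(seed, bars_per_staff, n_staves, x0,
                          staff_y_top, staff_y_bottom)
  }
}

# exp2: one minor-sixth skip per staff, target = last note of its bar,
# descending stepwise approach reversing at the skip, descending resolution
.generate_melody_exp2 <- function(seed, bars_per_staff, n_staves, x0,
                                  staff_y_top, staff_y_bottom) {
  if (bars_per_staff < 6L) stop("exp2 needs at least 6 bars per staff")
  .with_seed(seed, {
    first3 <- runif(1) < 0.5
    # per-staff target bars: first and last alike, middles complementing
    tb <- if (first3) c(3L, sample(c(4L, 5L)), 3L) else c(4L, sample(c(3L, 5L)), 4L)
    tb <- rep_len(tb, n_staves)
    # matched stepwise-control bar for target bars 3, 4, 5 -> bars 5, 2, 3
    cb <- c(`3` = 5L, `4` = 2L, `5` = 3L)[as.character(tb)]
    staves <- vector("list", n_staves)
    for (s in seq_len(n_staves)) {
      npb <- 4L
      n <- bars_per_staff * npb
      t_idx <- (tb[s] - 1L) * npb + npb          # target: last note of its bar
      deg <- integer(n)
      deg[(t_idx - 4):(t_idx - 1)] <- c(5L, 4L, 3L, 2L)  # stepwise descent
      deg[t_idx] <- 7L                                   # minor sixth above 2
      # filler before the approach: backwards +/-1 walk from degree 4/6
      if (t_idx - 5L >= 1L) {
        deg[t_idx - 5L] <- if (runif(1) < 0.5) 4L else 6L
        i <- t_idx - 6L
        while (i >= 1L) {
          step <- if (deg[i + 1L] <= 1L) 1L else if (deg[i + 1L] >= 8L) -1L
                  else sample(c(-1L, 1L), 1L)
          deg[i] <- deg[i + 1L] + step
          i <- i - 1L
        }
      }
      # after the skip: stepwise descent filling the gap, then bounded walk
      if (t_idx + 1L <= n) {
        for (i in seq(t_idx + 1L, n)) {
          prev <- deg[i - 1L]
          down_run <- i <= t_idx + 4L            # at least one bar downward
          step <- if (down_run && prev > 1L) -1L
                  else if (prev <= 1L) 1L else if (prev >= 8L) -1L
                  else sample(c(-1L, 1L), 1L)
          deg[i] <- prev + step
        }
      }
      pos <- rep(seq_len(npb), bars_per_staff)
      bar <- rep(seq_len(bars_per_staff), each = npb)
      # head-to-head spacing 41 px within a bar, 57 px across a bar line
      dx <- ifelse(pos == 1L, 57, 41)
      dx[1] <- 0
      midi <- c(60, 62, 64, 65, 67, 69, 71, 72)[deg]
      altered <- logical(n)
      midi[t_idx] <- midi[t_idx - 1L] + 8L       # chromatic minor sixth
      altered[t_idx] <- TRUE
      tags <- rep(list(character(0)), n)
      tags[[t_idx]] <- "skip_target"
      tags[[t_idx - 1L]] <- "pre_skip"
      skip_bar_notes <- which(bar == tb[s])
      ctrl_bar_notes <- which(bar == cb[s])
      for (i in skip_bar_notes) tags[[i]] <- c(tags[[i]], "skip_bar")
      for (i in ctrl_bar_notes) tags[[i]] <- c(tags[[i]], "stepwise_control")
      if (s <= 3L)   # lowest staff prone to off-screen data loss
        for (i in c(skip_bar_notes, ctrl_bar_notes))
          tags[[i]] <- c(tags[[i]], "analysis")
      staves[[s]] <- data.frame(
        staff_index = s, bar_local = bar, pos = pos,
        deg = deg, midi = midi, altered = altered,
        x = x0 + cumsum(dx), stringsAsFactors = FALSE)
      staves[[s]]$tags <- tags
    }
    all <- do.call(rbind, staves)
    npb <- 4L
    beat <- seq_len(nrow(all)) - 1L
    bar_global <- (all$staff_index - 1L) * bars_per_staff + all$bar_local
    notes <- note_events(
      note_id = sprintf("s%db%dn%d", all$staff_index, all$bar_local, all$pos),
      beat_onset = beat,
      bar_index = bar_global,
      pos_in_bar = all$pos,
      x_anchor = all$x + (all$staff_index - 1L) * 1e4,  # global monotonicity
      tags = all$tags,
      degree = all$deg, midi = all$midi, altered = all$altered,
      staff_index = all$staff_index)
    # true on-screen x is per staff; undo the global offset for display use
    notes$x_anchor <- notes$x_anchor - (notes$staff_index - 1L) * 1e4
    attr(notes, "staff_geom") <- data.frame(
      staff_index = seq_len(n_staves),
      y_top = staff_y_top + (seq_len(n_staves) - 1L) * 120,
      y_bottom = staff_y_bottom + (seq_len(n_staves) - 1L) * 120)
    notes
  })
}

#' Per-staff score layouts for a multi-staff melody
#'
#' A staff line is a monotone beat-to-pixel map of its own; fixations are
#' routed to a staff by their y position and mapped within it.
#'
#' @param notes A multi-staff [note_events()] table with `staff_index` and a
#'   `staff_geom` attribute (as produced by [generate_melody()] with
#'   `dialect = "exp2"`).
#' @param aoi_margin Vertical AOI margin (px).
#' @return A list of [score_layout()]s, one per staff, each with an attribute
#'   `note_ids` naming the notes it covers.
#' @export
staff_layouts <- function(notes, aoi_margin = 35) {
  geom <- attr(notes, "staff_geom")
  if (is.null(geom) || is.null(notes$staff_index))
    stop("notes lack staff_index/staff_geom; not a multi-staff melody")
  lapply(geom$staff_index, function(s) {
    sub <- notes[notes$staff_index == s, , drop = FALSE]
    lay <- score_layout(sub$beat_onset, sub$x_anchor,
                        staff_y_top = geom$y_top[geom$staff_index == s],
                        staff_y_bottom = geom$y_bottom[geom$staff_index == s],
                        aoi_margin = aoi_margin,
                        aoi_boundaries = aoi_boundaries_from_anchors(sub$x_anchor),
                        dialect = "head_midpoint")
    attr(lay, "note_ids") <- sub$note_id
    lay
  })
}

#' Single-staff layout for a note table
#'
#' Convenience constructor: anchors at the note positions, AOI cuts midway
#' between them.
#'
#' @param notes A [note_events()] table (single staff).
#' @param staff_y_top,staff_y_bottom Staff band (px).
#' @param aoi_margin Vertical AOI margin (px).
#' @param dialect Boundary convention label.
#' @return A [score_layout()].
#' @export
layout_from_notes <- function(notes, staff_y_top = 500, staff_y_bottom = 534,
                              aoi_margin = 35, dialect = "stem_midpoint") {
  score_layout(notes$beat_onset, notes$x_anchor,
               staff_y_top = staff_y_top, staff_y_bottom = staff_y_bottom,
               aoi_margin = aoi_margin,
               aoi_boundaries = aoi_boundaries_from_anchors(notes$x_anchor),
               dialect = dialect)
}

#' Mechanical performance onsets
#'
#' A performance perfectly synchronized to the metronome: each note sounds
#' exactly on its beat, `start + beat_onset * beat_period` seconds into the
#' recording.
#'
#' @param notes A [note_events()] table.
#' @param tempo A [tempo_spec()].
#' @return Named numeric vector of onsets (s), names = `note_id`.
#' @export
mechanical_performance <- function(notes, tempo) {
  stopifnot(inherits(tempo, "tempo_spec"))
  stats::setNames(tempo$start_snapped_s + notes$beat_onset * tempo$beat_period_s,
                  notes$note_id)
}

#' Humanly jittered performance onsets
#'
#' Mechanical onsets plus independent Gaussian timing noise; `sd_s = 0`
#' reduces exactly to [mechanical_performance()].
#'
#' @param notes A [note_events()] table.
#' @param tempo A [tempo_spec()].
#' @param sd_s Timing jitter SD (s).
#' @param seed Integer seed.
#' @return Named numeric vector of onsets (s).
#' @export
jittered_performance <- function(notes, tempo, sd_s = 0.02, seed = 1L) {
  base <- mechanical_performance(notes, tempo)
  if (sd_s == 0) return(base)
  base + .with_seed(seed, stats::rnorm(length(base), 0, sd_s))
}

# attraction multiplier per note: tagged notes and the window before them
.attraction_mult <- function(notes, cfg) {
  a <- rep(1, nrow(notes))
  idx <- which(has_tag(notes, "skip_target"))
  for (i in idx) {
    lo <- max(1L, i - cfg$attraction_window)
    a[lo:i] <- cfg$attraction_multiplier
  }
  a
}

#' Simulate a scanpath over a score
#'
#' Generative model of first-pass reading under metronome control: for each
#' note (unless skipped with probability `p_skip`) a look-ahead distance
#' `L ~ Gamma(shape k, mean mu * a * mean_mult)` is drawn, where `a` is the
#' attraction multiplier at and before tagged notes; the fixation onset is
#' placed so that the metrical cursor stands `L` beats before the note
#' (`metrical_time(onset) = beat - L`), and the landing position is the
#' note's anchor displaced by Gaussian noise on the beat scale
#' (`x = beat_to_x(beat + eps)`, `eps ~ N(0, sigma)`).  Onsets are clipped to
#' be strictly increasing and not earlier than the score display onset
#' (4 beats before the performance starts); clipped notes are flagged.
#' Durations fill the inter-onset gaps.
#'
#' The returned fixation table carries a `truth` attribute
#' (`data.frame(note_id, lookahead, landing_eps, skipped, clipped,
#' in_own_aoi)`) recording the generative values, so the measurement chain
#' can be checked against them: for every non-clipped note whose landing
#' stayed inside its own AOI, the measured ETS equals
#' `lookahead + landing_eps` exactly (up to float round-off).
#'
#' @param notes A [note_events()] table (single staff).
#' @param layout A [score_layout()] for those notes.
#' @param tempo A [tempo_spec()].
#' @param cfg A [sim_config()].
#' @param seed Integer seed for this scanpath.
#' @param mean_mult Extra multiplier on the mean look-ahead (participant
#'   expertise, tempo), applied on top of `cfg`.
#' @return A [fixations()] table with the `truth` attribute.
#' @export
simulate_scanpath <- function(notes, layout, tempo, cfg, seed = 1L,
                              mean_mult = 1) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(seed, {
    n <- nrow(notes)
    beat <- notes$beat_onset
    a <- .attraction_mult(notes, cfg)
    mu <- cfg$lookahead_mean_beats * a * mean_mult
    skipped <- stats::runif(n) < cfg$p_skip
    L <- stats::rgamma(n, shape = cfg$lookahead_shape,
                       rate = cfg$lookahead_shape / mu)
    eps <- if (cfg$landing_sd_beats > 0)
      stats::rnorm(n, 0, cfg$landing_sd_beats) else numeric(n)
    onset_raw <- tempo$start_snapped_s + (beat - L) * tempo$beat_period_s
    display_start <- tempo$start_snapped_s - 4 * tempo$beat_period_s

    keep <- which(!skipped)
    onset <- onset_raw[keep]
    clipped <- onset < display_start
    onset[clipped] <- display_start
    min_gap <- 1e-3
    if (length(onset) > 1L) for (i in 2:length(onset)) {
      if (onset[i] < onset[i - 1L] + min_gap) {
        onset[i] <- onset[i - 1L] + min_gap
        clipped[i] <- TRUE
      }
    }
    x <- beat_to_x(layout, beat[keep] + eps[keep])
    y <- rep((layout$staff_y_top + layout$staff_y_bottom) / 2, length(keep))

    # optional regression injection: a far-ahead preview fixation squeezed in
    # right before a note's first fixation makes its incoming saccade regressive
    reg <- cfg$regression_rate > 0 &
      stats::runif(length(keep)) < cfg$regression_rate
    reg[1] <- FALSE
    o2 <- x2 <- y2 <- numeric(0)
    if (any(reg)) {
      max_beat <- max(layout$anchors_beat)
      for (i in which(reg)) {
        o2 <- c(o2, onset[i] - min_gap / 2)
        x2 <- c(x2, beat_to_x(layout, min(beat[keep][i] + 2.5, max_beat)))
        y2 <- c(y2, layout$staff_y_top - layout$aoi_margin - 60)  # off-band
      }
    }
    oo <- c(onset, o2); xx <- c(x, x2); yy <- c(y, y2)
    ord <- order(oo)
    oo <- oo[ord]; xx <- xx[ord]; yy <- yy[ord]
    dur <- if (length(oo)) pmax(c(diff(oo) - 1e-4, 0.25), 1e-4) else numeric(0)
    fx <- fixations(oo, dur, xx, yy)

    b <- layout$aoi_boundaries
    in_own <- rep(NA, n)
    if (!is.null(b)) {
      own <- findInterval(beat_to_x(layout, beat + eps), b)
      in_own[] <- own == seq_len(n)
    }
    attr(fx, "truth") <- data.frame(
      note_id = notes$note_id, lookahead = L, landing_eps = eps,
      skipped = skipped,
      clipped = replace(rep(NA, n), keep, clipped),
      in_own_aoi = in_own, stringsAsFactors = FALSE)
    attr(fx, "n_clipped") <- sum(clipped)
    fx
  })
}

#' Simulate a full multi-participant experiment
#'
#' Builds the complete synthetic study: `n_participants` readers (the second
#' half labelled `"performance"` experts, receiving the expertise offset),
#' each playing `trials_per_tempo` trials at every tempo, with the three
#' melodic conditions cycling within each tempo block and contour inversions
#' alternating.  Each trial owns an independent RNG substream derived from
#' the master seed and the (participant, trial) indices, so any single trial
#' is reproducible in isolation.  Performances are mechanical.
#'
#' @param cfg A [sim_config()].
#' @param dialect Stimulus dialect passed to [generate_melody()].
#' @return An object of class `sim_experiment`: a list with `cfg` and
#'   `trials`, each trial holding `participant_id`, `trial_id`, `condition`,
#'   `expertise`, `tempo` (a [tempo_spec()]), `notes`, `layout`, `fixations`
#'   (with its `truth` attribute) and `perf_onsets_s`.
#' @export
simulate_experiment <- function(cfg, dialect = "exp1") {
  stopifnot(inherits(cfg, "sim_config"))
  conditions <- c("stepwise", "barline", "midbar")
  n_trials <- cfg$trials_per_tempo * length(cfg$tempi_bpm)
  trials <- vector("list", cfg$n_participants * n_trials)
  # the exp1 stimulus set is fixed: build the condition x inversion variants
  # (and their layouts/tempi) once, not per trial
  stim <- list()
  if (dialect == "exp1") {
    for (cond in conditions) for (inv in c(FALSE, TRUE)) {
      notes <- generate_melody("exp1", condition = cond, inversion = inv)
      stim[[paste(cond, inv)]] <- list(notes = notes,
                                       layout = layout_from_notes(notes))
    }
  }
  tempos <- lapply(cfg$tempi_bpm, function(bpm)
    tempo_spec(bpm, phase_ref_s = 0.3, performance_start_s = 12.3))
  names(tempos) <- as.character(cfg$tempi_bpm)
  k <- 0L
  for (p in seq_len(cfg$n_participants)) {
    expertise <- if (p > cfg$n_participants / 2) "performance" else "education"
    exp_off <- if (expertise == "performance") cfg$expertise_offset_beats else 0
    for (t in seq_len(n_trials)) {
      bpm <- cfg$tempi_bpm[ceiling(t / cfg$trials_per_tempo)]
      cond <- conditions[(t - 1L) %% 3L + 1L]
      inv <- ((t - 1L) %/% 3L) %% 2L == 1L
      if (dialect == "exp1") {
        st <- stim[[paste(cond, inv)]]
        notes <- st$notes
        layout <- st$layout
      } else {
        notes <- generate_melody(dialect, condition = cond, inversion = inv,
                                 seed = .trial_seed(cfg$seed, p, t))
        layout <- layout_from_notes(notes)
      }
      tempo <- tempos[[as.character(bpm)]]
      mean_mult <- if (bpm > min(cfg$tempi_bpm)) cfg$tempo_lookahead_mult else 1
      # expertise enters additively on the baseline mean
      mean_mult <- mean_mult *
        (cfg$lookahead_mean_beats + exp_off) / cfg$lookahead_mean_beats
      fx <- simulate_scanpath(notes, layout, tempo, cfg,
                              seed = .trial_seed(cfg$seed, p, t) + 7L,
                              mean_mult = mean_mult)
      k <- k + 1L
      trials[[k]] <- list(participant_id = sprintf("P%02d", p),
                          trial_id = t, condition = cond,
                          expertise = expertise, tempo = tempo,
                          notes = notes, layout = layout, fixations = fx,
                          perf_onsets_s = mechanical_performance(notes, tempo))
    }
  }
  structure(list(cfg = cfg, trials = trials), class = "sim_experiment")
}

#' Run the measurement chain over a simulated experiment
#'
#' Applies [compute_spans()] to every trial and stacks the records with the
#' design columns attached.
#'
#' @param sim A `sim_experiment` from [simulate_experiment()].
#' @param analysis_tag Note tag restricting the records (default
#'   `"analysis"`, the skip-region notes); `NULL` keeps every note.
#' @param with_performance Attach the baseline spans from the trial's
#'   performance log.
#' @return A span-record `data.frame` across all trials.
#' @export
measure_experiment <- function(sim, analysis_tag = "analysis",
                               with_performance = FALSE) {
  stopifnot(inherits(sim, "sim_experiment"))
  out <- lapply(sim$trials, function(tr) {
    rec <- compute_spans(tr$fixations, tr$layout, tr$notes, tr$tempo,
                         perf_onsets_s = if (with_performance) tr$perf_onsets_s,
                         analysis_tag = analysis_tag)
    if (nrow(rec) == 0L) return(NULL)
    rec$condition <- tr$condition
    rec$participant_id <- tr$participant_id
    rec$trial_id <- tr$trial_id
    rec$expertise <- tr$expertise
    rec
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  cols <- c("participant_id", "trial_id", "note_id", "condition", "expertise",
            "note_factor", "note_pos", "tempo_bpm", "ets_beats",
            "saccade_beats", "fix_onset_beats", "fix_beat_pos", "excluded",
            "ehs_lag_s", "fps_beats")
  out[, cols]
}
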