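# shared in-code fixtures: a uniformly engraved score and simple scanpaths

uniform_notes <- function(n = 8, px_per_beat = 15, x0 = 100) {
  beat <- seq_len(n) - 1
  note_events(note_id = paste0("n", seq_len(n)),
              beat_onset = beat,
              bar_index = (beat %/% 4) + 1L,
              pos_in_bar = as.integer(beat %% 4) + 1L,
              x_anchor = x0 + px_per_beat * beat)
}

uniform_layout <- function(notes, margin = 35) {
  score_layout(notes$beat_onset, notes$x_anchor,
               staff_y_top = 500, staff_y_bottom = 534, aoi_margin = margin,
               aoi_boundaries = aoi_boundaries_from_anchors(notes$x_anchor))
}

# one left-to-right fixation per note, each landing exactly on its anchor,
# onset placed `lookahead` beats before the note's beat
sweep_fixations <- function(notes, tempo, lookahead = 2) {
  onset <- tempo$start_snapped_s +
    (notes$beat_onset - lookahead) * tempo$beat_period_s
  fixations(onset, c(diff(onset), tempo$beat_period_s), notes$x_anchor,
            rep(517, nrow(notes)))
}

# record-level gamma span records (no pixel stage) for statistics tests
gamma_records <- function(seed, n_part = 20, trials = 6,
                          conditions = c("a", "b", "c"), notes = 4,
                          mu_fun = function(cond, note, part) 2.1,
                          shape = 6) {
  set.seed(seed)
  d <- expand.grid(participant_id = sprintf("P%02d", seq_len(n_part)),
                   trial_id = seq_len(trials), note_factor = seq_len(notes),
                   stringsAsFactors = FALSE)
  d$condition <- conditions[(d$trial_id - 1L) %% length(conditions) + 1L]
  d$expertise <- ifelse(as.integer(substring(d$participant_id, 2)) > n_part / 2,
                        "performance", "education")
  mu <- mapply(mu_fun, d$condition, d$note_factor, d$participant_id)
  d$ets_beats <- rgamma(nrow(d), shape = shape, rate = shape / mu)
  d
}
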