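test_that("first_fixations keeps the earliest hit per note and skips unfixated notes", {
  notes <- uniform_notes(5)
  lay <- uniform_layout(notes)
  tp <- tempo_spec(60, performance_start_s = 12)
  fx <- sweep_fixations(notes, tp)
  ff <- first_fixations(fx, lay, notes)
  expect_identical(ff$note_id, notes$note_id)
  expect_identical(ff$fix_idx, 1:5)
  expect_identical(ff$prev_idx, c(NA, 1:4))

  # refixation: second visit to n2 is ignored; n4 never fixated
  fx2 <- fixations(onset_s = c(10, 10.5, 11, 11.5, 12),
                   duration_s = rep(0.3, 5),
                   x_px = c(100, 115, 130, 115, 160),
                   y_px = rep(517, 5))
  ff2 <- first_fixations(fx2, lay, notes)
  expect_identical(ff2$fix_idx[ff2$note_id == "n2"], 2L)
  expect_false("n4" %in% ff2$note_id)
})

test_that("compute_ets measures landing beat minus metrical cursor", {
  notes <- uniform_notes(8)
  lay <- uniform_layout(notes)
  tp <- tempo_spec(60, phase_ref_s = 0, performance_start_s = 12)
  # fixation landing at beat 3.5 while the cursor stands at 2.0
  fx <- fixations(14, 0.3, beat_to_x(lay, 3.5), 517)
  expect_equal(compute_ets(fx, lay, tp), 1.5, tolerance = 1e-12)
  # landing at beat 4.5, same cursor
  fx2 <- fixations(14, 0.3, beat_to_x(lay, 4.5), 517)
  expect_equal(compute_ets(fx2, lay, tp), 2.5, tolerance = 1e-12)
  # fixation exactly at the metrical cursor
  fx3 <- fixations(14, 0.3, beat_to_x(lay, 2), 517)
  expect_equal(compute_ets(fx3, lay, tp), 0, tolerance = 1e-12)
})

test_that("incoming saccades convert pixel distances via the local beat scale", {
  notes <- uniform_notes(6)
  lay <- uniform_layout(notes)
  expect_equal(incoming_saccade_beats(115, 100, lay), 1, tolerance = 1e-12)
  expect_lt(incoming_saccade_beats(100, 115, lay), 0)   # regressive
  expect_true(is.na(incoming_saccade_beats(115, NA, lay)))
  # non-uniform engraving: 15 px over a 15-px-per-beat segment is 1 beat
  # even though the neighbouring segment is 3 times wider
  wide <- score_layout(c(0, 1, 2), c(100, 115, 160))
  expect_equal(incoming_saccade_beats(115, 100, wide), 1, tolerance = 1e-12)
  expect_equal(incoming_saccade_beats(160, 115, wide), 1, tolerance = 1e-12)
})

test_that("exclusion rules match brute force on an exhaustive toy grid", {
  ets_vals <- c(-0.1, 0, 0.4, 1, 2, 3.5)
  sacc_vals <- c(NA, -0.3, 0, 0.5, 1, 3.1, 6)
  toy <- expand.grid(ets_beats = ets_vals, saccade_beats = sacc_vals)
  got <- apply_exclusions(toy)$excluded
  brute <- mapply(function(e, s) {
    if (e < 0) "neg_ets"
    else if (!is.na(s) && s < 0) "regressive"
    else if (!is.na(s) && s > e + 2) "sacc_gt_ets_plus2"
    else "none"
  }, toy$ets_beats, toy$saccade_beats)
  expect_identical(as.character(got), unname(brute))
  # idempotence
  expect_identical(apply_exclusions(apply_exclusions(toy))$excluded, got)
  # survivors satisfy the record invariants
  ok <- toy[got == "none" & !is.na(toy$saccade_beats), ]
  expect_true(all(ok$ets_beats >= 0 & ok$saccade_beats >= 0 &
                    ok$saccade_beats <= ok$ets_beats + 2))
})

test_that("the worked toy exclusion set leaves a single survivor", {
  toy <- data.frame(ets_beats = c(2, -0.1, 2, 1),
                    saccade_beats = c(1, 0.5, -0.3, 3.5))
  out <- apply_exclusions(toy)
  expect_identical(as.character(out$excluded),
                   c("none", "neg_ets", "regressive", "sacc_gt_ets_plus2"))
})

test_that("zero-length incoming saccades are not regressive", {
  out <- apply_exclusions(data.frame(ets_beats = 1, saccade_beats = 0))
  expect_identical(as.character(out$excluded), "none")
})

test_that("single-item lag is performance onset minus fixation onset", {
  expect_equal(single_item_lag(10, 11.3), 1.3)
  expect_identical(single_item_lag(10, 10), 0)
  expect_lt(single_item_lag(12, 11.3), 0)   # fixated after being played
})

test_that("forward projective span is constant within a fixation", {
  notes <- uniform_notes(8)
  lay <- uniform_layout(notes)
  tp <- tempo_spec(60, performance_start_s = 12)
  fx <- sweep_fixations(notes, tp)
  on <- fx$onset_s[4]
  a <- forward_projective_span(fx, lay, tp, on)
  b <- forward_projective_span(fx, lay, tp, on + fx$duration_s[4] * 0.9)
  expect_true(a$in_fixation && b$in_fixation)
  # the landing x is frozen while the fixation lasts, so the probed span
  # shrinks exactly with the advancing metrical cursor
  expect_equal(b$fps_beats, a$fps_beats - (b$t_s - a$t_s) / tp$beat_period_s,
               tolerance = 1e-12)
  expect_true(is.na(forward_projective_span(fx, lay, tp,
                                            fx$onset_s[1] - 1)$fps_beats))
})

test_that("forward and backward projections differ except at fixation onset", {
  notes <- uniform_notes(8)
  lay <- uniform_layout(notes)
  tp <- tempo_spec(60, performance_start_s = 12)
  fx <- sweep_fixations(notes, tp, lookahead = 2)
  perf <- mechanical_performance(notes, tp)
  # probe at note n4's execution: the active fixation is the one on n6
  # (launched 2 beats ahead); FPS equals that fixation's ETS only because the
  # probe coincides with its onset here
  probe <- perf[["n6"]] - 2 * tp$beat_period_s  # = onset of fixation 6? no:
  probe <- perf[["n4"]]
  fps <- forward_projective_span(fx, lay, tp, probe)$fps_beats
  idx <- max(which(fx$onset_s <= probe))
  ets_active <- compute_ets(fx[idx, ], lay, tp)
  if (fx$onset_s[idx] == probe) {
    expect_equal(fps, ets_active, tolerance = 1e-12)
  }
  # probing strictly inside the fixation breaks the equality
  probe2 <- fx$onset_s[idx] + 0.2
  fps2 <- forward_projective_span(fx, lay, tp, probe2)$fps_beats
  expect_false(isTRUE(all.equal(fps2, ets_active, tolerance = 1e-9)))
})

test_that("ETS is invariant under a rigid time shift of the recording", {
  notes <- uniform_notes(8)
  lay <- uniform_layout(notes)
  for (shift in c(-3.7, 5.37)) {
    tp0 <- tempo_spec(60, phase_ref_s = 0.3, performance_start_s = 12.3)
    tp1 <- tempo_spec(60, phase_ref_s = (0.3 + shift) %% 1,
                      performance_start_s = 12.3 + shift)
    fx0 <- sweep_fixations(notes, tp0, lookahead = 1.3)
    fx1 <- fixations(fx0$onset_s + shift, fx0$duration_s, fx0$x_px, fx0$y_px)
    expect_equal(compute_ets(fx1, lay, tp1), compute_ets(fx0, lay, tp0),
                 tolerance = 1e-9)
  }
})

test_that("chain identity links consecutive first fixations", {
  # ets(F) = ets(F_prev) - delta_beats(onsets) + saccade(F_prev -> F)
  cfg <- sim_config(seed = 31, n_participants = 2, trials_per_tempo = 2)
  sim <- simulate_experiment(cfg)
  checked <- 0L
  for (tr in sim$trials) {
    ff <- first_fixations(tr$fixations, tr$layout, tr$notes)
    ets <- compute_ets(tr$fixations[ff$fix_idx, ], tr$layout, tr$tempo)
    for (i in seq_len(nrow(ff))[-1]) {
      if (!is.na(ff$prev_idx[i]) && ff$prev_idx[i] == ff$fix_idx[i - 1]) {
        dt <- metrical_time(tr$fixations$onset_s[ff$fix_idx[i]], tr$tempo) -
          metrical_time(tr$fixations$onset_s[ff$fix_idx[i - 1]], tr$tempo)
        sac <- incoming_saccade_beats(tr$fixations$x_px[ff$fix_idx[i]],
                                      tr$fixations$x_px[ff$prev_idx[i]],
                                      tr$layout)
        expect_equal(ets[i], ets[i - 1] - dt + sac, tolerance = 1e-9)
        checked <- checked + 1L
      }
    }
  }
  expect_gt(checked, 50)
})

test_that("mechanical performances equate ETS (in seconds) with the single-item lag", {
  cfg <- sim_config(seed = 13, n_participants = 2, trials_per_tempo = 2,
                    landing_sd_beats = 0, p_skip = 0.1)
  sim <- simulate_experiment(cfg)
  rec <- measure_experiment(sim, analysis_tag = NULL, with_performance = TRUE)
  expect_gt(nrow(rec), 50)
  expect_equal(rec$ets_beats * 60 / rec$tempo_bpm, rec$ehs_lag_s,
               tolerance = 1e-9)
})

test_that("compute_spans restricts to tagged notes and orders by score position", {
  cfg <- sim_config(seed = 9, n_participants = 1, trials_per_tempo = 1, p_skip = 0)
  sim <- simulate_experiment(cfg)
  tr <- sim$trials[[1]]
  rec <- compute_spans(tr$fixations, tr$layout, tr$notes, tr$tempo,
                       analysis_tag = "analysis")
  expect_identical(rec$note_id, tr$notes$note_id[has_tag(tr$notes, "analysis")])
  expect_identical(rec$note_factor, 1:6)
  rec_all <- compute_spans(tr$fixations, tr$layout, tr$notes, tr$tempo)
  expect_identical(rec_all$note_id, tr$notes$note_id)
})
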