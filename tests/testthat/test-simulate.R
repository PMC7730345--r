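test_that("five-bar stepwise melodies move entirely by step", {
  for (inv in c(FALSE, TRUE)) {
    m <- generate_melody("exp1", "stepwise", inversion = inv)
    expect_identical(nrow(m), 17L)
    expect_true(all(abs(diff(m$degree)) <= 1))
    expect_length(which(has_tag(m, "skip_target")), 0)
    expect_identical(m$degree[17], 3L)  # ends on the third degree (E4)
  }
})

test_that("bar-line melodies place a fourth and a fifth at the bar lines of bar 3", {
  m <- generate_melody("exp1", "barline")
  iv <- abs(diff(m$degree))
  skips <- which(iv >= 2)
  expect_identical(skips, c(8L, 12L))          # into bar 3 and into bar 4
  expect_setequal(iv[skips], c(3, 4))          # perfect fourth and fifth
  tgt <- which(has_tag(m, "skip_target"))
  expect_identical(tgt, c(9L, 13L))
  expect_identical(m$pos_in_bar[tgt], c(1L, 1L))   # landing on downbeats
  expect_identical(which(has_tag(m, "pre_skip")), c(8L, 12L))
})

test_that("mid-bar melodies shift the same skips two beats into the bar", {
  m <- generate_melody("exp1", "midbar")
  iv <- abs(diff(m$degree))
  skips <- which(iv >= 2)
  expect_identical(skips, c(10L, 14L))
  expect_setequal(iv[skips], c(3, 4))
  tgt <- which(has_tag(m, "skip_target"))
  expect_identical(m$pos_in_bar[tgt], c(3L, 3L))   # mid-bar landings
})

test_that("the analysis region spans the six notes around the skips", {
  for (cond in c("stepwise", "barline", "midbar")) {
    m <- generate_melody("exp1", cond)
    expect_identical(which(has_tag(m, "analysis")), 8:13)
  }
  m <- generate_melody("exp1", "barline")
  expect_identical(m$note_id[8:13],
                   c("b2n4", "b3n1", "b3n2", "b3n3", "b3n4", "b4n1"))
})

test_that("contour inversion mirrors degrees and preserves interval sizes", {
  m <- generate_melody("exp1", "barline")
  mi <- generate_melody("exp1", "barline", inversion = TRUE)
  expect_identical(mi$degree, 6L - m$degree)
  expect_identical(abs(diff(mi$degree)), abs(diff(m$degree)))
  expect_identical(mi$degree[17], 3L)
})

test_that("multi-staff melodies hide one chromatic minor sixth per staff", {
  for (seed in c(2, 17, 91)) {
    m <- generate_melody("exp2", seed = seed)
    expect_identical(max(m$staff_index), 4L)
    for (s in 1:4) {
      sub <- m[m$staff_index == s, ]
      expect_identical(nrow(sub), 24L)           # 6 bars of quarter notes
      iv <- abs(diff(sub$midi))
      big <- which(iv > 2)
      expect_length(big, 1)                      # exactly one skip
      expect_equal(iv[big], 8)                   # a minor sixth in semitones
      tgt <- big + 1L
      expect_true(has_tag(sub, "skip_target")[tgt])
      expect_true(sub$altered[tgt])
      expect_identical(sub$pos_in_bar[tgt], 4L)  # last note of its bar
      expect_true(sub$bar_index[tgt] %in%
                    ((s - 1) * 6 + 3:5))         # in bars 3-5 of the staff
      # at least one bar of stepwise approach, reversing at the skip
      expect_true(all(diff(sub$degree[(tgt - 4):(tgt - 1)]) == -1))
      # the gap is filled by reversed stepwise motion after the skip
      if (tgt < 24) expect_lt(sub$degree[tgt + 1], sub$degree[tgt])
      # matched stepwise-control bar exists and contains no skip
      ctrl <- which(has_tag(sub, "stepwise_control"))
      expect_length(ctrl, 4)
      expect_true(all(abs(diff(sub$degree[ctrl])) <= 1))
    }
    # engraving: 41 px between heads within a bar, 57 px across bar lines
    s1 <- m[m$staff_index == 1, ]
    dx <- diff(s1$x_anchor)
    expect_true(all(dx[s1$pos_in_bar[-1] == 1] == 57))
    expect_true(all(dx[s1$pos_in_bar[-1] != 1] == 41))
  }
})

test_that("exp2 generation is deterministic given the seed", {
  a <- generate_melody("exp2", seed = 5)
  b <- generate_melody("exp2", seed = 5)
  expect_identical(a, b)
})

test_that("per-staff layouts route fixations through their own beat scale", {
  m <- generate_melody("exp2", seed = 3)
  lays <- staff_layouts(m)
  expect_length(lays, 4)
  geom <- attr(m, "staff_geom")
  for (s in 1:4) {
    sub <- m[m$staff_index == s, ]
    lay <- lays[[s]]
    expect_equal(x_to_beat(lay, sub$x_anchor), sub$beat_onset, tolerance = 1e-9)
    y <- (geom$y_top[s] + geom$y_bottom[s]) / 2
    expect_identical(assign_aoi(lay, sub, sub$x_anchor[7], y), sub$note_id[7])
  }
})

test_that("mechanical performances sit exactly on the beat grid", {
  notes <- uniform_notes(8)
  tp60 <- tempo_spec(60, performance_start_s = 12)
  on <- mechanical_performance(notes, tp60)
  expect_equal(unname(on["n4"]), 12 + 3)
  tp100 <- tempo_spec(100, performance_start_s = 10)
  on100 <- mechanical_performance(notes, tp100)
  expect_equal(unname(on100["n5"] - on100["n1"]), 2.4)  # one 4/4 bar
  expect_identical(jittered_performance(notes, tp60, sd_s = 0), on)
  j <- jittered_performance(notes, tp60, sd_s = 0.02, seed = 4)
  expect_false(identical(j, on))
  expect_lt(max(abs(j - on)), 0.2)
})

test_that("noise-free scanpaths recover the mean look-ahead exactly in the limit", {
  notes <- uniform_notes(12)
  lay <- uniform_layout(notes)
  tp <- tempo_spec(60, performance_start_s = 12)
  cfg <- sim_config(seed = 1, lookahead_mean_beats = 2.1,
                    lookahead_shape = 1e10, landing_sd_beats = 0, p_skip = 0)
  fx <- simulate_scanpath(notes, lay, tp, cfg, seed = 2)
  rec <- compute_spans(fx, lay, notes, tp)
  expect_equal(rec$ets_beats, rep(2.1, nrow(rec)), tolerance = 1e-3)
})

test_that("attraction multiplies the mean look-ahead at tagged notes", {
  # law of large numbers over ~1e4 notes: tagged/untagged mean ratio -> a
  n <- 10000
  beat <- seq_len(n) - 1
  tags <- rep(list(character(0)), n)
  tagged <- seq(10, n, by = 10)
  for (i in tagged) tags[[i]] <- "skip_target"
  notes <- note_events(paste0("n", seq_len(n)), beat, beat %/% 4 + 1,
                       beat %% 4 + 1, 100 + 15 * beat, tags = tags)
  lay <- uniform_layout(notes)
  tp <- tempo_spec(60, performance_start_s = 30)
  cfg <- sim_config(seed = 1, attraction_multiplier = 1.2,
                    landing_sd_beats = 0, p_skip = 0)
  fx <- simulate_scanpath(notes, lay, tp, cfg, seed = 8)
  tru <- attr(fx, "truth")
  is_tag <- has_tag(notes, "skip_target")
  # law of large numbers on the unconditional generative draws
  ratio <- mean(tru$lookahead[is_tag]) / mean(tru$lookahead[!is_tag])
  expect_equal(ratio, 1.2, tolerance = 0.05)
  # the measured ETS on non-clipped notes matches the same draws, so its
  # tagged/untagged ratio equals the conditional truth ratio of that subset
  # (onset clipping truncates the largest look-aheads, so the subset ratio
  # itself sits below the unconditional 1.2)
  ok <- !tru$skipped & !is.na(tru$clipped) & !tru$clipped & tru$in_own_aoi
  rec <- compute_spans(fx, lay, notes, tp)
  rec <- rec[rec$excluded == "none" & ok[match(rec$note_id, notes$note_id)], ]
  tag_rec <- is_tag[match(rec$note_id, notes$note_id)]
  i <- match(rec$note_id, tru$note_id)
  truth_sub <- tru$lookahead[i] + tru$landing_eps[i]
  expect_equal(mean(rec$ets_beats[tag_rec]) / mean(rec$ets_beats[!tag_rec]),
               mean(truth_sub[tag_rec]) / mean(truth_sub[!tag_rec]),
               tolerance = 0.01)
  expect_gt(mean(rec$ets_beats[tag_rec]) / mean(rec$ets_beats[!tag_rec]), 1.05)
})

test_that("under the null the seed stream ignores the tagging entirely", {
  m1 <- generate_melody("exp1", "barline")
  m0 <- m1
  m0$tags <- rep(list(character(0)), nrow(m0))
  lay <- layout_from_notes(m1)
  tp <- tempo_spec(60, phase_ref_s = 0.3, performance_start_s = 12.3)
  cfg <- sim_config(seed = 1, attraction_multiplier = 1)
  f1 <- simulate_scanpath(m1, lay, tp, cfg, seed = 77)
  f0 <- simulate_scanpath(m0, lay, tp, cfg, seed = 77)
  expect_identical(f1$onset_s, f0$onset_s)
  expect_identical(f1$x_px, f0$x_px)
})

test_that("small-shape look-ahead populations are right-skewed", {
  cfg <- sim_config(seed = 6, lookahead_shape = 1.5, p_skip = 0)
  notes <- uniform_notes(2000, px_per_beat = 15)
  lay <- uniform_layout(notes)
  tp <- tempo_spec(60, performance_start_s = 30)
  fx <- simulate_scanpath(notes, lay, tp, cfg, seed = 3)
  rec <- compute_spans(fx, lay, notes, tp)
  e <- rec$ets_beats[rec$excluded == "none"]
  skew <- mean((e - mean(e))^3) / sd(e)^3
  expect_gt(skew, 0.5)
})

test_that("simulated trials are reproducible in isolation via their substream", {
  cfg <- sim_config(seed = 123, n_participants = 2, trials_per_tempo = 1)
  s1 <- simulate_experiment(cfg)
  s2 <- simulate_experiment(cfg)
  expect_identical(s1$trials[[3]]$fixations, s2$trials[[3]]$fixations)
  # a different master seed changes the scanpaths
  s3 <- simulate_experiment(sim_config(seed = 124, n_participants = 2,
                                       trials_per_tempo = 1))
  expect_false(identical(s1$trials[[3]]$fixations$onset_s,
                         s3$trials[[3]]$fixations$onset_s))
})

test_that("regression injection produces regressive incoming saccades", {
  cfg <- sim_config(seed = 21, n_participants = 3, trials_per_tempo = 2,
                    regression_rate = 0.3)
  rec <- measure_experiment(simulate_experiment(cfg), analysis_tag = NULL)
  expect_gt(sum(rec$excluded == "regressive"), 5)
})

test_that("sim_config rejects invalid generative parameters", {
  expect_error(sim_config(lookahead_mean_beats = -1))
  expect_error(sim_config(lookahead_shape = 0))
  expect_error(sim_config(p_skip = 1))
  expect_error(sim_config(attraction_multiplier = 0))
})
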