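#' Fixation event table
#'
#' Validates and normalizes a fixation stream: one row per fixation with
#' onset (s), duration (s) and screen coordinates (px), time-ordered.
#' Fixation detection itself (velocity/distance thresholding in the
#' eye-tracker software) is upstream of this package; its output is consumed
#' as given.
#'
#' @param onset_s Strictly increasing numeric onsets (s).
#' @param duration_s Positive durations (s).
#' @param x_px,y_px Screen coordinates (px; x rightward, y downward).
#' @return A `data.frame` with class `fixations` prepended.
#' @export
fixations <- function(onset_s, duration_s, x_px, y_px) {
  if (any(diff(onset_s) <= 0))
    stop("fixation onsets must be strictly increasing within a recording")
  if (any(duration_s <= 0)) stop("fixation durations must be positive")
  out <- data.frame(onset_s = as.numeric(onset_s),
                    duration_s = as.numeric(duration_s),
                    x_px = as.numeric(x_px), y_px = as.numeric(y_px))
  class(out) <- c("fixations", class(out))
  out
}

#' First fixation landing on each note's AOI
#'
#' For every note, finds the earliest fixation assigned to its AOI, together
#' with the index of the immediately preceding fixation in the raw stream
#' (the saccade launch site).  Notes never fixated are absent from the
#' result -- note skipping is a normal outcome, not an error.
#'
#' @param fx A [fixations()] table (time-ordered).
#' @param layout A [score_layout()] with AOI boundaries.
#' @param notes A [note_events()] table.
#' @return A `data.frame` with columns `note_id`, `fix_idx` (row in `fx`),
#'   `prev_idx` (`NA` for the first fixation of the recording).
#' @export
first_fixations <- function(fx, layout, notes) {
  aoi <- assign_aoi(layout, notes, fx$x_px, fx$y_px)
  hit <- which(!is.na(aoi))
  if (length(hit) == 0L)
    return(data.frame(note_id = character(0), fix_idx = integer(0),
                      prev_idx = integer(0)))
  first <- hit[!duplicated(aoi[hit])]  # fx is time-ordered, so earliest wins
  data.frame(note_id = aoi[first],
             fix_idx = first,
             prev_idx = ifelse(first > 1L, first - 1L, NA_integer_))
}

#' Eye-Time Span of a fixation
#'
#' The ETS is the distance, in beats, between the fixation's horizontal
#' position on the score (read as a metrical time scale) and the score
#' position where metrical time stood at fixation onset:
#' `x_to_beat(x) - metrical_time(onset)`.  The actual landing x is used, not
#' the AOI or note center.  Negative values (fixation behind the metrical
#' cursor) are legal output here and filtered by [apply_exclusions()].
#'
#' @param fx A [fixations()] table (or any data.frame with `onset_s`,
#'   `x_px`).
#' @param layout A [score_layout()].
#' @param tempo A [tempo_spec()].
#' @return ETS in beats, one value per fixation.
#' @export
compute_ets <- function(fx, layout, tempo) {
  x_to_beat(layout, fx$x_px) - metrical_time(fx$onset_s, tempo)
}

#' Incoming saccade length in beats
#'
#' Signed horizontal displacement from the previous fixation to the current
#' one, converted from pixels to metrical units via the score's beat scale:
#' `x_to_beat(x) - x_to_beat(x_prev)`.  The conversion is segment-local, so a
#' 15-px saccade over a 15-px-per-beat region is 1 beat even when
#' neighbouring regions are engraved wider.  Negative values are regressive
#' saccades.
#'
#' @param x_px,x_prev_px Landing and launch x positions (px); `x_prev_px` may
#'   contain `NA` (no preceding fixation), yielding `NA`.
#' @param layout A [score_layout()].
#' @return Signed saccade lengths in beats.
#' @export
incoming_saccade_beats <- function(x_px, x_prev_px, layout) {
  x_to_beat(layout, x_px) - x_to_beat(layout, x_prev_px)
}

#' Single-Item Lag eye-hand span
#'
#' Time from first fixating a note to performing that same note:
#' `perf_onset - fix_onset` (s).  Negative when the note was fixated only
#' after being played.  With a mechanical performance locked to the
#' metronome, this lag equals the ETS converted to seconds.
#'
#' @param first_fix_onset_s First-fixation onsets (s).
#' @param note_perf_onset_s Performance onsets of the same notes (s); `NA`
#'   where the note was never played (or never fixated).
#' @return Lags in seconds.
#' @export
single_item_lag <- function(first_fix_onset_s, note_perf_onset_s) {
  as.numeric(note_perf_onset_s) - as.numeric(first_fix_onset_s)
}

#' Forward Projective eye-hand span at a probe time
#'
#' How far ahead (in beats) of the metrical cursor the eyes are at time
#' `t_s` -- typically probed at a note's execution.  Uses the fixation active
#' at `t_s` (onset <= t < onset + duration); when the probe falls in a
#' saccade gap, the nearest preceding fixation is used and flagged.
#'
#' @param fx A [fixations()] table.
#' @param layout A [score_layout()].
#' @param tempo A [tempo_spec()].
#' @param t_s Numeric vector of probe times (s).
#' @return A `data.frame` with columns `t_s`, `fps_beats`, `in_fixation`
#'   (FALSE when a preceding fixation was substituted); `fps_beats` is `NA`
#'   for probes before the first fixation.
#' @export
forward_projective_span <- function(fx, layout, tempo, t_s) {
  t_s <- as.numeric(t_s)
  idx <- findInterval(t_s, fx$onset_s)      # nearest fixation at or before t
  active <- idx >= 1L
  fb <- rep(NA_real_, length(t_s))
  in_fix <- rep(NA, length(t_s))
  if (any(active)) {
    i <- idx[active]
    fb[active] <- x_to_beat(layout, fx$x_px[i]) - metrical_time(t_s[active], tempo)
    in_fix[active] <- t_s[active] < fx$onset_s[i] + fx$duration_s[i]
  }
  data.frame(t_s = t_s, fps_beats = fb, in_fixation = in_fix)
}

#' Apply the first-fixation exclusion rules
#'
#' Flags first-fixation records that are irrelevant or artifactual for span
#' analysis: (i) negative ETS; (ii) regressive (leftward) incoming saccades;
#' (iii) incoming saccades longer than the ETS plus two beats (long
#' re-entries after glancing back, e.g. to the key signature).  Rules are
#' checked in the order (i), (ii), (iii) and the first match wins.  A
#' zero-length incoming saccade is not regressive; an undefined saccade
#' (no preceding fixation) can only be excluded by rule (i).
#'
#' @param records A span-record `data.frame` with numeric columns `ets_beats`
#'   and `saccade_beats` (the latter may contain `NA`).
#' @return The same data.frame with an `excluded` factor column set to one of
#'   `"none"`, `"neg_ets"`, `"regressive"`, `"sacc_gt_ets_plus2"`.
#' @export
apply_exclusions <- function(records) {
  ets <- records$ets_beats
  sac <- records$saccade_beats
  flag <- rep("none", length(ets))
  flag[!is.na(sac) & sac > ets + 2] <- "sacc_gt_ets_plus2"
  flag[!is.na(sac) & sac < 0] <- "regressive"
  flag[ets < 0] <- "neg_ets"
  records$excluded <- factor(flag, levels = c("none", "neg_ets", "regressive",
                                              "sacc_gt_ets_plus2"))
  records
}

#' Exclusion summary in reporting style
#'
#' Counts and percentages (of all records, 2 decimals) per exclusion rule.
#'
#' @param records Output of [apply_exclusions()].
#' @return A `data.frame` with columns `rule`, `n`, `pct`.
#' @export
exclusion_summary <- function(records) {
  lev <- levels(records$excluded)
  n <- as.integer(table(records$excluded)[lev])
  data.frame(rule = lev, n = n,
             pct = round(100 * n / max(1L, nrow(records)), 2))
}

#' Compute span records for one trial
#'
#' Runs the full measurement chain on one recording: AOI assignment, first
#' fixations, ETS, incoming saccade conversion, exclusion flags, and (when a
#' performance log is supplied) the Single-Item Lag and Forward Projective
#' baseline spans.  The performance log is optional throughout -- the ETS
#' never needs one.
#'
#' @param fx A [fixations()] table for the trial.
#' @param layout A [score_layout()].
#' @param notes A [note_events()] table.
#' @param tempo A [tempo_spec()].
#' @param perf_onsets_s Optional named numeric vector (names = `note_id`) of
#'   performance note onsets (s).
#' @param analysis_tag Optional tag restricting output to tagged notes
#'   (e.g. `"analysis"`); `NULL` keeps all notes.
#' @return A `data.frame` (one row per first-fixated note, in note order)
#'   with columns `note_id`, `note_factor` (1..k within the analyzed set),
#'   `note_pos` (the note's 1-based beat position within its bar -- the
#'   "Note" factor of the condition analysis),
#'   `condition` (`NA`, filled by dataset-level wrappers), `ets_beats`,
#'   `saccade_beats`, `fix_onset_beats`, `fix_beat_pos`, `excluded`,
#'   `ehs_lag_s`, `fps_beats`.
#' @export
compute_spans <- function(fx, layout, notes, tempo,
                          perf_onsets_s = NULL, analysis_tag = NULL) {
  keep <- if (is.null(analysis_tag)) rep(TRUE, nrow(notes)) else has_tag(notes, analysis_tag)
  ff <- first_fixations(fx, layout, notes)
  note_sel <- notes$note_id[keep]
  ff <- ff[ff$note_id %in% note_sel, , drop = FALSE]
  # order records by note position in the score
  ord <- order(match(ff$note_id, notes$note_id))
  ff <- ff[ord, , drop = FALSE]

  f1 <- fx[ff$fix_idx, , drop = FALSE]
  prev_x <- ifelse(is.na(ff$prev_idx), NA_real_, fx$x_px[ff$prev_idx])
  rec <- data.frame(
    note_id = ff$note_id,
    note_factor = match(ff$note_id, note_sel),
    note_pos = notes$pos_in_bar[match(ff$note_id, notes$note_id)],
    condition = NA_character_,
    tempo_bpm = tempo$bpm,
    ets_beats = compute_ets(f1, layout, tempo),
    saccade_beats = incoming_saccade_beats(f1$x_px, prev_x, layout),
    fix_onset_beats = metrical_time(f1$onset_s, tempo),
    fix_beat_pos = x_to_beat(layout, f1$x_px),
    stringsAsFactors = FALSE)
  rec <- apply_exclusions(rec)

  rec$ehs_lag_s <- NA_real_
  rec$fps_beats <- NA_real_
  if (!is.null(perf_onsets_s)) {
    po <- perf_onsets_s[rec$note_id]
    rec$ehs_lag_s <- single_item_lag(f1$onset_s, po)
    ok <- !is.na(po)
    if (any(ok))
      rec$fps_beats[ok] <-
        forward_projective_span(fx, layout, tempo, po[ok])$fps_beats
  }
  rec
}
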