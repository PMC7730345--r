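#' Tempo specification anchoring metrical time to recording time
#'
#' Metrical time is musical time counted in beats: at `bpm` beats per minute
#' one beat lasts `60/bpm` seconds.  The metronome click recurs cyclically in
#' the recording clock; `phase_ref_s` is its estimated offset within one beat
#' period (see [estimate_click_phase()]).  `performance_start_s` marks beat 0
#' and, because performances start on a click, is snapped to the nearest
#' click of the grid implied by the phase before any beat arithmetic.
#'
#' @param bpm Beats per minute (> 0).
#' @param phase_ref_s Click offset within one beat period, in
#'   `[0, 60/bpm)` seconds.
#' @param performance_start_s Recording time (s) of performance beat 0;
#'   snapped to the click grid.
#' @param segment_start_s Recording time at which this tempo takes effect
#'   (bookkeeping for multi-tempo sessions).
#' @return An object of class `tempo_spec` with the derived `beat_period_s`
#'   and the snapped start in `start_snapped_s`.
#' @export
tempo_spec <- function(bpm, phase_ref_s = 0, performance_start_s = 0,
                       segment_start_s = 0) {
  if (!is.numeric(bpm) || length(bpm) != 1L || bpm <= 0)
    stop("bpm must be a single positive number")
  beat_period_s <- 60 / bpm
  if (phase_ref_s < 0 || phase_ref_s >= beat_period_s)
    stop("phase_ref_s must lie in [0, beat_period_s)")
  start_snapped_s <- phase_ref_s +
    beat_period_s * round((performance_start_s - phase_ref_s) / beat_period_s)
  structure(
    list(bpm = bpm, beat_period_s = beat_period_s, phase_ref_s = phase_ref_s,
         performance_start_s = performance_start_s,
         start_snapped_s = start_snapped_s,
         segment_start_s = segment_start_s),
    class = "tempo_spec")
}

#' @export
print.tempo_spec <- function(x, ...) {
  cat("<tempo_spec> ", x$bpm, " bpm (beat period ", format(x$beat_period_s),
      " s), click phase ", format(x$phase_ref_s), " s, beat 0 at ",
      format(x$start_snapped_s), " s\n", sep = "")
  invisible(x)
}

#' Estimate the metronome click phase from synchronization timestamps
#'
#' The experimenter's screen-switch key presses (or any other events produced
#' on metronome clicks) leave timestamps in the eye-tracking recording.  The
#' click phase is recovered as a median of the timestamp residues modulo the
#' beat period.  Because residues live on a circle, the plain median is wrong
#' when they straddle the wrap point (e.g. residues 0.999 and 0.001 s for a
#' 1-s period); the circular median -- the observed residue minimizing the
#' summed circular distance to all residues -- is used instead.  Away from the
#' wrap boundary it coincides with the ordinary median.
#'
#' @param timestamps_s Numeric vector of event times (s), length >= 3.
#' @param beat_period_s Beat period (s), > 0.
#' @return The estimated phase in `[0, beat_period_s)`.  A warning is issued
#'   when the circular dispersion of the residues exceeds a quarter period
#'   (poor synchronization).
#' @export
estimate_click_phase <- function(timestamps_s, beat_period_s) {
  if (length(timestamps_s) == 0L) stop("no synchronization timestamps supplied")
  if (length(timestamps_s) < 3L)
    stop("need at least 3 synchronization timestamps")
  if (beat_period_s <= 0) stop("beat_period_s must be > 0")
  r <- timestamps_s %% beat_period_s
  # circular distance matrix between observed residues
  d <- abs(outer(r, r, "-"))
  d <- pmin(d, beat_period_s - d)
  tot <- rowSums(d)
  phase <- r[which.min(tot)]
  # circular SD from the mean resultant length; large when the residues
  # spread around the whole beat cycle
  ang <- 2 * pi * r / beat_period_s
  rbar <- sqrt(mean(cos(ang))^2 + mean(sin(ang))^2)
  disp <- sqrt(-2 * log(max(rbar, 1e-12))) * beat_period_s / (2 * pi)
  if (disp > beat_period_s / 4)
    warning(sprintf(
      "click-phase residues are widely dispersed (circular SD %.3g s > period/4); synchronization may be poor",
      disp))
  phase
}

#' Metrical time of appearance of a recording-time event
#'
#' Indexes an event (typically a fixation onset) with its position in
#' metrical beats relative to performance beat 0: `(t - start) / period`,
#' where the start has been snapped to the metronome click grid.  Negative
#' values (events before the performance began) are returned as-is and
#' filtered downstream.
#'
#' @param t_s Numeric vector of recording times (s).
#' @param tempo A [tempo_spec()].
#' @return Metrical times in beats.
#' @export
metrical_time <- function(t_s, tempo) {
  stopifnot(inherits(tempo, "tempo_spec"))
  (as.numeric(t_s) - tempo$start_snapped_s) / tempo$beat_period_s
}
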