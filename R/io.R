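# cheap deterministic polynomial hash of a string, as 8 hex digits
# (config fingerprinting only, no cryptographic intent)
.fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(paste(s, collapse = "\n")))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# write text/JSON atomically: temp file in the same directory, then rename
.atomic_write <- function(writer, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not write ", path)
  invisible(path)
}

#' Read a fixation report
#'
#' Delimited text export with one row per fixation and columns
#' `participant`, `trial`, `onset_ms`, `duration_ms`, `x`, `y` (extra
#' columns pass through).  Times are eye-tracker milliseconds and are
#' converted to seconds.  Within each (participant, trial) the onsets must
#' be strictly increasing; violations are reported with their file row
#' numbers.
#'
#' @param path Path to a TSV (or other delimited) file.
#' @param sep Field separator (default tab).
#' @return A `data.frame` sorted by participant, trial, onset, with added
#'   `onset_s` and `duration_s` columns.
#' @export
read_fixations <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("fixation file not found: ", path)
  d <- utils::read.table(path, header = TRUE, sep = sep,
                         stringsAsFactors = FALSE, check.names = TRUE)
  need <- c("participant", "trial", "onset_ms", "duration_ms", "x", "y")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("fixation file lacks required columns: ",
         paste(missing, collapse = ", "))
  d$onset_ms <- suppressWarnings(as.numeric(d$onset_ms))
  d$duration_ms <- suppressWarnings(as.numeric(d$duration_ms))
  malformed <- which(is.na(d$onset_ms) | is.na(d$duration_ms) |
                       d$duration_ms <= 0)
  if (length(malformed))
    stop("malformed fixation rows (file rows, excluding header): ",
         paste(malformed + 1L, collapse = ", "))
  d$.row <- seq_len(nrow(d)) + 1L          # file row incl. header
  for (key in split(seq_len(nrow(d)), list(d$participant, d$trial), drop = TRUE)) {
    o <- d$onset_ms[key]
    if (is.unsorted(o, strictly = TRUE)) {
      viol <- key[which(diff(o) <= 0) + 1L]
      stop("fixation onsets not strictly increasing within participant '",
           d$participant[key[1]], "', trial ", d$trial[key[1]],
           " at file row(s) ", paste(d$.row[viol], collapse = ", "))
    }
  }
  d$onset_s <- d$onset_ms / 1000
  d$duration_s <- d$duration_ms / 1000
  d <- d[order(d$participant, d$trial, d$onset_s), ]
  d$.row <- NULL
  rownames(d) <- NULL
  d
}

#' Read a trial configuration (layout, notes, tempo)
#'
#' JSON or YAML (by file extension) describing the stimulus geometry and
#' synchronization: `layout` (anchors as `beat`/`x` arrays, `staff_y_top`,
#' `staff_y_bottom`, optional `aoi_margin`, `aoi_boundaries`, `dialect`),
#' `notes` (parallel arrays `note_id`, `beat_onset`, `bar_index`,
#' `pos_in_bar`, `x_anchor`, optional `tags` as comma-separated strings),
#' and `tempo` segments (`bpm`, `performance_start_s`, plus either
#' `phase_ref_s` or `sync_timestamps_s` from which the click phase is
#' estimated).  All structural invariants are validated on load.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A list with `layout` ([score_layout()]), `notes`
#'   ([note_events()]), `tempos` (list of [tempo_spec()]) and
#'   `analysis_tag` (may be `NULL`).
#' @export
read_trial_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (fld in c("layout", "notes", "tempo"))
    if (is.null(raw[[fld]])) stop("config lacks required field '", fld, "'")
  lay <- raw$layout
  nt <- raw$notes
  for (fld in c("note_id", "beat_onset", "bar_index", "pos_in_bar", "x_anchor"))
    if (is.null(nt[[fld]])) stop("config notes lack field '", fld, "'")
  tags <- if (is.null(nt$tags)) list(character(0)) else
    lapply(strsplit(as.character(nt$tags), ",", fixed = TRUE), trimws)
  notes <- note_events(nt$note_id, nt$beat_onset, nt$bar_index,
                       nt$pos_in_bar, nt$x_anchor, tags = tags)
  boundaries <- lay$aoi_boundaries
  if (is.null(boundaries)) boundaries <- aoi_boundaries_from_anchors(notes$x_anchor)
  layout <- score_layout(
    lay$anchors$beat, lay$anchors$x,
    staff_y_top = lay$staff_y_top, staff_y_bottom = lay$staff_y_bottom,
    aoi_margin = if (is.null(lay$aoi_margin)) 35 else lay$aoi_margin,
    aoi_boundaries = boundaries,
    dialect = if (is.null(lay$dialect)) "stem_midpoint" else lay$dialect)
  tempo_raw <- raw$tempo
  if (!is.null(tempo_raw$bpm) && !is.data.frame(tempo_raw))
    tempo_raw <- list(tempo_raw)
  if (is.data.frame(tempo_raw)) tempo_raw <- split(tempo_raw, seq_len(nrow(tempo_raw)))
  tempos <- lapply(tempo_raw, function(tp) {
    period <- 60 / tp$bpm
    phase <- if (!is.null(tp$phase_ref_s)) tp$phase_ref_s
    else if (!is.null(tp$sync_timestamps_s))
      estimate_click_phase(unlist(tp$sync_timestamps_s), period) %% period
    else stop("tempo segment needs phase_ref_s or sync_timestamps_s")
    tempo_spec(tp$bpm, phase_ref_s = phase,
               performance_start_s = tp$performance_start_s,
               segment_start_s = if (is.null(tp$segment_start_s)) 0
               else tp$segment_start_s)
  })
  list(layout = layout, notes = notes, tempos = tempos,
       analysis_tag = raw$analysis_tag)
}

.span_columns <- c("participant_id", "trial_id", "note_id", "condition",
                   "expertise", "note_factor", "note_pos", "tempo_bpm",
                   "ets_beats", "saccade_beats", "fix_onset_beats",
                   "fix_beat_pos", "excluded", "ehs_lag_s", "fps_beats")

#' Write span records with an exclusion-summary sidecar
#'
#' CSV with a stable column order and full numeric precision (17 significant
#' digits, so a round-trip read reproduces every value bit-exactly), plus a
#' JSON sidecar `<path>.summary.json` holding the exclusion counts and
#' percentages, an auxiliary seconds scale (`beats * 60/bpm`), the seed and
#' a config hash.  Writes are atomic.
#'
#' @param records Span-record `data.frame` (as from [compute_spans()] or
#'   [measure_experiment()]).
#' @param path Output CSV path.
#' @param seed Seed to record in the sidecar metadata.
#' @param config Optional object fingerprinted into `config_hash`.
#' @return `path`, invisibly.
#' @export
write_spans <- function(records, path, seed = NA_integer_, config = NULL) {
  cols <- intersect(.span_columns, names(records))
  cols <- c(cols, setdiff(names(records), cols))
  d <- records[, cols, drop = FALSE]
  for (j in seq_along(d))
    if (is.double(d[[j]])) d[[j]] <- sprintf("%.17g", d[[j]])
  .atomic_write(function(tmp)
    utils::write.csv(d, tmp, row.names = FALSE, quote = TRUE, na = "NA"),
    path)
  summ <- list(
    n_records = nrow(records),
    exclusions = exclusion_summary(records),
    mean_ets_beats = mean(records$ets_beats[records$excluded == "none"]),
    mean_ets_s = mean((records$ets_beats * 60 / records$tempo_bpm)[
      records$excluded == "none"]),
    seed = seed,
    config_hash = .fnv1a(if (is.null(config)) "" else
      jsonlite::toJSON(config, auto_unbox = TRUE, force = TRUE)))
  .atomic_write(function(tmp)
    jsonlite::write_json(summ, tmp, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns"),
    paste0(path, ".summary.json"))
  invisible(path)
}

#' Read span records written by [write_spans()]
#'
#' @param path CSV path.
#' @return Span-record `data.frame` with numeric columns restored and
#'   `excluded` as a factor.
#' @export
read_spans <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (col in c("note_factor", "note_pos", "tempo_bpm", "ets_beats",
                "saccade_beats", "fix_onset_beats", "fix_beat_pos",
                "ehs_lag_s", "fps_beats"))
    if (col %in% names(d)) d[[col]] <- as.numeric(d[[col]])
  if ("excluded" %in% names(d))
    d$excluded <- factor(d$excluded, levels = c("none", "neg_ets",
                                                "regressive",
                                                "sacc_gt_ets_plus2"))
  d
}
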