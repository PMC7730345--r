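#' Score layout: the stimulus score as a metrical time scale
#'
#' A `score_layout` ties horizontal pixel positions on the displayed score to
#' metrical beat positions, and carries the geometry needed to assign
#' fixations to note areas of interest (AOIs).  The mapping is a monotone
#' piecewise-linear interpolation through `(beat, x)` anchor pairs -- one
#' anchor per notated beat in the simplest case -- so that a score with
#' equidistant note symbols behaves as a literal time axis, while scores with
#' non-uniform engraving (e.g. wider spacing across bar lines) are handled
#' segment-locally.
#'
#' @param anchors_beat Numeric vector of beat positions (quarter-note units,
#'   0-based at performance start), strictly increasing.
#' @param anchors_x Numeric vector of the corresponding horizontal pixel
#'   positions (x grows rightward), strictly increasing, same length.
#' @param staff_y_top,staff_y_bottom Vertical pixel extent of the staff
#'   (y grows downward, so `staff_y_top < staff_y_bottom`).
#' @param aoi_margin Vertical AOI tolerance in pixels beyond the outermost
#'   staff lines (default 35).
#' @param aoi_boundaries Optional strictly increasing pixel cut points between
#'   note AOIs; length must be one more than the number of notes they
#'   delimit.  Usually built with [aoi_boundaries_from_anchors()].
#' @param dialect AOI boundary convention: `"stem_midpoint"` (cuts midway
#'   between note stems) or `"head_midpoint"` (cuts midway between note-head
#'   centers).  Informational; the geometry itself lives in the anchors and
#'   boundaries.
#'
#' @return An object of class `score_layout`.
#' @export
score_layout <- function(anchors_beat, anchors_x,
                         staff_y_top = 0, staff_y_bottom = 0,
                         aoi_margin = 35,
                         aoi_boundaries = NULL,
                         dialect = c("stem_midpoint", "head_midpoint")) {
  dialect <- match.arg(dialect)
  anchors_beat <- as.numeric(anchors_beat)
  anchors_x <- as.numeric(anchors_x)
  if (length(anchors_beat) != length(anchors_x))
    stop("anchors_beat and anchors_x must have equal length")
  if (length(anchors_beat) < 2L)
    stop("a score_layout needs at least 2 anchors")
  if (any(diff(anchors_beat) <= 0) || any(diff(anchors_x) <= 0))
    stop("anchors must be strictly increasing in both beat and x")
  if (!is.null(aoi_boundaries)) {
    aoi_boundaries <- as.numeric(aoi_boundaries)
    if (any(diff(aoi_boundaries) <= 0))
      stop("aoi_boundaries must be strictly increasing")
  }
  if (staff_y_bottom < staff_y_top)
    stop("staff_y_bottom must be >= staff_y_top (y grows downward)")
  structure(
    list(anchors_beat = anchors_beat, anchors_x = anchors_x,
         staff_y_top = staff_y_top, staff_y_bottom = staff_y_bottom,
         aoi_margin = aoi_margin, aoi_boundaries = aoi_boundaries,
         dialect = dialect),
    class = "score_layout")
}

#' @export
print.score_layout <- function(x, ...) {
  cat("<score_layout> ", length(x$anchors_beat), " anchors, beats [",
      x$anchors_beat[1], ", ", x$anchors_beat[length(x$anchors_beat)],
      "], x [", x$anchors_x[1], ", ", x$anchors_x[length(x$anchors_x)],
      "] px, dialect ", x$dialect, "\n", sep = "")
  if (!is.null(x$aoi_boundaries))
    cat("  ", length(x$aoi_boundaries) - 1L, " AOIs, staff y [",
        x$staff_y_top, ", ", x$staff_y_bottom, "] +/- ", x$aoi_margin,
        " px margin\n", sep = "")
  invisible(x)
}

# piecewise-linear map through (u, v) anchors with segment-slope
# extrapolation beyond the hull; strictly monotone for monotone anchors
.pwl <- function(u_anchor, v_anchor, u) {
  n <- length(u_anchor)
  seg <- findInterval(u, u_anchor, all.inside = TRUE)  # clamped to [1, n-1]
  slope <- (v_anchor[seg + 1L] - v_anchor[seg]) / (u_anchor[seg + 1L] - u_anchor[seg])
  v_anchor[seg] + (u - u_anchor[seg]) * slope
}

#' Convert horizontal pixel position to a beat position
#'
#' Reads the score as a metrical time scale: a fixation landing between two
#' note symbols, one third of their mutual distance to the right of the left
#' symbol, sits 0.33 beats past that symbol's beat onset.  Piecewise-linear
#' through the layout anchors; beyond the first/last anchor the adjacent
#' segment's slope is extended.
#'
#' @param layout A [score_layout()].
#' @param x Numeric vector of horizontal pixel positions.
#' @return Beat positions, same length as `x`.
#' @seealso [beat_to_x()] for the exact inverse.
#' @export
x_to_beat <- function(layout, x) {
  stopifnot(inherits(layout, "score_layout"))
  .pwl(layout$anchors_x, layout$anchors_beat, as.numeric(x))
}

#' Convert a beat position to a horizontal pixel position
#'
#' Exact inverse of [x_to_beat()] (the anchor map is strictly monotone, so the
#' inverse is the same piecewise-linear interpolation with the axes swapped).
#'
#' @param layout A [score_layout()].
#' @param beat Numeric vector of beat positions.
#' @return Pixel positions, same length as `beat`.
#' @export
beat_to_x <- function(layout, beat) {
  stopifnot(inherits(layout, "score_layout"))
  .pwl(layout$anchors_beat, layout$anchors_x, as.numeric(beat))
}

#' AOI cut points from note anchor positions
#'
#' Places a boundary at the midpoint of each pair of neighbouring note
#' anchors ("drawn exactly between the note stems" / "at the exact midpoints
#' between the note heads"), and closes the first and last AOI half an
#' adjacent spacing beyond the outer notes.
#'
#' @param x_anchor Strictly increasing note anchor x positions (px).
#' @return Numeric vector of `length(x_anchor) + 1` strictly increasing cut
#'   points.
#' @export
aoi_boundaries_from_anchors <- function(x_anchor) {
  x_anchor <- as.numeric(x_anchor)
  if (length(x_anchor) < 2L) stop("need at least 2 anchors to cut AOIs")
  if (any(diff(x_anchor) <= 0)) stop("x_anchor must be strictly increasing")
  mid <- (x_anchor[-1] + x_anchor[-length(x_anchor)]) / 2
  c(x_anchor[1] - (mid[1] - x_anchor[1]),
    mid,
    x_anchor[length(x_anchor)] + (x_anchor[length(x_anchor)] - mid[length(mid)]))
}

#' Build a note-event table
#'
#' One row per notated symbol.  `beat_onset` is 0-based and continuous;
#' `bar_index`/`pos_in_bar` are 1-based labels.  `tags` is a list column of
#' character vectors with design labels such as `"skip_target"`,
#' `"pre_skip"`, or `"analysis"`.
#'
#' @param note_id Character or integer identifiers, unique.
#' @param beat_onset Strictly increasing numeric beat onsets (>= 0).
#' @param bar_index,pos_in_bar 1-based bar and within-bar beat labels.
#' @param x_anchor Strictly increasing pixel anchors of the note symbols.
#' @param tags List of character vectors (recycled if a single vector).
#' @param ... Further per-note columns (e.g. `degree`, `midi`).
#' @return A `data.frame` with class `note_events` prepended.
#' @export
note_events <- function(note_id, beat_onset, bar_index, pos_in_bar, x_anchor,
                        tags = list(character(0)), ...) {
  if (anyDuplicated(note_id)) stop("note_id must be unique")
  if (any(diff(beat_onset) <= 0)) stop("beat_onset must be strictly increasing")
  if (any(beat_onset < 0)) stop("beat_onset must be >= 0")
  if (any(diff(x_anchor) <= 0)) stop("x_anchor must be strictly increasing")
  if (!is.list(tags)) tags <- list(as.character(tags))
  tags <- rep_len(tags, length(note_id))
  out <- data.frame(note_id = as.character(note_id),
                    beat_onset = as.numeric(beat_onset),
                    bar_index = as.integer(bar_index),
                    pos_in_bar = as.integer(pos_in_bar),
                    x_anchor = as.numeric(x_anchor),
                    stringsAsFactors = FALSE, ...)
  out$tags <- tags
  class(out) <- c("note_events", class(out))
  out
}

#' Test whether notes carry a tag
#'
#' @param notes A [note_events()] table.
#' @param tag A single tag string.
#' @return Logical vector, one element per note.
#' @export
has_tag <- function(notes, tag) {
  vapply(notes$tags, function(tg) tag %in% tg, logical(1))
}

#' Assign fixations to note areas of interest
#'
#' A fixation belongs to the note whose half-open horizontal band
#' `[left, right)` contains its x position, provided its y position lies
#' within the staff band extended by the vertical AOI margin
#' (`[staff_y_top - margin, staff_y_bottom + margin]`).  Fixations outside
#' the AOI grid or the vertical band get `NA` (they are off-score or
#' task-irrelevant).  Boundary ties go to the right-hand AOI, which keeps the
#' AOIs an exact partition of the analyzed region.
#'
#' @param layout A [score_layout()] with `aoi_boundaries` set.
#' @param notes A [note_events()] table; row `i` owns the AOI between
#'   boundaries `i` and `i + 1`.
#' @param x,y Numeric vectors of fixation screen coordinates (px).
#' @return Character vector of `note_id`s with `NA` for unassigned fixations.
#' @export
assign_aoi <- function(layout, notes, x, y) {
  stopifnot(inherits(layout, "score_layout"))
  if (is.null(layout$aoi_boundaries))
    stop("layout has no aoi_boundaries; build them with aoi_boundaries_from_anchors()")
  b <- layout$aoi_boundaries
  if (length(b) != nrow(notes) + 1L)
    stop("aoi_boundaries must delimit exactly one AOI per note (length nrow(notes)+1)")
  x <- as.numeric(x); y <- as.numeric(y)
  # findInterval with left.open=FALSE gives [left, right): b[i] <= x < b[i+1]
  idx <- findInterval(x, b)
  idx[idx < 1L | idx > nrow(notes)] <- NA_integer_
  in_band <- y >= layout$staff_y_top - layout$aoi_margin &
    y <= layout$staff_y_bottom + layout$aoi_margin
  idx[!in_band] <- NA_integer_
  notes$note_id[idx]
}
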