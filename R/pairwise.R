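#' Merge overlapping or abutting genomic intervals
#'
#' Thin wrapper over [IRanges::reduce()] for 0-based half-open intervals.
#' Overlapping and abutting intervals (e.g. `[0,5)` and `[5,9)`) are merged;
#' the result is the minimal sorted disjoint set with the same union.
#'
#' @param intervals Tibble (or data frame) with `start` and `end` columns,
#'   0-based half-open.
#' @return Tibble with `start` and `end`, sorted, disjoint.
#' @examples
#' merge_alignment_intervals(tibble::tibble(start = c(0, 5), end = c(10, 15)))
#' @export
merge_alignment_intervals <- function(intervals) {
  stopifnot(all(c("start", "end") %in% names(intervals)))
  if (nrow(intervals) == 0) return(tibble(start = integer(), end = integer()))
  if (any(intervals$start >= intervals$end)) {
    abort("merge_alignment_intervals: intervals require start < end")
  }
  ir <- IRanges::IRanges(start = intervals$start + 1L, end = intervals$end)
  red <- IRanges::reduce(ir)
  tibble(
    start = IRanges::start(red) - 1L,
    end = IRanges::end(red)
  )
}

#' Per-coordinate best-identity track of a sequence under a set of HSPs
#'
#' For each coordinate of the sequence, takes the highest percent identity
#' among the HSPs whose interval on the chosen side covers it (stored as a
#' fraction in `[0, 1]`); coordinates covered by no alignment get 0.
#' Reverse-strand HSPs contribute over their coordinate span like forward
#' ones — the statistic is orientation-agnostic.
#'
#' @param hsps HSP tibble.
#' @param seq_id Sequence id to build the track for.
#' @param seq_length Length of that sequence in bp.
#' @param side `"query"` or `"subject"`: which side of the HSPs carries
#'   `seq_id`.
#' @return An `identity_track` object: list with `seq_id`, `length` and
#'   `best_identity` (numeric vector of length `seq_length`).
#' @export
best_identity_track <- function(hsps, seq_id, seq_length, side = c("query", "subject")) {
  side <- match.arg(side)
  validate_hsps(hsps)
  idc <- if (side == "query") "query_id" else "subject_id"
  stc <- if (side == "query") "q_start" else "s_start"
  enc <- if (side == "query") "q_end" else "s_end"
  h <- hsps[hsps[[idc]] == seq_id, , drop = FALSE]
  if (nrow(h) && max(h[[enc]]) > seq_length) {
    abort("best_identity_track: HSP interval exceeds seq_length")
  }
  track <- numeric(seq_length)
  for (i in seq_len(nrow(h))) {
    idx <- (h[[stc]][i] + 1L):h[[enc]][i]
    track[idx] <- pmax(track[idx], h$percent_identity[i] / 100)
  }
  structure(
    list(seq_id = seq_id, length = seq_length, best_identity = track),
    class = "identity_track"
  )
}

#' Total pairwise identity statistic T = I / L
#'
#' Combines the per-coordinate best-identity tracks of two sequences into the
#' scalar statistic `T = I / L`, where `I` is the sum of the highest alignment
#' identities at each coordinate of both sequences and `L` the sum of the two
#' sequence lengths. `T` is 1 exactly when every coordinate of both sequences
#' is covered by a 100%-identity alignment, and 0 when there are no
#' alignments. Repetitive elements present in unequal copy number on the two
#' sequences inflate `T`, since one copy can align to many places on the
#' partner sequence.
#'
#' @param track_a,track_b `identity_track` objects from
#'   [best_identity_track()].
#' @return An `identity_comparison` object with elements `track_a`, `track_b`,
#'   `I`, `L` and `T`.
#' @export
total_identity <- function(track_a, track_b) {
  stopifnot(inherits(track_a, "identity_track"), inherits(track_b, "identity_track"))
  L <- track_a$length + track_b$length
  if (L == 0) abort("total_identity: zero combined length")
  I <- sum(track_a$best_identity) + sum(track_b$best_identity)
  structure(
    list(track_a = track_a, track_b = track_b, I = I, L = L, T = I / L),
    class = "identity_comparison"
  )
}

#' @export
print.identity_comparison <- function(x, ...) {
  cat(
    "<identity_comparison> ", x$track_a$seq_id, " vs ", x$track_b$seq_id,
    ": T = I/L = ", format(x$I, digits = 6), "/", x$L,
    " = ", format(x$T, digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname total_identity
#' @param x An `identity_comparison`.
#' @param ... Unused.
#' @export
glance.identity_comparison <- function(x, ...) {
  tibble(
    seq_a = x$track_a$seq_id, seq_b = x$track_b$seq_id,
    length_a = x$track_a$length, length_b = x$track_b$length,
    I = x$I, L = x$L, T = x$T
  )
}

#' @rdname total_identity
#' @export
tidy.identity_track <- function(x, ...) {
  tibble(
    seq_id = x$seq_id,
    position = seq_len(x$length) - 1L,
    best_identity = x$best_identity
  )
}
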