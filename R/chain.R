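#' Chain transcript-to-locus HSPs into ordered alignment structures
#'
#' Groups HSPs by transcript, orders blocks along the transcript, and selects
#' for each transcript the maximum-bitscore subset of blocks in which every
#' pair of consecutive retained blocks is within `max_intron` bp on the
#' genome. This makes the "split at long introns, keep the better-scoring
#' side" rule exact: the selection agrees with brute-force enumeration of all
#' block subsets respecting the intron limit. Transcripts whose surviving
#' blocks cover less than `min_coverage` of their length are dropped.
#'
#' @param hsps HSP tibble (see [read_blast_tab()]); all HSPs must share one
#'   subject sequence.
#' @param transcript_lengths Named vector of transcript lengths in bp, or a
#'   sequence tibble with `id` and `seq` columns (lengths are taken from the
#'   sequences). Must cover every query id in `hsps`.
#' @param max_intron Maximum allowed genomic gap between consecutive blocks.
#' @param min_coverage Minimum fraction of the transcript covered by the union
#'   of surviving block query intervals, in `[0, 1]`.
#' @param trim_query_overlaps Resolve splice-junction overlaps: when two
#'   consecutive retained blocks double-align the same transcript bases
#'   (local alignments extending across a splice junction always do), the
#'   overlap is trimmed from the block with the lower percent identity (ties:
#'   from the upstream block), shifting its genomic edge by the same amount
#'   (junction-proximal alignment is treated as ungapped). Each transcript
#'   base is then reported aligned at most once, which is what exon inference
#'   downstream wants. Set to `FALSE` to keep raw HSP extents.
#' @return A `tast_alignment` object: a list with
#'   * `blocks`: tibble of surviving blocks with `order_index` (0-based order
#'     along the transcript) and the HSP columns;
#'   * `transcripts`: one row per retained transcript with
#'     `transcript_length`, `coverage`, `n_blocks` and `s_leftmost`,
#'     sorted by leftmost subject coordinate;
#'   * `params`: the chaining parameters.
#' @examples
#' hsps <- tibble::tibble(
#'   query_id = "t1", subject_id = "g", percent_identity = 100,
#'   q_start = c(0L, 40L), q_end = c(40L, 100L),
#'   s_start = c(1000L, 5000L), s_end = c(1040L, 5060L),
#'   strand = "forward", bitscore = c(74, 110)
#' )
#' chain_transcript_alignments(hsps, c(t1 = 100), max_intron = 10000,
#'                             min_coverage = 0.9)
#' @export
chain_transcript_alignments <- function(hsps, transcript_lengths, max_intron,
                                        min_coverage = 0,
                                        trim_query_overlaps = TRUE) {
  validate_hsps(hsps)
  if (min_coverage < 0 || min_coverage > 1) {
    abort("min_coverage must lie in [0, 1]")
  }
  if (is.data.frame(transcript_lengths)) {
    transcript_lengths <- setNames(
      nchar(transcript_lengths$seq), transcript_lengths$id
    )
  }
  unknown <- setdiff(unique(hsps$query_id), names(transcript_lengths))
  if (length(unknown)) {
    abort(paste0(
      "transcript length unknown for query id(s): ", paste(unknown, collapse = ", ")
    ))
  }
  if (length(unique(hsps$subject_id)) > 1) {
    abort("all HSPs must share a single subject sequence")
  }

  groups <- split(hsps, hsps$query_id)
  kept <- purrr::map(groups, function(g) {
    g <- arrange(g, .data$q_start, .data$s_start)
    sel <- chain_select_blocks(g, max_intron)
    g <- g[sel, , drop = FALSE]
    if (trim_query_overlaps) g <- trim_junction_overlaps(g)
    cov <- interval_union_width(g$q_start, g$q_end) /
      transcript_lengths[[g$query_id[1]]]
    if (cov < min_coverage) return(NULL)
    g$order_index <- seq_len(nrow(g)) - 1L
    attr(g, "coverage") <- cov
    g
  })
  kept <- purrr::compact(kept)
  if (!length(kept)) {
    return(new_tast_alignment(
      blocks = cbind_order(empty_hsp_tbl()),
      transcripts = tibble(
        transcript_id = character(), transcript_length = numeric(),
        coverage = numeric(), n_blocks = integer(), s_leftmost = integer()
      ),
      params = list(max_intron = max_intron, min_coverage = min_coverage)
    ))
  }
  kept <- purrr::map(kept, function(g) {
    g$transcript_id <- g$query_id
    g
  })
  txs <- tibble(
    transcript_id = unname(purrr::map_chr(kept, ~ .x$query_id[1])),
    transcript_length = unname(transcript_lengths[purrr::map_chr(kept, ~ .x$query_id[1])]),
    coverage = unname(purrr::map_dbl(kept, ~ attr(.x, "coverage"))),
    n_blocks = unname(purrr::map_int(kept, nrow)),
    s_leftmost = unname(purrr::map_int(kept, ~ min(.x$s_start)))
  ) |>
    arrange(.data$s_leftmost, .data$transcript_id)
  blocks <- bind_rows(kept[txs$transcript_id])
  new_tast_alignment(
    blocks = blocks,
    transcripts = txs,
    params = list(max_intron = max_intron, min_coverage = min_coverage)
  )
}

cbind_order <- function(tbl) {
  tbl$order_index <- integer(nrow(tbl))
  tbl$transcript_id <- character(nrow(tbl))
  tbl
}

new_tast_alignment <- function(blocks, transcripts, params) {
  structure(
    list(blocks = blocks, transcripts = transcripts, params = params),
    class = "tast_alignment"
  )
}

#' @export
print.tast_alignment <- function(x, ...) {
  cat(
    "<tast_alignment> ", nrow(x$transcripts), " transcript(s), ",
    nrow(x$blocks), " block(s); max_intron = ", x$params$max_intron,
    ", min_coverage = ", x$params$min_coverage, "\n",
    sep = ""
  )
  print(x$transcripts, ...)
  invisible(x)
}

# maximum-bitscore subset of query-ordered blocks such that each consecutive
# retained pair is within max_intron on the genome; O(n^2) chain DP
chain_select_blocks <- function(g, max_intron) {
  n <- nrow(g)
  if (n == 1) return(1L)
  best <- g$bitscore
  prev <- rep(NA_integer_, n)
  for (j in seq_len(n)[-1]) {
    for (i in seq_len(j - 1)) {
      gap <- genomic_gap(g$s_start[i], g$s_end[i], g$s_start[j], g$s_end[j])
      if (gap <= max_intron && best[i] + g$bitscore[j] > best[j]) {
        best[j] <- best[i] + g$bitscore[j]
        prev[j] <- i
      }
    }
  }
  j <- which.max(best)
  sel <- integer(0)
  while (!is.na(j)) {
    sel <- c(j, sel)
    j <- prev[j]
  }
  sel
}

# trim doubly-aligned transcript bases between consecutive blocks; the block
# with lower percent identity yields (ties: the upstream block's 3' end)
trim_junction_overlaps <- function(g) {
  if (nrow(g) < 2) return(g)
  repeat {
    changed <- FALSE
    i <- 1L
    while (i < nrow(g)) {
      k <- g$q_end[i] - g$q_start[i + 1]
      if (k > 0) {
        trim_up <- g$percent_identity[i] <= g$percent_identity[i + 1]
        j <- if (trim_up) i else i + 1L
        if (k >= g$q_end[j] - g$q_start[j]) {
          g <- g[-j, , drop = FALSE]          # overlap swallows the block
        } else if (trim_up) {
          g$q_end[i] <- g$q_end[i] - k
          if (g$strand[i] == "forward") g$s_end[i] <- g$s_end[i] - k
          else g$s_start[i] <- g$s_start[i] + k
        } else {
          g$q_start[i + 1] <- g$q_start[i + 1] + k
          if (g$strand[i + 1] == "forward") g$s_start[i + 1] <- g$s_start[i + 1] + k
          else g$s_end[i + 1] <- g$s_end[i + 1] - k
        }
        changed <- TRUE
        break
      }
      i <- i + 1L
    }
    if (!changed) break
  }
  g
}

genomic_gap <- function(a1, b1, a2, b2) {
  max(0L, max(a1, a2) - min(b1, b2))
}

interval_union_width <- function(start, end) {
  if (!length(start)) return(0)
  m <- merge_alignment_intervals(tibble(start = start, end = end))
  sum(m$end - m$start)
}

#' Detect collinear runs of alignment blocks along the genome
#'
#' Blocks are taken in ascending genomic order; a maximal run in which the
#' transcript order indices are non-decreasing with steps of 0 or +1 (e.g.
#' 1, 2, 3, 3) is collinear, and its genomic span is reported. A single block
#' is trivially collinear, so every block belongs to exactly one run.
#'
#' @param blocks Block tibble (from a `tast_alignment`) with `transcript_id`,
#'   `order_index`, `s_start`, `s_end`. Multiple transcripts are handled per
#'   transcript.
#' @return Tibble with one row per run: `transcript_id`, `start`, `end`
#'   (genomic span of the run), `n_blocks`.
#' @export
detect_collinearity <- function(blocks) {
  if (is.list(blocks) && inherits(blocks, "tast_alignment")) blocks <- blocks$blocks
  if (nrow(blocks) == 0) {
    return(tibble(
      transcript_id = character(), start = integer(),
      end = integer(), n_blocks = integer()
    ))
  }
  blocks |>
    group_by(.data$transcript_id) |>
    dplyr::group_modify(function(g, key) {
      g <- arrange(g, .data$s_start, .data$s_end)
      step <- diff(g$order_index)
      breaks <- c(TRUE, !(step %in% c(0L, 1L)))
      run <- cumsum(breaks)
      tibble(
        start = as.vector(tapply(g$s_start, run, min)),
        end = as.vector(tapply(g$s_end, run, max)),
        n_blocks = as.integer(as.vector(tapply(run, run, length)))
      )
    }) |>
    ungroup()
}

#' Splice-boundary placement error of a chained alignment
#'
#' For every internal block edge (all genomic block starts and ends except the
#' leftmost start and rightmost end of the transcript's alignment), computes
#' the distance to the nearest annotated exon boundary and sums them. A value
#' of 0 means perfect splice placement; errors of 1 bp typically reflect
#' splice-junction alignment ambiguity.
#'
#' @param blocks A `tast_alignment` or its block tibble.
#' @param boundaries Integer vector of annotated exon edges (0-based positions
#'   on the subject, i.e. each exon contributes its start and its end).
#' @return Tibble with one row per transcript: `transcript_id`, `error`
#'   (summed bp over internal edges), `n_internal_edges`.
#' @export
splice_boundary_error <- function(blocks, boundaries) {
  if (inherits(blocks, "tast_alignment")) blocks <- blocks$blocks
  if (!length(boundaries)) abort("splice_boundary_error: empty boundary annotation")
  boundaries <- as.numeric(boundaries)
  blocks |>
    group_by(.data$transcript_id) |>
    summarise(
      error = {
        edges <- sort(c(.data$s_start, .data$s_end))
        internal <- edges[-c(1, length(edges))]
        if (length(internal)) {
          sum(purrr::map_dbl(internal, ~ min(abs(.x - boundaries))))
        } else 0
      },
      n_internal_edges = 2L * (n() - 1L),
      .groups = "drop"
    )
}
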