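#' Find open reading frames on the forward strand of a transcript
#'
#' Scans all three frames with the standard codon table. For each
#' (frame, stop codon) pair the maximal ORF runs from the 5'-most in-frame ATG
#' after the previous stop through that stop; the stop codon is included in the
#' `[start, end)` interval but excluded from the protein. Transcripts are
#' assumed pre-oriented (poly-A at the 3' end), so only the forward strand is
#' scanned.
#'
#' @param seq Transcript nucleotide string (or a one-row sequence tibble).
#' @param require_stop If `TRUE` (default) ORFs lacking a terminal stop codon
#'   are excluded; if `FALSE` an ATG reaching the end of the sequence without a
#'   stop yields an open-ended ORF ending at the last complete codon.
#' @param all_starts If `TRUE`, every in-frame ATG inside a (frame, stop) unit
#'   yields its own (nested) ORF rather than only the 5'-most. Used by
#'   cysteine-rich ORF selection.
#' @return A tibble with columns `start`, `end` (0-based half-open on the
#'   transcript), `frame`, `protein`, `cysteine_count`, `has_stop`,
#'   `is_longest`. At most one row has `is_longest = TRUE`; ties on length are
#'   broken 5'-most.
#' @examples
#' find_orfs("ATGTGCTGTTAA")
#' @export
find_orfs <- function(seq, require_stop = TRUE, all_starts = FALSE) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1)
    seq <- seq$seq
  }
  s <- toupper(seq)
  n <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    if (n - frame < 3) next
    ncod <- (n - frame) %/% 3
    starts_nt <- frame + 3L * (seq_len(ncod) - 1L)        # 0-based codon starts
    codons <- substring(s, starts_nt + 1L, starts_nt + 3L)
    is_atg <- codons == "ATG"
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    unit_start <- 1L                                      # codon index of unit begin
    i <- 1L
    while (i <= ncod) {
      if (is_stop[i] || i == ncod) {
        unit <- unit_start:i
        atgs <- unit[is_atg[unit]]
        if (is_stop[i]) atgs <- atgs[atgs < i] else atgs <- atgs
        if (length(atgs)) {
          use <- if (all_starts) atgs else atgs[1]
          for (a in use) {
            if (is_stop[i]) {
              start <- starts_nt[a]
              end <- starts_nt[i] + 3L
              prot <- translate_dna(substr(s, start + 1, end - 3), 0L)
              out[[length(out) + 1L]] <- tibble(
                start = start, end = end, frame = frame,
                protein = prot, has_stop = TRUE
              )
            } else if (!require_stop) {
              start <- starts_nt[a]
              end <- starts_nt[i] + 3L                     # last complete codon
              prot <- translate_dna(substr(s, start + 1, end), 0L)
              out[[length(out) + 1L]] <- tibble(
                start = start, end = end, frame = frame,
                protein = prot, has_stop = FALSE
              )
            }
          }
        }
        unit_start <- i + 1L
      }
      i <- i + 1L
    }
  }
  if (!length(out)) {
    return(tibble(
      start = integer(), end = integer(), frame = integer(),
      protein = character(), cysteine_count = integer(),
      has_stop = logical(), is_longest = logical()
    ))
  }
  orfs <- bind_rows(out) |>
    mutate(cysteine_count = stringr::str_count(.data$protein, stringr::fixed("C"))) |>
    arrange(.data$start, .data$end)
  len <- orfs$end - orfs$start
  best <- which(len == max(len))[1]                        # ties: 5'-most wins
  orfs$is_longest <- seq_len(nrow(orfs)) == best
  orfs[, c("start", "end", "frame", "protein", "cysteine_count", "has_stop", "is_longest")]
}

#' Classify an alignment block by ORF overlap
#'
#' A block overlapping (by at least 1 bp) the longest ORF of its transcript is
#' `"longest_orf"`; overlapping any other ORF, `"minor_orf"`; otherwise
#' `"non_orf"`. These drive the fill/border colours of the alignment plot.
#'
#' @param q_start,q_end Block query interval (0-based half-open).
#' @param orfs ORF tibble from [find_orfs()] for the same transcript.
#' @return One of `"longest_orf"`, `"minor_orf"`, `"non_orf"` (vectorised over
#'   blocks).
#' @export
classify_block <- function(q_start, q_end, orfs) {
  stopifnot(length(q_start) == length(q_end))
  purrr::map2_chr(q_start, q_end, function(a, b) {
    if (nrow(orfs) == 0) return("non_orf")
    ov <- pmin(b, orfs$end) - pmax(a, orfs$start) > 0
    if (any(ov & orfs$is_longest)) "longest_orf"
    else if (any(ov)) "minor_orf"
    else "non_orf"
  })
}
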