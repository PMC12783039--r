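#' Filter reads by mean Phred quality
#'
#' Keeps reads whose mean Phred score is at least `min_mean_q` (boundary
#' inclusive); the Q30 default corresponds to a mean predicted accuracy of
#' 99.9%. Order is preserved.
#'
#' @param reads Read tibble from [read_fastq()] (with a `quality` list
#'   column).
#' @param min_mean_q Minimum mean Phred score.
#' @return The filtered read tibble.
#' @export
filter_by_quality <- function(reads, min_mean_q = 30) {
  stopifnot("quality" %in% names(reads))
  keep <- purrr::map_dbl(reads$quality, mean) >= min_mean_q
  reads[keep, , drop = FALSE]
}

#' Demultiplex reads by terminal barcodes
#'
#' Searches each barcode (and its reverse complement) by Hamming-distance
#' scanning within the first and last `window` bp of every read. A read is
#' `assigned` when both ends match the same barcode with at most
#' `max_mismatches` mismatches; reads matching at one end only
#' (`one_end_only`) or matching different barcodes at the two ends
#' (`conflicting_ends`, a chimera guard) are excluded from the assigned set
#' but reported with their status, as are reads with `no_barcode`.
#'
#' @param reads Read or sequence tibble (columns `id`, `seq`).
#' @param barcodes Sequence tibble of pairwise-distinct barcodes.
#' @param window Terminal search window in bp.
#' @param max_mismatches Maximum Hamming mismatches for a barcode hit.
#' @return Tibble with one row per read: `read_id`, `barcode_id` (`NA` unless
#'   assigned), `status`, `mm_5p`, `mm_3p` (best mismatch counts per end).
#' @export
demultiplex_barcodes <- function(reads, barcodes, window = 150L, max_mismatches = 2L) {
  if (nrow(barcodes) == 0) abort("demultiplex_barcodes: empty barcode list")
  if (anyDuplicated(barcodes$seq)) abort("demultiplex_barcodes: barcodes must be distinct")
  bc_fwd <- toupper(barcodes$seq)
  bc_rev <- purrr::map_chr(bc_fwd, reverse_complement)
  res <- purrr::map2(reads$id, reads$seq, function(id, s) {
    n <- nchar(s)
    w <- min(window, n)
    head_win <- substr(s, 1, w)
    tail_win <- substr(s, n - w + 1, n)
    best_end <- function(win) {
      mm <- purrr::map2_int(bc_fwd, bc_rev, function(f, r) {
        min(min_hamming_scan(win, f), min_hamming_scan(win, r))
      })
      list(idx = which.min(mm), mm = min(mm))
    }
    h <- best_end(head_win)
    t <- best_end(tail_win)
    hit5 <- h$mm <= max_mismatches
    hit3 <- t$mm <= max_mismatches
    status <-
      if (hit5 && hit3 && h$idx == t$idx) "assigned"
      else if (hit5 && hit3) "conflicting_ends"
      else if (hit5 || hit3) "one_end_only"
      else "no_barcode"
    tibble(
      read_id = id,
      barcode_id = if (status == "assigned") barcodes$id[h$idx] else NA_character_,
      status = status,
      mm_5p = if (hit5) h$mm else NA_integer_,
      mm_3p = if (hit3) t$mm else NA_integer_
    )
  })
  bind_rows(res)
}

# minimum Hamming distance of `pattern` over all alignments inside `window`
min_hamming_scan <- function(window, pattern) {
  n <- nchar(window); m <- nchar(pattern)
  if (n < m) return(m)
  w <- utf8ToInt(window); p <- utf8ToInt(pattern)
  best <- m
  for (i in 0:(n - m)) {
    d <- sum(w[(i + 1):(i + m)] != p)
    if (d < best) best <- d
    if (best == 0L) break
  }
  as.integer(best)
}

#' Orient a read by its poly-A tail
#'
#' If the longest adenosine run within the last `search_window` bp is at least
#' `min_tail`, the read is already forward; if instead the longest thymidine
#' run within the first `search_window` bp qualifies, the read is
#' reverse-complemented. When both qualify the longer run wins; ties and reads
#' with neither run are filtered (returned as `NA`).
#'
#' @param seq Read sequence (character scalar).
#' @param min_tail Minimum run length in bp.
#' @param search_window Terminal window searched for the run.
#' @return List with `seq` (oriented sequence or `NA`), `oriented` (logical),
#'   `polya_length` (bp or `NA`).
#' @export
orient_by_polya <- function(seq, min_tail = 10L, search_window = 50L) {
  s <- toupper(seq)
  n <- nchar(s)
  w <- min(search_window, n)
  a_run <- longest_run(substr(s, n - w + 1, n), "A")
  t_run <- longest_run(substr(s, 1, w), "T")
  a_ok <- a_run >= min_tail
  t_ok <- t_run >= min_tail
  if (a_ok && (!t_ok || a_run > t_run)) {
    list(seq = s, oriented = TRUE, polya_length = a_run)
  } else if (t_ok && (!a_ok || t_run > a_run)) {
    list(seq = reverse_complement(s), oriented = TRUE, polya_length = t_run)
  } else {
    list(seq = NA_character_, oriented = FALSE, polya_length = NA_integer_)
  }
}

longest_run <- function(s, base) {
  r <- rle(strsplit(s, "")[[1]])
  hits <- r$lengths[r$values == base]
  if (length(hits)) max(hits) else 0L
}

#' Full long-read preprocessing pipeline
#'
#' Chains quality filtering, two-ended barcode demultiplexing and poly-A
#' orientation (demultiplexing first, orientation after). Reads assigned a
#' barcode but lacking a qualifying poly-A signal get status `"no_polya"`, so
#' `status == "assigned"` always implies an oriented read with a barcode.
#'
#' @inheritParams demultiplex_barcodes
#' @inheritParams orient_by_polya
#' @param min_mean_q Minimum mean Phred quality; use `-Inf` (or reads without
#'   a `quality` column) to skip the filter.
#' @return Tibble with `read_id`, `barcode_id`, `status`, `oriented`,
#'   `polya_length`, and `seq` (oriented sequence for assigned reads).
#' @export
preprocess_reads <- function(reads, barcodes, min_mean_q = 30, window = 150L,
                             max_mismatches = 2L, min_tail = 10L,
                             search_window = 50L) {
  if ("quality" %in% names(reads) && is.finite(min_mean_q)) {
    reads <- filter_by_quality(reads, min_mean_q)
  }
  demux <- demultiplex_barcodes(reads, barcodes, window, max_mismatches)
  demux$oriented <- FALSE
  demux$polya_length <- NA_integer_
  demux$seq <- NA_character_
  for (i in seq_len(nrow(demux))) {
    if (demux$status[i] != "assigned") next
    ori <- orient_by_polya(reads$seq[i], min_tail, search_window)
    if (ori$oriented) {
      demux$oriented[i] <- TRUE
      demux$polya_length[i] <- ori$polya_length
      demux$seq[i] <- ori$seq
    } else {
      demux$status[i] <- "no_polya"
      demux$barcode_id[i] <- NA_character_
    }
  }
  demux
}

#' N50 of a length distribution
#'
#' The largest length `L` such that sequences of length at least `L` together
#' contain at least half of the total sequence.
#'
#' @param lengths Positive integer vector of sequence lengths.
#' @return N50 in bp.
#' @examples
#' compute_n50(c(5, 4, 3, 2, 1))
#' @export
compute_n50 <- function(lengths) {
  if (!length(lengths)) abort("compute_n50: empty length list")
  if (any(lengths <= 0)) abort("compute_n50: lengths must be positive")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= sum(as.numeric(s)) / 2)[1]]
}
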