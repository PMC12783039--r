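#' Retrieve transcripts hit by exon queries
#'
#' Returns the ids of transcripts (HSP subjects) hit by at least one
#' exon-query HSP at or above a bitscore threshold.
#'
#' @param hsps HSP tibble of exon queries vs transcript subjects.
#' @param min_bitscore Bitscore threshold.
#' @return Sorted character vector of unique transcript ids.
#' @export
mine_transcripts_by_exon <- function(hsps, min_bitscore) {
  validate_hsps(hsps)
  sort(unique(hsps$subject_id[hsps$bitscore >= min_bitscore]))
}

#' Select the most cysteine-rich ORF of a transcript
#'
#' In metallothionein mining the longest ORF is not always the coding one; the
#' true ORF is recognised by its high cysteine content. This scans all ORFs of
#' the transcript, including alternative in-frame ATG starts within each
#' (frame, stop) unit, and returns the one with the most cysteines (ties:
#' longest, then 5'-most). Returns no ORF when the best has fewer than
#' `min_cys` cysteines.
#'
#' @param seq Transcript sequence (character scalar or one-row tibble).
#' @param min_cys Minimum cysteine count to accept an ORF.
#' @param require_stop Require a terminal stop codon (see [find_orfs()]).
#' @return A one-row ORF tibble, or a zero-row tibble when no ORF passes.
#' @export
select_cysteine_rich_orf <- function(seq, min_cys = 10L, require_stop = TRUE) {
  orfs <- find_orfs(seq, require_stop = require_stop, all_starts = TRUE)
  if (nrow(orfs) == 0) return(orfs)
  orfs <- arrange(
    orfs,
    desc(.data$cysteine_count), desc(.data$end - .data$start), .data$start
  )
  best <- orfs[1, , drop = FALSE]
  if (best$cysteine_count < min_cys) return(orfs[0, , drop = FALSE])
  best
}

#' Collapse identical proteins into clusters
#'
#' Removes redundancy at 100% protein identity: one cluster per distinct
#' protein string, carrying its member transcript ids and count. Clusters are
#' sorted by count (descending), ties broken lexicographically by protein.
#'
#' @param proteins Tibble with columns `transcript_id` and `protein`.
#' @return Tibble with `protein`, `count`, `cysteine_count`, `member_ids`
#'   (list column).
#' @export
dedupe_protein_clusters <- function(proteins) {
  if (nrow(proteins) == 0) {
    return(tibble(
      protein = character(), count = integer(),
      cysteine_count = integer(), member_ids = list()
    ))
  }
  proteins |>
    group_by(.data$protein) |>
    summarise(count = n(), member_ids = list(.data$transcript_id), .groups = "drop") |>
    mutate(cysteine_count = stringr::str_count(.data$protein, stringr::fixed("C"))) |>
    arrange(desc(.data$count), .data$protein) |>
    select("protein", "count", "cysteine_count", "member_ids")
}

#' Classify transcripts into clades by 3'-UTR alignment
#'
#' The 3' UTR is the most clade-divergent part of these transcripts, so a
#' transcript is assigned the clade of its best-scoring UTR query. HSPs below
#' `min_bitscore` are ignored; a transcript whose top passing bitscore is tied
#' between two clades is reported as `"unclassified"`.
#'
#' @param hsps HSP tibble of UTR queries vs transcript subjects.
#' @param clades Tibble mapping `query_id` (UTR query) to `clade` (label).
#' @param min_bitscore Bitscore threshold.
#' @return Tibble with `transcript_id`, `clade`, `bitscore` (top passing hit);
#'   transcripts with no passing hit are absent.
#' @export
classify_by_utr <- function(hsps, clades, min_bitscore) {
  validate_hsps(hsps)
  stopifnot(all(c("query_id", "clade") %in% names(clades)))
  h <- hsps |>
    filter(.data$bitscore >= min_bitscore) |>
    left_join(clades[, c("query_id", "clade")], by = "query_id")
  if (any(is.na(h$clade))) abort("classify_by_utr: UTR query without a clade label")
  h |>
    group_by(transcript_id = .data$subject_id) |>
    summarise(
      clade = {
        top <- .data$clade[.data$bitscore == max(.data$bitscore)]
        if (length(unique(top)) > 1) "unclassified" else top[1]
      },
      bitscore = max(.data$bitscore),
      .groups = "drop"
    )
}

#' Tissue count summary with representation ratios
#'
#' Computes, for each tissue, its share of all transcripts and of
#' target-family transcripts, and the representation ratio (the target share
#' divided by the overall share; > 1 marks enrichment). Percentages and ratios
#' are computed on unrounded fractions, then rounded half-away-from-zero to
#' one decimal. A totals row carries the column sums and 100 / 100 / 1.
#'
#' @param counts Tibble with `tissue`, `transcripts` (total transcript count)
#'   and `target_count` (target-family transcript count) per tissue.
#' @return Tibble with `tissue`, `transcripts`, `transcripts_pct`,
#'   `target_count`, `target_pct`, `representation`; last row is `"Total"`.
#' @export
tissue_summary <- function(counts) {
  stopifnot(all(c("tissue", "transcripts", "target_count") %in% names(counts)))
  if (nrow(counts) == 0) abort("tissue_summary: no rows")
  if (any(counts$transcripts < 0) || any(counts$target_count < 0)) {
    abort("tissue_summary: negative count")
  }
  tot_tx <- sum(counts$transcripts)
  tot_tg <- sum(counts$target_count)
  frac_tx <- counts$transcripts / tot_tx
  frac_tg <- counts$target_count / tot_tg
  rows <- tibble(
    tissue = counts$tissue,
    transcripts = counts$transcripts,
    transcripts_pct = round_half_away(100 * frac_tx, 1),
    target_count = counts$target_count,
    target_pct = round_half_away(100 * frac_tg, 1),
    representation = round_half_away(frac_tg / frac_tx, 1)
  )
  bind_rows(rows, tibble(
    tissue = "Total", transcripts = tot_tx, transcripts_pct = 100,
    target_count = tot_tg, target_pct = 100, representation = 1
  ))
}

iupac_sets <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

set_to_iupac <- local({
  codes <- vapply(iupac_sets, function(s) paste(sort(s), collapse = ""), "")
  setNames(names(codes), codes)
})

#' IUPAC consensus and mean identity of splice-site flanks
#'
#' Builds, per position, the minimal IUPAC code covering every base whose
#' frequency reaches `ambiguity_threshold` (if no base reaches the threshold,
#' all observed bases are covered, possibly giving `N`), and the mean over all
#' unordered sequence pairs of positionwise percent identity. Used on fixed-
#' width (e.g. 10 bp) regions flanking splice donors and acceptors.
#'
#' @param flanks Character vector of equal-length ungapped sequences, or a
#'   sequence tibble.
#' @param ambiguity_threshold Minimum base frequency for inclusion in the
#'   consensus code.
#' @param consensus_only Allow a single sequence (identity reported as `NA`).
#' @return A `consensus_result` list: `consensus`, `mean_identity_pct`,
#'   `n_sequences`.
#' @export
splice_site_consensus <- function(flanks, ambiguity_threshold = 0.25,
                                  consensus_only = FALSE) {
  if (is.data.frame(flanks)) flanks <- flanks$seq
  flanks <- toupper(flanks)
  if (!length(flanks)) abort("splice_site_consensus: no sequences")
  if (length(unique(nchar(flanks))) != 1) {
    abort("splice_site_consensus: flanks must be of equal length")
  }
  if (length(flanks) < 2 && !consensus_only) {
    abort("splice_site_consensus: need >= 2 sequences for identity (set consensus_only = TRUE)")
  }
  m <- do.call(rbind, strsplit(flanks, ""))
  consensus <- apply(m, 2, function(col) {
    freq <- table(col) / length(col)
    keep <- names(freq)[freq >= ambiguity_threshold]
    if (!length(keep)) keep <- names(freq)
    key <- paste(sort(unique(unlist(iupac_sets[keep]))), collapse = "")
    code <- set_to_iupac[[key]]
    if (is.null(code)) "N" else code
  })
  mean_id <- NA_real_
  if (length(flanks) >= 2) {
    pairs <- utils::combn(length(flanks), 2)
    ids <- apply(pairs, 2, function(p) 100 * mean(m[p[1], ] == m[p[2], ]))
    mean_id <- mean(ids)
  }
  structure(
    list(
      consensus = paste(consensus, collapse = ""),
      mean_identity_pct = mean_id,
      n_sequences = length(flanks)
    ),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat(
    "<consensus_result> ", x$consensus, " (", x$n_sequences, " sequences",
    if (!is.na(x$mean_identity_pct)) {
      paste0(", mean pairwise identity ", format(x$mean_identity_pct, digits = 4), "%")
    },
    ")\n",
    sep = ""
  )
  invisible(x)
}

#' Scan a sequence for an IUPAC motif
#'
#' Reports every 0-based start position whose window matches the pattern
#' under IUPAC semantics: each concrete base of the sequence must belong to
#' the set denoted by the pattern character (an `N` in the sequence matches
#' only pattern `N`). With `both_strands = TRUE`, matches of the
#' reverse-complement pattern are also reported (positions on the forward
#' coordinate system).
#'
#' @param seq Sequence (character scalar or one-row tibble).
#' @param pattern IUPAC pattern string (e.g. `"AATAAA"` for the poly-A
#'   signal).
#' @param both_strands Also scan the reverse strand.
#' @return Integer vector of 0-based match start positions (sorted, unique).
#' @export
scan_motif <- function(seq, pattern, both_strands = FALSE) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1)
    seq <- seq$seq
  }
  s <- toupper(seq); p <- toupper(pattern)
  if (grepl("[^ACGTRYSWKMBDHVN]", p)) abort("scan_motif: invalid IUPAC character in pattern")
  hits <- iupac_scan(s, p)
  if (both_strands) {
    rc <- paste(
      rev(purrr::map_chr(strsplit(p, "")[[1]], iupac_complement)),
      collapse = ""
    )
    hits <- union(hits, iupac_scan(s, rc))
  }
  sort(unique(hits))
}

iupac_complement <- function(ch) {
  chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", ch)
}

iupac_scan <- function(s, p) {
  n <- nchar(s); m <- nchar(p)
  if (n < m) return(integer(0))
  smat <- strsplit(s, "")[[1]]
  pmat <- strsplit(p, "")[[1]]
  ok <- matrix(TRUE, nrow = n - m + 1, ncol = m)
  for (j in seq_len(m)) {
    allowed <- iupac_sets[[pmat[j]]]
    sub <- smat[j:(j + n - m)]
    ok[, j] <- sub %in% allowed | (sub == "N" & pmat[j] == "N")
  }
  which(rowSums(ok) == m) - 1L
}
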