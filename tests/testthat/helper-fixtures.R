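# shared fixture builders for the test suite; everything is generated in code

make_hsp <- function(query_id = "t1", subject_id = "g1", q_start = 0L,
                     q_end = 10L, s_start = 0L, s_end = 10L,
                     percent_identity = 100, bitscore = 50,
                     strand = "forward", e_value = 0) {
  tibble::tibble(
    query_id = query_id, subject_id = subject_id,
    percent_identity = percent_identity,
    align_length = as.integer(q_end - q_start),
    mismatches = 0L, gap_open = 0L,
    q_start = as.integer(q_start), q_end = as.integer(q_end),
    s_start = as.integer(s_start), s_end = as.integer(s_end),
    strand = strand, e_value = e_value, bitscore = bitscore
  )
}

write_tmp_fasta <- function(lines) {
  path <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

write_tmp_blast6 <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# independent per-coordinate best-identity oracle (naive loop over coordinates)
brute_best_identity <- function(hsps, seq_id, seq_length, side) {
  stc <- if (side == "query") "q_start" else "s_start"
  enc <- if (side == "query") "q_end" else "s_end"
  idc <- if (side == "query") "query_id" else "subject_id"
  h <- hsps[hsps[[idc]] == seq_id, , drop = FALSE]
  vapply(seq_len(seq_length) - 1L, function(pos) {
    cov <- h[[stc]] <= pos & pos < h[[enc]]
    if (any(cov)) max(h$percent_identity[cov]) / 100 else 0
  }, numeric(1))
}

# independent chain oracle: enumerate every block subset whose consecutive
# (query-ordered) members are within max_intron on the genome; best bitscore
brute_chain_score <- function(g, max_intron) {
  g <- g[order(g$q_start, g$s_start), , drop = FALSE]
  n <- nrow(g)
  best <- 0
  gap <- function(i, j) {
    max(0, max(g$s_start[i], g$s_start[j]) - min(g$s_end[i], g$s_end[j]))
  }
  for (mask in seq_len(2^n) - 1L) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (!length(idx)) next
    ok <- TRUE
    if (length(idx) > 1) {
      for (k in seq_len(length(idx) - 1)) {
        if (gap(idx[k], idx[k + 1]) > max_intron) { ok <- FALSE; break }
      }
    }
    if (ok) best <- max(best, sum(g$bitscore[idx]))
  }
  best
}
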