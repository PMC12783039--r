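#' Read a FASTA file into a sequence tibble
#'
#' Parses FASTA with [Biostrings::readBStringSet()] and returns one row per
#' record. Residues are uppercased (soft-masking is not preserved) and wrapped
#' lines are concatenated. Record ids must be unique within a file.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id`, `seq` and `desc` (the remainder of the
#'   header line after the first whitespace, `""` when absent), in file order.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1 demo", "acgt", "ACGT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) abort(paste0("malformed FASTA in ", path, ": ", conditionMessage(e)))
  )
  if (length(set) == 0) {
    abort(paste0("FASTA format error: no records in ", path))
  }
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id)) {
    dup <- unique(id[duplicated(id)])
    abort(paste0("duplicate FASTA id(s): ", paste(dup, collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs))) {
    abort("FASTA format error: record with empty sequence")
  }
  tibble(id = id, seq = unname(seqs), desc = desc)
}

#' Write a sequence tibble to FASTA
#'
#' @param seqs Tibble with columns `id`, `seq` and optionally `desc`.
#' @param path Output path.
#' @param width Line-wrap width in residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(all(c("id", "seq") %in% names(seqs)))
  desc <- if ("desc" %in% names(seqs)) seqs$desc else rep("", nrow(seqs))
  header <- ifelse(nzchar(desc), paste(seqs$id, desc), seqs$id)
  lines <- purrr::map2(header, seqs$seq, function(h, s) {
    starts <- seq(1L, nchar(s), by = width)
    c(paste0(">", h), substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

#' Read a FASTQ file (Phred+33) into a read tibble
#'
#' @param path Path to a FASTQ file.
#' @return A tibble with columns `id`, `seq`, `desc` and `quality` (a list
#'   column of integer Phred scores, one per residue).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(paste0("FASTQ file not found: ", path))
  set <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    # Biostrings emits a cosmetic note about dropped metadata columns
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  if (length(set) == 0) abort(paste0("FASTQ format error: no records in ", path))
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  qual <- as(Biostrings::quality(set), "IntegerList")
  tibble(
    id = id,
    seq = toupper(unname(as.character(set))),
    desc = desc,
    quality = unname(as.list(qual))
  )
}

#' Write a read tibble to FASTQ (Phred+33)
#'
#' @param reads Tibble with columns `id`, `seq`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "quality") %in% names(reads)))
  qline <- purrr::map_chr(reads$quality, function(q) intToUtf8(q + 33L))
  lines <- rbind(paste0("@", reads$id), reads$seq, "+", qline)
  writeLines(as.vector(lines), path)
  invisible(path)
}

# column order of the standard 12-column BLAST -outfmt 6 dialect
blast6_cols <- c(
  "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
  "qstart", "qend", "sstart", "send", "evalue", "bitscore"
)

#' Read BLAST tabular output (-outfmt 6) into a normalized HSP tibble
#'
#' Accepts only the standard 12-column dialect (`qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore`). Input
#' coordinates are 1-based inclusive; they are normalized to 0-based half-open
#' intervals with `q_start < q_end` and `s_start < s_end`. A subject interval
#' given in descending order (sstart > send) marks a reverse-strand HSP and is
#' stored ascending. Lines starting with `#` are ignored.
#'
#' @param path Path to a BLAST tabular file.
#' @return An HSP tibble with columns `query_id`, `subject_id`,
#'   `percent_identity`, `align_length`, `mismatches`, `gap_open`, `q_start`,
#'   `q_end`, `s_start`, `s_end`, `strand` (`"forward"`/`"reverse"`),
#'   `e_value`, `bitscore`.
#' @export
read_blast_tab <- function(path) {
  if (!file.exists(path)) abort(paste0("BLAST tabular file not found: ", path))
  lines <- readLines(path)
  keep <- !startsWith(trimws(lines), "#") & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(fields)
  if (any(nfield != 12L)) {
    bad <- which(nfield != 12L)[1]
    abort(paste0(
      "BLAST tabular format error at line ", lineno[bad], ": expected 12 columns, found ",
      nfield[bad]
    ))
  }
  if (length(fields) == 0) {
    return(empty_hsp_tbl())
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num_cols <- c(3:11)
  nums <- suppressWarnings(apply(m[, num_cols, drop = FALSE], 2, as.numeric))
  nums <- matrix(nums, ncol = length(num_cols))
  if (anyNA(nums)) {
    bad <- which(rowSums(is.na(nums)) > 0)[1]
    abort(paste0("BLAST tabular format error at line ", lineno[bad], ": non-numeric field"))
  }
  bitscore <- suppressWarnings(as.numeric(m[, 12]))
  if (anyNA(bitscore)) {
    bad <- which(is.na(bitscore))[1]
    abort(paste0("BLAST tabular format error at line ", lineno[bad], ": non-numeric bitscore"))
  }
  qstart <- nums[, 5]; qend <- nums[, 6]; sstart <- nums[, 7]; send <- nums[, 8]
  rev <- sstart > send
  out <- tibble(
    query_id = m[, 1],
    subject_id = m[, 2],
    percent_identity = nums[, 1],
    align_length = as.integer(nums[, 2]),
    mismatches = as.integer(nums[, 3]),
    gap_open = as.integer(nums[, 4]),
    q_start = as.integer(qstart - 1),
    q_end = as.integer(qend),
    s_start = as.integer(ifelse(rev, send - 1, sstart - 1)),
    s_end = as.integer(ifelse(rev, sstart, send)),
    strand = ifelse(rev, "reverse", "forward"),
    e_value = nums[, 9],
    bitscore = bitscore
  )
  validate_hsps(out)
  out
}

empty_hsp_tbl <- function() {
  tibble(
    query_id = character(), subject_id = character(),
    percent_identity = numeric(), align_length = integer(),
    mismatches = integer(), gap_open = integer(),
    q_start = integer(), q_end = integer(),
    s_start = integer(), s_end = integer(),
    strand = character(), e_value = numeric(), bitscore = numeric()
  )
}

validate_hsps <- function(hsps) {
  req <- c(
    "query_id", "subject_id", "percent_identity", "q_start", "q_end",
    "s_start", "s_end", "strand", "bitscore"
  )
  missing <- setdiff(req, names(hsps))
  if (length(missing)) {
    abort(paste0("HSP table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  if (nrow(hsps) == 0) return(invisible(hsps))
  if (any(hsps$q_start < 0) || any(hsps$q_start >= hsps$q_end) ||
      any(hsps$s_start < 0) || any(hsps$s_start >= hsps$s_end)) {
    abort("invalid HSP intervals: require 0 <= start < end on both sides")
  }
  if (any(hsps$percent_identity < 0 | hsps$percent_identity > 100)) {
    abort("percent_identity must lie in [0, 100]")
  }
  if (any(hsps$bitscore < 0)) abort("bitscore must be >= 0")
  if (!all(hsps$strand %in% c("forward", "reverse"))) {
    abort('strand must be "forward" or "reverse"')
  }
  invisible(hsps)
}

#' Reverse-complement a nucleotide string
#'
#' @param seq Character scalar over `{A, C, G, T, N}` (case-insensitive).
#' @return The reverse complement, uppercase.
#' @examples
#' reverse_complement("AAAC")
#' @export
reverse_complement <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1)
  s <- toupper(seq)
  if (grepl("[^ACGTN]", s)) {
    abort("reverse_complement: sequence contains non-nucleotide characters")
  }
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

#' Translate DNA in a given frame with the standard codon table
#'
#' Translation runs from `frame` to the last complete codon. Stop codons (TAA,
#' TAG, TGA) are rendered `*`; any codon containing `N` is rendered `X`.
#'
#' @param seq Nucleotide string.
#' @param frame Reading frame offset, 0, 1 or 2.
#' @return Amino-acid string of length `floor((nchar(seq) - frame) / 3)`.
#' @examples
#' translate_dna("ATGTGCTGTTAA")
#' @export
translate_dna <- function(seq, frame = 0L) {
  stopifnot(length(seq) == 1, frame %in% 0:2)
  s <- toupper(seq)
  n <- nchar(s)
  if (n - frame < 3) abort("translate_dna: sequence shorter than one codon in this frame")
  ncod <- (n - frame) %/% 3
  codons <- substring(s, frame + 1 + 3 * (seq_len(ncod) - 1), frame + 3 * seq_len(ncod))
  aa <- codon_table[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

codon_table <- local({
  bases <- c("T", "C", "A", "G")
  # standard table, third base varying fastest within each first/second pair
  aas <- strsplit(
    "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG", ""
  )[[1]]
  tbl <- character(0)
  i <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    i <- i + 1
    tbl[paste0(b1, b2, b3)] <- aas[i]
  }
  tbl
})

#' Hamming distance between two equal-length strings
#'
#' @param a,b Character scalars of equal length.
#' @return Integer count of positions at which `a` and `b` differ.
#' @examples
#' hamming_distance("GCC", "ACA")
#' @export
hamming_distance <- function(a, b) {
  stopifnot(length(a) == 1, length(b) == 1)
  if (nchar(a) != nchar(b)) abort("hamming_distance: strings differ in length")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}
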