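#' Simulate a multi-exon locus with known truth
#'
#' Builds a deterministic (seeded) genomic sequence containing a multi-exon
#' gene — by default with the very short first exons (22 and 26 bp)
#' characteristic of the metallothionein locus this toolkit was designed
#' around — plus random flanks, canonical GT...AG introns, an optional
#' intronic tandem-repeat array, and a planted open reading frame between the
#' 5' and 3' UTR portions of the transcript. Splicing the recorded exon
#' intervals out of the genome reproduces the noise-free transcript exactly.
#'
#' @param exon_lengths Exon lengths in bp, 5' to 3'.
#' @param intron_lengths Intron lengths in bp (length `length(exon_lengths) -
#'   1`); excludes any repeat array, which is inserted into the middle of
#'   intron 1 on top of its stated length.
#' @param utr_lengths 5' and 3' untranslated lengths on the transcript; the
#'   planted ORF occupies the codon-aligned span between them.
#' @param flank_lengths Unique-sequence flank lengths either side of the gene.
#' @param repeat_spec Optional repeat array description, a list as accepted by
#'   [simulate_monomer_array()] (`templates`, `copies`, `sub_rate`, ...).
#' @param gc Background GC fraction (default 0.42, the observed repeat-monomer
#'   GC of the sequenced clones).
#' @param seed Integer seed; outputs are a pure function of the arguments.
#' @return A `simulated_locus` list: `genome` (sequence tibble), `transcript`
#'   (sequence tibble of the spliced transcript), `exons` (tibble of genomic
#'   `start`/`end`), `boundaries` (sorted vector of exon edges), `orf`
#'   (transcript-coordinate `start`/`end`), `repeat_region` (genomic interval
#'   or `NULL`), `monomer_truth` (tibble or `NULL`).
#' @export
simulate_locus <- function(exon_lengths = c(22L, 26L, 150L, 250L),
                           intron_lengths = c(1500L, 400L, 400L),
                           utr_lengths = c(30L, 100L),
                           flank_lengths = c(400L, 400L),
                           repeat_spec = NULL,
                           gc = 0.42,
                           seed = 1L) {
  if (length(intron_lengths) != length(exon_lengths) - 1) {
    abort("simulate_locus: need length(intron_lengths) == length(exon_lengths) - 1")
  }
  if (any(c(exon_lengths, intron_lengths, flank_lengths) < 1)) {
    abort("simulate_locus: all lengths must be >= 1")
  }
  with_seed(seed, {
    tx_len <- sum(exon_lengths)
    transcript <- random_dna(tx_len, gc)
    orf <- plant_orf(transcript, utr_lengths[1], utr_lengths[2])
    transcript <- orf$seq

    # exon sequences re-sliced from the (ORF-bearing) transcript
    ex_end <- cumsum(exon_lengths)
    ex_start <- ex_end - exon_lengths
    exon_seqs <- substring(transcript, ex_start + 1, ex_end)

    introns <- purrr::map_chr(intron_lengths, function(L) {
      stopifnot(L >= 4)
      paste0("GT", random_dna(L - 4L, gc), "AG")
    })
    monomer_truth <- NULL
    repeat_region_local <- NULL
    if (!is.null(repeat_spec)) {
      repeat_spec$seed <- NULL           # array shares the locus RNG stream
      arr <- do.call(simulate_monomer_array, repeat_spec)
      half <- (intron_lengths[1] - 4L) %/% 2
      body <- substr(introns[1], 3, intron_lengths[1] - 2)
      introns[1] <- paste0(
        "GT", substr(body, 1, half), arr$sequence,
        substr(body, half + 1, nchar(body)), "AG"
      )
      repeat_region_local <- c(2L + half, 2L + half + nchar(arr$sequence))
      monomer_truth <- arr$monomers
    }

    pieces <- character(0)
    for (i in seq_along(exon_seqs)) {
      pieces <- c(pieces, exon_seqs[i])
      if (i < length(exon_seqs)) pieces <- c(pieces, introns[i])
    }
    gene <- paste(pieces, collapse = "")
    genome <- paste0(
      random_dna(flank_lengths[1], gc), gene, random_dna(flank_lengths[2], gc)
    )

    # genomic exon intervals
    offset <- flank_lengths[1]
    g_start <- integer(length(exon_seqs))
    g_end <- integer(length(exon_seqs))
    pos <- offset
    for (i in seq_along(exon_seqs)) {
      g_start[i] <- pos
      pos <- pos + nchar(exon_seqs[i])
      g_end[i] <- pos
      if (i < length(exon_seqs)) pos <- pos + nchar(introns[i])
    }
    repeat_region <- NULL
    if (!is.null(repeat_region_local)) {
      intron1_start <- g_end[1]
      repeat_region <- intron1_start + repeat_region_local
      monomer_truth$start <- monomer_truth$start + repeat_region[1]
      monomer_truth$end <- monomer_truth$end + repeat_region[1]
    }
    exon_tbl <- tibble(start = g_start, end = g_end)
    structure(
      list(
        genome = tibble(id = "locus", seq = genome, desc = "simulated locus"),
        transcript = tibble(id = "tx1", seq = transcript, desc = "truth transcript"),
        exons = exon_tbl,
        boundaries = equivalent_splice_boundaries(genome, exon_tbl),
        exon_boundaries = sort(c(g_start, g_end)),
        orf = c(orf$start, orf$end),
        repeat_region = repeat_region,
        monomer_truth = monomer_truth,
        seed = seed
      ),
      class = "simulated_locus"
    )
  })
}

#' All splice-equivalent exon boundary placements of an annotation
#'
#' A splice junction whose intron begins with the same bases as the
#' downstream exon (or ends with the same bases as the upstream exon) can be
#' annotated at several genomic positions that all splice to the identical
#' transcript. Without splice-site consensus information no aligner can
#' distinguish these placements, so truth evaluation must accept any of them.
#' This enumerates, for each internal junction, every shifted donor/acceptor
#' pair yielding the same transcript, plus the outer gene edges.
#'
#' @param genome_seq Genomic sequence (character scalar or one-row tibble).
#' @param exons Tibble of exon `start`/`end` (0-based half-open, ascending).
#' @param max_shift Largest junction shift considered, per direction.
#' @return Sorted integer vector of equivalent boundary positions.
#' @export
equivalent_splice_boundaries <- function(genome_seq, exons, max_shift = 25L) {
  if (is.data.frame(genome_seq)) genome_seq <- genome_seq$seq
  g <- strsplit(toupper(genome_seq), "")[[1]]
  n_ex <- nrow(exons)
  bounds <- sort(c(exons$start, exons$end))
  for (j in seq_len(n_ex - 1)) {
    don <- exons$end[j]                  # 0-based donor edge (intron start)
    acc <- exons$start[j + 1]            # acceptor edge (exon start)
    # right shifts: intron prefix equals downstream exon prefix
    d <- 0L
    while (d < max_shift && acc + d < exons$end[j + 1] &&
           g[don + d + 1] == g[acc + d + 1]) {
      d <- d + 1L
      bounds <- c(bounds, don + d, acc + d)
    }
    # left shifts: intron suffix equals upstream exon suffix
    d <- 0L
    while (d < max_shift && don - d > exons$start[j] &&
           g[acc - d] == g[don - d]) {
      d <- d + 1L
      bounds <- c(bounds, don - d, acc - d)
    }
  }
  sort(unique(bounds))
}

# plant ATG ... stop spanning the codon-aligned region between the UTRs and
# scrub premature in-frame stops
plant_orf <- function(seq, utr5, utr3) {
  n <- nchar(seq)
  cds_len <- ((n - utr5 - utr3) %/% 3) * 3
  if (cds_len < 9) abort("plant_orf: transcript too short for an ORF between the UTRs")
  start <- utr5
  end <- start + cds_len
  chars <- strsplit(seq, "")[[1]]
  chars[(start + 1):(start + 3)] <- c("A", "T", "G")
  chars[(end - 2):end] <- c("T", "A", "A")
  # internal codons: remove in-frame stops
  for (cs in seq(start + 3, end - 6, by = 3)) {
    codon <- paste(chars[(cs + 1):(cs + 3)], collapse = "")
    if (codon %in% c("TAA", "TAG", "TGA")) chars[cs + 1] <- "C"
  }
  list(seq = paste(chars, collapse = ""), start = start, end = end)
}

#' Simulate a tandem-repeat monomer array with truth labels
#'
#' Concatenates mutated copies of one or more monomer templates into a tandem
#' array. Each copy receives i.i.d. substitutions at `sub_rate`; in addition
#' the outer `junction_width` bp of each copy are hyper-mutated at
#' `junction_sub_rate`, emulating the junction decay of real satellite arrays
#' (without it, identical abutting copies self-align at constant depth and the
#' array has no troughs to split at). Copies of template `i` are emitted as a
#' block, optionally reverse-complemented via `orientation`.
#'
#' @param templates Character vector of monomer templates, or an integer
#'   (number of random templates to draw).
#' @param copies Copies per template (recycled).
#' @param sub_rate Per-base substitution rate of the monomer body.
#' @param monomer_length Template length when `templates` is a count.
#' @param junction_width Width of the hyper-mutated edge region, per side.
#' @param junction_sub_rate Substitution rate within the edge regions.
#' @param orientation `"+"`/`"-"` per template block (recycled).
#' @param gc GC fraction for random templates.
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @return List with `sequence` (the array) and `monomers` (tibble: `template`
#'   truth label, `start`, `end` local to the array, `sequence`).
#' @export
simulate_monomer_array <- function(templates = 2L, copies = 10L,
                                   sub_rate = 0.02, monomer_length = 180L,
                                   junction_width = 10L, junction_sub_rate = 0.6,
                                   orientation = "+", gc = 0.42, seed = NULL) {
  run <- function() {
    if (is.numeric(templates) && length(templates) == 1) {
      templates <- purrr::map_chr(seq_len(templates), ~ random_dna(monomer_length, gc))
    }
    nt <- length(templates)
    copies <- rep_len(copies, nt)
    orientation <- rep_len(orientation, nt)
    seqs <- character(0)
    labels <- integer(0)
    for (i in seq_len(nt)) {
      for (j in seq_len(copies[i])) {
        m <- mutate_seq(templates[i], sub_rate)
        m <- hypermutate_edges(m, junction_width, junction_sub_rate)
        if (orientation[i] == "-") m <- reverse_complement(m)
        seqs <- c(seqs, m)
        labels <- c(labels, i)
      }
    }
    ends <- cumsum(nchar(seqs))
    starts <- ends - nchar(seqs)
    list(
      sequence = paste(seqs, collapse = ""),
      monomers = tibble(
        template = labels, start = as.integer(starts), end = as.integer(ends),
        sequence = seqs
      )
    )
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate barcoded, poly-A-tailed long reads from transcripts
#'
#' Each read is `barcode + transcript + poly-A + revcomp(barcode)`, reverse-
#' complemented as a whole with probability 0.5, with i.i.d. substitutions at
#' `sub_rate` and Phred scores drawn consistently with that error rate. The
#' truth table records the planted barcode, orientation, transcript and
#' poly-A length per read.
#'
#' @param transcripts Sequence tibble of transcripts to sample from.
#' @param n_reads Number of reads.
#' @param barcodes Sequence tibble of barcodes.
#' @param sub_rate Per-base substitution rate in `[0, 0.1]`.
#' @param polya_range Two-element range of poly-A tail lengths.
#' @param seed Integer seed.
#' @return List with `reads` (read tibble with `quality`) and `truth` (tibble
#'   `read_id`, `barcode_id`, `transcript_id`, `orientation`, `polya_length`).
#' @export
simulate_reads <- function(transcripts, n_reads, barcodes, sub_rate = 0.01,
                           polya_range = c(15L, 30L), seed = 1L) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.1, n_reads >= 1)
  with_seed(seed, {
    tx_idx <- sample.int(nrow(transcripts), n_reads, replace = TRUE)
    bc_idx <- sample.int(nrow(barcodes), n_reads, replace = TRUE)
    polya <- sample(polya_range[1]:polya_range[2], n_reads, replace = TRUE)
    flip <- stats::runif(n_reads) < 0.5
    q_err <- max(sub_rate, 1e-4)
    phred <- as.integer(round(-10 * log10(q_err)))
    reads <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      bc <- barcodes$seq[bc_idx[i]]
      core <- paste0(
        bc, transcripts$seq[tx_idx[i]], strrep("A", polya[i]),
        reverse_complement(bc)
      )
      if (flip[i]) core <- reverse_complement(core)
      core <- mutate_seq(core, sub_rate)
      reads[[i]] <- tibble(
        id = sprintf("read%05d", i), seq = core, desc = "",
        quality = list(rep(phred, nchar(core)))
      )
    }
    list(
      reads = bind_rows(reads),
      truth = tibble(
        read_id = sprintf("read%05d", seq_len(n_reads)),
        barcode_id = barcodes$id[bc_idx],
        transcript_id = transcripts$id[tx_idx],
        orientation = ifelse(flip, "reverse", "forward"),
        polya_length = polya
      )
    )
  })
}

#' Generate well-separated random barcodes
#'
#' @param n Number of barcodes.
#' @param length Barcode length in bp (16 by default, the usual length of
#'   PacBio barcoding primers).
#' @param min_dist Minimum pairwise Hamming distance.
#' @param seed Integer seed.
#' @return Sequence tibble with ids `BC1..BCn`.
#' @export
simulate_barcodes <- function(n = 4L, length = 16L, min_dist = 8L, seed = 1L) {
  with_seed(seed, {
    out <- character(0)
    while (base::length(out) < n) {
      cand <- random_dna(length, 0.5)
      ok <- all(purrr::map_int(out, ~ hamming_distance(.x, cand)) >= min_dist)
      if (ok) out <- c(out, cand)
    }
    tibble(id = paste0("BC", seq_len(n)), seq = out, desc = "")
  })
}

#' Naive seed-and-extend local aligner (BLAST stand-in for fixtures)
#'
#' Exact `word_size` seeds, ungapped extension with +1/-2 scoring and X-drop,
#' per-diagonal merging of overlapping HSPs; both strands are searched.
#' Deterministic. `bitscore` is the raw ungapped score and `e_value` a
#' placeholder 0 — downstream filtering of fixture alignments must use
#' bitscore or identity.
#'
#' @param query,subject Sequences (character scalars or one-row tibbles).
#' @param word_size Exact seed length (>= 2).
#' @param min_hsp_len Minimum HSP length to report.
#' @param xdrop X-drop termination threshold for extension.
#' @param query_id,subject_id Ids used in the output when character input is
#'   given.
#' @return HSP tibble (same columns as [read_blast_tab()]), sorted by
#'   descending bitscore.
#' @export
naive_local_align <- function(query, subject, word_size = 4L, min_hsp_len = 12L,
                              xdrop = 6L, query_id = "query",
                              subject_id = "subject") {
  if (is.data.frame(query)) {
    stopifnot(nrow(query) == 1)
    query_id <- query$id
    query <- query$seq
  }
  if (is.data.frame(subject)) {
    stopifnot(nrow(subject) == 1)
    subject_id <- subject$id
    subject <- subject$seq
  }
  if (word_size < 2) abort("naive_local_align: word_size must be >= 2")
  out <- as_tibble(naive_align_cpp(
    toupper(query), toupper(subject), query_id, subject_id,
    as.integer(word_size), as.integer(min_hsp_len), as.integer(xdrop)
  ))
  out <- arrange(out, desc(.data$bitscore))
  validate_hsps(out)
  out
}

# ---- seeded randomness helpers ------------------------------------------

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n, gc = 0.5) {
  if (n == 0) return("")
  at <- (1 - gc) / 2
  paste(
    sample(c("A", "T", "G", "C"), n, replace = TRUE, prob = c(at, at, gc / 2, gc / 2)),
    collapse = ""
  )
}

mutate_seq <- function(s, rate) {
  if (rate <= 0) return(s)
  n <- nchar(s)
  hit <- which(stats::runif(n) < rate)
  if (!length(hit)) return(s)
  chars <- strsplit(s, "")[[1]]
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  }
  paste(chars, collapse = "")
}

hypermutate_edges <- function(s, width, rate) {
  if (width <= 0 || rate <= 0) return(s)
  n <- nchar(s)
  w <- min(width, n %/% 2)
  if (w == 0) return(s)
  left <- mutate_seq(substr(s, 1, w), rate)
  right <- mutate_seq(substr(s, n - w + 1, n), rate)
  paste0(left, substr(s, w + 1, n - w), right)
}
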