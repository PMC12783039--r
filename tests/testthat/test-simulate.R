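test_that("splicing truth exon intervals reproduces the transcript exactly", {
  for (s in c(1, 7, 23)) {
    loc <- simulate_locus(seed = s)
    spliced <- paste(
      substring(loc$genome$seq, loc$exons$start + 1, loc$exons$end),
      collapse = ""
    )
    expect_identical(spliced, loc$transcript$seq)
    # introns are canonical GT...AG
    introns <- substring(
      loc$genome$seq, head(loc$exons$end, -1) + 1, tail(loc$exons$start, -1)
    )
    expect_true(all(startsWith(introns, "GT") & endsWith(introns, "AG")))
    # planted ORF is a real ORF of the transcript
    cds <- substr(loc$transcript$seq, loc$orf[1] + 1, loc$orf[2])
    prot <- translate_dna(cds)
    expect_equal(substr(cds, 1, 3), "ATG")
    expect_equal(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
  }
})

test_that("generators are pure functions of their seed", {
  expect_identical(simulate_locus(seed = 9), simulate_locus(seed = 9))
  expect_false(identical(simulate_locus(seed = 9)$genome$seq,
                         simulate_locus(seed = 10)$genome$seq))
  bcs <- simulate_barcodes(seed = 2)
  expect_identical(
    simulate_reads(simulate_locus(seed = 2)$transcript, 20, bcs, seed = 4),
    simulate_reads(simulate_locus(seed = 2)$transcript, 20, bcs, seed = 4)
  )
})

test_that("a repeat array lands inside intron 1 with truth labels", {
  loc <- simulate_locus(
    repeat_spec = list(templates = 2, copies = 10), seed = 6
  )
  expect_equal(nrow(loc$monomer_truth), 20L)
  expect_equal(sort(unique(loc$monomer_truth$template)), c(1L, 2L))
  intron1 <- c(loc$exons$end[1], loc$exons$start[2])
  expect_gte(loc$repeat_region[1], intron1[1])
  expect_lte(loc$repeat_region[2], intron1[2])
  # monomer truth intervals tile the repeat region
  expect_equal(loc$monomer_truth$start[1], loc$repeat_region[1])
  expect_equal(tail(loc$monomer_truth$end, 1), loc$repeat_region[2])
  expect_equal(
    substr(loc$genome$seq, loc$monomer_truth$start[3] + 1, loc$monomer_truth$end[3]),
    loc$monomer_truth$sequence[3]
  )
})

test_that("simulated reads carry barcodes and poly-A tails as stated", {
  loc <- simulate_locus(seed = 8)
  bcs <- simulate_barcodes(n = 2, seed = 8)
  sim <- simulate_reads(loc$transcript, 40, bcs, sub_rate = 0,
                        polya_range = c(15, 30), seed = 8)
  expect_equal(nrow(sim$reads), 40L)
  fwd <- sim$truth$orientation == "forward"
  for (i in which(fwd)[1:5]) {
    bc <- bcs$seq[match(sim$truth$barcode_id[i], bcs$id)]
    s <- sim$reads$seq[i]
    expect_equal(substr(s, 1, nchar(bc)), bc)
    expect_match(s, paste0("A{", sim$truth$polya_length[i], "}",
                           reverse_complement(bc), "$"))
  }
  expect_true(all(sim$truth$polya_length >= 15 & sim$truth$polya_length <= 30))
})

test_that("the naive aligner finds exact and reverse-strand matches", {
  s <- "ACGTTGCAATGCCGTAGGAT"
  hit <- naive_local_align(s, s, min_hsp_len = 12)
  expect_equal(hit$q_start[1], 0L)
  expect_equal(hit$q_end[1], 20L)
  expect_equal(hit$percent_identity[1], 100)
  expect_equal(hit$strand[1], "forward")

  rc <- naive_local_align(reverse_complement(s), s, min_hsp_len = 12)
  expect_equal(rc$strand[1], "reverse")
  expect_equal(c(rc$s_start[1], rc$s_end[1]), c(0L, 20L))
  expect_error(naive_local_align("ACGT", "ACGT", word_size = 1), "word_size")
})

test_that("top HSP agrees with Smith-Waterman local alignment on small pairs", {
  set.seed(55)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -2)
  for (rep in 1:15) {
    subject <- tastkit:::random_dna(60)
    core_start <- sample(1:35, 1)
    core <- substr(subject, core_start, core_start + sample(18:24, 1))
    query <- paste0(
      tastkit:::random_dna(sample(0:8, 1)),
      tastkit:::mutate_seq(core, 0.04),
      tastkit:::random_dna(sample(0:8, 1))
    )
    hsps <- naive_local_align(query, subject, min_hsp_len = 12)
    if (nrow(hsps) == 0) next
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(query), Biostrings::DNAString(subject),
      type = "local", substitutionMatrix = mat,
      gapOpening = 6, gapExtension = 3
    )
    sw_start <- Biostrings::start(Biostrings::subject(pa)) - 1L
    sw_end <- Biostrings::end(Biostrings::subject(pa))
    expect_lte(abs(hsps$s_start[1] - sw_start), 2L)
    expect_lte(abs(hsps$s_end[1] - sw_end), 2L)
  }
})

test_that("equivalent splice boundaries enumerate ambiguity shifts", {
  # exon1 = ACGT | intron = GTAC..AG | exon2 = GTTT...
  # intron prefix "GT" equals exon2 prefix "GT" -> shifts 1 and 2 are valid
  genome <- paste0("ACGT", "GTACGCTCAG", "GTTTCCAA")
  exons <- tibble::tibble(start = c(0L, 14L), end = c(4L, 22L))
  b <- equivalent_splice_boundaries(genome, exons)
  expect_true(all(c(4, 5, 6, 14, 15, 16) %in% b))
  expect_false(7 %in% b)
  expect_false(17 %in% b)
})

test_that("noise-free pipeline closure recovers every exon block", {
  ok <- vapply(1:10, function(s) {
    loc <- simulate_locus(seed = s)
    hsps <- naive_local_align(loc$transcript, loc$genome)
    hsps <- hsps[hsps$bitscore >= 15, ]
    aln <- chain_transcript_alignments(hsps, loc$transcript,
                                       max_intron = 5000, min_coverage = 0.8)
    nrow(aln$transcripts) == 1 && aln$transcripts$n_blocks == 4
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})
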