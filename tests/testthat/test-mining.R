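test_that("exon mining keeps transcripts passing the bitscore threshold", {
  hsps <- dplyr::bind_rows(
    make_hsp(query_id = "exon1", subject_id = "t1", bitscore = 80),
    make_hsp(query_id = "exon1", subject_id = "t1", bitscore = 20),
    make_hsp(query_id = "exon2", subject_id = "t2", bitscore = 55)
  )
  expect_equal(mine_transcripts_by_exon(hsps, 50), c("t1", "t2"))
  expect_equal(mine_transcripts_by_exon(hsps, 500), character(0))
})

test_that("cysteine-rich ORF selection overrides longest-ORF logic", {
  # long ORF with one cysteine followed by a shorter ORF with twelve
  long_low <- paste0("ATG", "TGC", strrep("GCA", 40), "TAA")
  short_rich <- paste0("ATG", strrep("TGT", 12), "TAA")
  tx <- paste0(long_low, "CC", short_rich)
  longest <- find_orfs(tx)
  expect_equal(longest$protein[longest$is_longest], paste0("MC", strrep("A", 40)))
  best <- select_cysteine_rich_orf(tx, min_cys = 10)
  expect_equal(best$cysteine_count, 12L)
  expect_equal(best$protein, paste0("M", strrep("C", 12)))
  # fewer than min_cys -> nothing
  nine <- paste0("ATG", strrep("TGT", 9), "TAA")
  expect_equal(nrow(select_cysteine_rich_orf(nine, min_cys = 10)), 0L)
  expect_equal(select_cysteine_rich_orf(nine, min_cys = 5)$cysteine_count, 9L)
})

test_that("cysteine selection never loses to an exhaustive ORF scan", {
  set.seed(21)
  for (i in 1:15) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE,
                      prob = c(0.2, 0.2, 0.35, 0.25)), collapse = "")
    best <- select_cysteine_rich_orf(s, min_cys = 0)
    all_orfs <- find_orfs(s, all_starts = TRUE)
    if (nrow(all_orfs) == 0) {
      expect_equal(nrow(best), 0L)
    } else {
      expect_equal(best$cysteine_count, max(all_orfs$cysteine_count))
    }
  }
})

test_that("protein deduplication preserves counts and ordering", {
  cl <- dedupe_protein_clusters(tibble::tibble(
    transcript_id = c("t1", "t2", "t3"),
    protein = c("MCC", "MCC", "MCK")
  ))
  expect_equal(cl$protein, c("MCC", "MCK"))
  expect_equal(cl$count, c(2L, 1L))
  expect_equal(cl$member_ids[[1]], c("t1", "t2"))
  expect_equal(nrow(dedupe_protein_clusters(tibble::tibble(
    transcript_id = character(), protein = character()
  ))), 0L)
  many <- dedupe_protein_clusters(tibble::tibble(
    transcript_id = paste0("t", 1:7), protein = rep("MC", 7)
  ))
  expect_equal(many$count, 7L)
  # conservation of members
  set.seed(22)
  prots <- tibble::tibble(
    transcript_id = paste0("t", 1:30),
    protein = sample(c("MA", "MB", "MC", "MD"), 30, TRUE)
  )
  expect_equal(sum(dedupe_protein_clusters(prots)$count), 30L)
})

test_that("UTR clade classification takes the top passing bitscore", {
  clades <- tibble::tibble(query_id = c("utr1", "utr2"), clade = c("wMT-1", "wMT-2"))
  hsps <- dplyr::bind_rows(
    make_hsp(query_id = "utr1", subject_id = "t1", bitscore = 120),
    make_hsp(query_id = "utr1", subject_id = "t2", bitscore = 30),
    make_hsp(query_id = "utr1", subject_id = "t3", bitscore = 80),
    make_hsp(query_id = "utr2", subject_id = "t3", bitscore = 200),
    make_hsp(query_id = "utr1", subject_id = "t4", bitscore = 90),
    make_hsp(query_id = "utr2", subject_id = "t4", bitscore = 90)
  )
  res <- classify_by_utr(hsps, clades, min_bitscore = 50)
  lab <- setNames(res$clade, res$transcript_id)
  expect_equal(unname(lab["t1"]), "wMT-1")
  expect_false("t2" %in% res$transcript_id)       # below threshold
  expect_equal(unname(lab["t3"]), "wMT-2")        # higher bitscore wins
  expect_equal(unname(lab["t4"]), "unclassified") # equal-top conflict
})

test_that("tissue summary percentages and ratios behave at the edges", {
  single <- tissue_summary(tibble::tibble(
    tissue = "gut", transcripts = 10, target_count = 3
  ))
  expect_equal(single$transcripts_pct, c(100, 100))
  expect_equal(single$target_pct, c(100, 100))
  expect_equal(single$representation, c(1, 1))
  expect_error(
    tissue_summary(tibble::tibble(tissue = "x", transcripts = -1, target_count = 0)),
    "negative"
  )
  # rounding is half-away-from-zero at one decimal
  two <- tissue_summary(tibble::tibble(
    tissue = c("a", "b"), transcripts = c(125, 875), target_count = c(1, 7)
  ))
  expect_equal(two$transcripts_pct[1:2], c(12.5, 87.5))
})

test_that("splice-site consensus builds minimal IUPAC codes", {
  same <- splice_site_consensus(rep("GTAAGTTTTC", 3))
  expect_equal(same$consensus, "GTAAGTTTTC")
  expect_equal(same$mean_identity_pct, 100)

  pair <- splice_site_consensus(c("GTAAGTTTTC", "GTAAGTTTTT"))
  expect_equal(pair$consensus, "GTAAGTTTTY")
  expect_equal(pair$mean_identity_pct, 90)

  all4 <- splice_site_consensus(c("A", "C", "G", "T"))
  expect_equal(all4$consensus, "N")

  expect_error(splice_site_consensus(c("AA", "AAA")), "equal length")
  expect_error(splice_site_consensus("AAAA"), "consensus_only")
  solo <- splice_site_consensus("AAAA", consensus_only = TRUE)
  expect_equal(solo$consensus, "AAAA")
  expect_true(is.na(solo$mean_identity_pct))
})

test_that("cover-all consensus matches every input flank", {
  set.seed(23)
  flanks <- vapply(1:8, function(i) tastkit:::random_dna(10), "")
  cons <- splice_site_consensus(flanks, ambiguity_threshold = 0)$consensus
  for (f in flanks) {
    expect_equal(scan_motif(f, cons), 0L)
  }
})

test_that("motif scanning follows IUPAC semantics", {
  expect_equal(scan_motif("GGAATAAACC", "AATAAA"), 2L)
  expect_equal(scan_motif("AG", "R"), c(0L, 1L))
  expect_equal(scan_motif("CCCC", "AATAAA"), integer(0))
  expect_error(scan_motif("ACGT", "AZ"), "IUPAC")
  # reverse strand: TTTATT is the reverse complement of AATAAA
  expect_equal(scan_motif("GGTTTATTCC", "AATAAA"), integer(0))
  expect_equal(scan_motif("GGTTTATTCC", "AATAAA", both_strands = TRUE), 2L)
})
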