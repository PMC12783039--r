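test_that("chaining orders blocks and computes coverage", {
  hsps <- dplyr::bind_rows(
    make_hsp(q_start = 0, q_end = 40, s_start = 1000, s_end = 1040, bitscore = 74),
    make_hsp(q_start = 40, q_end = 100, s_start = 5000, s_end = 5060, bitscore = 110)
  )
  aln <- chain_transcript_alignments(hsps, c(t1 = 100), max_intron = 10000,
                                     min_coverage = 0.9)
  expect_equal(nrow(aln$transcripts), 1L)
  expect_equal(aln$blocks$order_index, c(0L, 1L))
  expect_equal(aln$transcripts$coverage, 1.0)
})

test_that("a long genomic gap splits the chain and the poorer side is lost", {
  hsps <- dplyr::bind_rows(
    make_hsp(q_start = 0, q_end = 40, s_start = 1000, s_end = 1040, bitscore = 74),
    make_hsp(q_start = 40, q_end = 100, s_start = 5000, s_end = 5060, bitscore = 110)
  )
  # genomic gap 3960 > 2000: surviving side covers 60/100 < 0.9 -> dropped
  aln <- chain_transcript_alignments(hsps, c(t1 = 100), max_intron = 2000,
                                     min_coverage = 0.9)
  expect_equal(nrow(aln$transcripts), 0L)
  # without the coverage filter the higher-bitscore side survives
  aln2 <- chain_transcript_alignments(hsps, c(t1 = 100), max_intron = 2000,
                                      min_coverage = 0)
  expect_equal(nrow(aln2$blocks), 1L)
  expect_equal(aln2$blocks$bitscore, 110)
})

test_that("coverage uses the union of query intervals", {
  hsps <- dplyr::bind_rows(
    make_hsp(q_start = 0, q_end = 50, s_start = 100, s_end = 150, bitscore = 50),
    make_hsp(q_start = 40, q_end = 100, s_start = 300, s_end = 360, bitscore = 60)
  )
  aln <- chain_transcript_alignments(hsps, c(t1 = 100), max_intron = 10000,
                                     min_coverage = 0, trim_query_overlaps = FALSE)
  expect_equal(aln$transcripts$coverage, 1.0)
})

test_that("junction overlap trimming leaves each transcript base aligned once", {
  hsps <- dplyr::bind_rows(
    make_hsp(q_start = 0, q_end = 50, s_start = 100, s_end = 150,
             percent_identity = 98, bitscore = 46),
    make_hsp(q_start = 44, q_end = 100, s_start = 300, s_end = 356,
             percent_identity = 100, bitscore = 56)
  )
  aln <- chain_transcript_alignments(hsps, c(t1 = 100), max_intron = 10000)
  b <- aln$blocks
  expect_equal(b$q_end[1], b$q_start[2])       # no double-aligned bases
  expect_equal(b$q_end[1], 44L)                # lower-identity block yields
  expect_equal(b$s_end[1], 144L)               # genomic edge shifts in step
})

test_that("chain errors on unknown ids and bad coverage bounds", {
  hsps <- make_hsp(query_id = "mystery")
  expect_error(
    chain_transcript_alignments(hsps, c(t1 = 100), 1000),
    "mystery"
  )
  expect_error(
    chain_transcript_alignments(make_hsp(), c(t1 = 100), 1000, min_coverage = 1.5),
    "min_coverage"
  )
})

test_that("block selection matches brute-force subset enumeration", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(1:6, 1)
    starts <- sort(sample(0:200, n))
    g <- dplyr::bind_rows(purrr::map(seq_len(n), function(i) {
      w <- sample(10:40, 1)
      make_hsp(
        q_start = starts[i], q_end = starts[i] + w,
        s_start = (s0 <- sample(0:5000, 1)), s_end = s0 + w,
        bitscore = sample(5:100, 1)
      )
    }))
    max_intron <- sample(c(100, 500, 2000), 1)
    aln <- chain_transcript_alignments(
      g, c(t1 = 500), max_intron = max_intron,
      min_coverage = 0, trim_query_overlaps = FALSE
    )
    expect_equal(sum(aln$blocks$bitscore), brute_chain_score(g, max_intron))
  }
})

test_that("chain invariants: coverage bounds, index permutation, filter monotonicity", {
  set.seed(43)
  for (rep in 1:15) {
    n_tx <- sample(1:3, 1)
    hsps <- dplyr::bind_rows(purrr::map(seq_len(n_tx), function(t) {
      k <- sample(1:5, 1)
      dplyr::bind_rows(purrr::map(seq_len(k), function(i) {
        q0 <- sample(0:180, 1); w <- sample(5:20, 1)
        make_hsp(
          query_id = paste0("t", t),
          q_start = q0, q_end = q0 + w,
          s_start = (s0 <- sample(0:3000, 1)), s_end = s0 + w,
          bitscore = sample(1:50, 1)
        )
      }))
    }))
    lens <- setNames(rep(200, n_tx), paste0("t", 1:n_tx))
    strict <- chain_transcript_alignments(hsps, lens, 1000, min_coverage = 0.3)
    loose <- chain_transcript_alignments(hsps, lens, 1000, min_coverage = 0)
    expect_gte(nrow(loose$transcripts), nrow(strict$transcripts))
    expect_true(all(loose$transcripts$coverage >= 0 & loose$transcripts$coverage <= 1))
    for (tid in loose$transcripts$transcript_id) {
      idx <- loose$blocks$order_index[loose$blocks$transcript_id == tid]
      expect_equal(sort(idx), seq_along(idx) - 1L)
    }
  }
})

test_that("collinearity runs follow the 0/+1 step rule in genomic order", {
  mk <- function(order_index, s_start) {
    b <- make_hsp(q_start = order_index * 10, q_end = order_index * 10 + 10,
                  s_start = s_start, s_end = s_start + 10)
    b$order_index <- as.integer(order_index)
    b$transcript_id <- "t1"
    b
  }
  # genomic order with indices 1,2,3,3 -> one run spanning all four
  runs <- detect_collinearity(dplyr::bind_rows(
    mk(1, 100), mk(2, 300), mk(3, 500), mk(3, 700)
  ))
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$n_blocks, 4L)
  expect_equal(c(runs$start, runs$end), c(100L, 710L))
  # 0,2,1 in genomic order: steps +2 and -1 both break the run
  runs2 <- detect_collinearity(dplyr::bind_rows(mk(0, 100), mk(2, 200), mk(1, 300)))
  expect_equal(nrow(runs2), 3L)
  expect_equal(runs2$n_blocks, rep(1L, 3))
  # a single block is trivially collinear
  runs3 <- detect_collinearity(mk(0, 50))
  expect_equal(nrow(runs3), 1L)
})

test_that("collinearity runs partition the blocks", {
  set.seed(44)
  for (rep in 1:20) {
    k <- sample(1:8, 1)
    blocks <- dplyr::bind_rows(purrr::map(seq_len(k), function(i) {
      b <- make_hsp(q_start = i * 10, q_end = i * 10 + 10,
                    s_start = (s0 <- sample(0:2000, 1)), s_end = s0 + 10)
      b$transcript_id <- "t1"
      b
    }))
    blocks$order_index <- sample(0:(k - 1))
    runs <- detect_collinearity(blocks)
    expect_equal(sum(runs$n_blocks), k)
  }
})

test_that("splice boundary error sums distances over internal edges", {
  blocks <- dplyr::bind_rows(
    make_hsp(q_start = 0, q_end = 20, s_start = 100, s_end = 120),
    make_hsp(q_start = 20, q_end = 50, s_start = 500, s_end = 530)
  )
  blocks$transcript_id <- "t1"
  expect_equal(
    splice_boundary_error(blocks, c(100, 120, 500, 530))$error, 0
  )
  # one internal edge off by one
  expect_equal(
    splice_boundary_error(blocks, c(100, 121, 500, 530))$error, 1
  )
  # two edges off by 1 and 2 -> 3
  expect_equal(
    splice_boundary_error(blocks, c(100, 121, 502, 530))$error, 3
  )
  expect_error(splice_boundary_error(blocks, integer(0)), "empty")
})
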