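self_hsp <- function(q_start, q_end, s_start, s_end, strand = "forward") {
  make_hsp(query_id = "bac", subject_id = "bac", q_start = q_start,
           q_end = q_end, s_start = s_start, s_end = s_end, strand = strand)
}

test_that("self-alignment depth excludes the identity diagonal and mirrors", {
  ident <- self_hsp(0, 100, 0, 100)
  prof <- self_alignment_depth(ident, 100)
  expect_equal(prof$depth, rep(0L, 100))

  one <- dplyr::bind_rows(ident, self_hsp(10, 20, 30, 40))
  prof1 <- self_alignment_depth(one, 100)
  expect_equal(which(prof1$depth == 1L), c(11:20, 31:40))

  mirrored <- dplyr::bind_rows(one, self_hsp(30, 40, 10, 20))
  expect_equal(self_alignment_depth(mirrored, 100)$depth, prof1$depth)

  expect_error(self_alignment_depth(self_hsp(0, 10, 90, 120), 100), "exceeds")
})

test_that("total depth equals the summed interval lengths of counted HSPs", {
  set.seed(91)
  for (rep in 1:10) {
    hsps <- dplyr::bind_rows(purrr::map(1:6, function(i) {
      a <- sample(0:80, 1); w <- sample(1:20, 1)
      b <- sample(0:80, 1)
      self_hsp(a, a + w, b, b + w)
    }))
    counted <- hsps[!(hsps$q_start == hsps$s_start & hsps$q_end == hsps$s_end), ]
    prof <- self_alignment_depth(hsps, 120)
    expect_equal(
      sum(prof$depth),
      sum(counted$q_end - counted$q_start) + sum(counted$s_end - counted$s_start)
    )
    # symmetry under (q,s) swap
    swapped <- hsps
    swapped[, c("q_start", "q_end", "s_start", "s_end")] <-
      hsps[, c("s_start", "s_end", "q_start", "q_end")]
    expect_equal(self_alignment_depth(swapped, 120)$depth, prof$depth)
  }
})

test_that("a tandem array stands out of the depth profile and splits at troughs", {
  arr <- simulate_monomer_array(templates = 1, copies = 5, sub_rate = 0, seed = 1)
  g <- tibble::tibble(
    id = "bac",
    seq = paste0(
      tastkit:::random_dna(300, 0.42), arr$sequence, tastkit:::random_dna(300, 0.42)
    ),
    desc = ""
  )
  region <- c(300L, 300L + nchar(arr$sequence))
  prof <- self_alignment_depth(naive_local_align(g, g), nchar(g$seq))
  expect_gt(
    mean(prof$depth[(region[1] + 1):region[2]]),
    mean(prof$depth[1:300]) + 2
  )
  mono <- split_monomers_at_troughs(g, region, prof)
  expect_equal(nrow(mono), 5L)
  expect_lte(abs(mean(mono$length) - 180), 25)
  # splits reconstruct the region
  expect_equal(
    paste(mono$sequence, collapse = ""),
    substr(g$seq, region[1] + 1, region[2])
  )
})

test_that("explicit breakpoints bypass trough detection", {
  g <- tibble::tibble(id = "x", seq = strrep("ACGT", 50), desc = "")
  mono <- split_monomers_at_troughs(
    g, c(0L, 200L), profile = NULL, breakpoints = c(0L, 100L, 200L)
  )
  expect_equal(mono$length, c(100L, 100L))
  prof0 <- structure(
    list(seq_id = "x", length = 200L, depth = rep(0L, 200)),
    class = "depth_profile"
  )
  expect_error(
    split_monomers_at_troughs(g, c(0L, 200L), prof0),
    "no repeat signal"
  )
})

test_that("k-mer feature matrix counts overlapping occurrences", {
  m <- kmer_feature_matrix(strrep("A", 11), k = 10)
  expect_equal(dim(m), c(1L, 1L))
  expect_equal(unname(m[1, "AAAAAAAAAA"]), 2L)
  m2 <- kmer_feature_matrix(c("ACGTACGTA", strrep("A", 11)), k = 10)
  expect_equal(unname(rowSums(m2)), c(0, 2))
  m3 <- kmer_feature_matrix(c("ACGTTGCA", "ACGTTGCA"), k = 4)
  expect_equal(m3[1, ], m3[2, ])
  expect_error(kmer_feature_matrix(character(0)), "empty")
  # row-sum contract
  set.seed(92)
  seqs <- vapply(sample(5:40, 8), function(n) tastkit:::random_dna(n), "")
  mm <- kmer_feature_matrix(seqs, k = 10)
  expect_equal(unname(rowSums(mm)), pmax(0, nchar(seqs) - 10 + 1))
})

test_that("two monomer templates are recovered as two clusters", {
  arr <- simulate_monomer_array(
    templates = 2, copies = 20, sub_rate = 0.02, junction_width = 0, seed = 1
  )
  cl <- cluster_monomers(kmer_feature_matrix(arr$monomers), min_samples = 2)
  expect_equal(cl$n_clusters, 2L)
  expect_equal(adjusted_rand_index(arr$monomers$template, cl$labels), 1.0)
  expect_true(cl$variance_captured > 0 && cl$variance_captured <= 1)
})

test_that("degenerate clustering inputs use the stated conventions", {
  ident <- kmer_feature_matrix(rep(strrep("ACGT", 30), 4), k = 10)
  cl <- cluster_monomers(ident, min_samples = 2)
  expect_equal(cl$n_clusters, 1L)
  expect_equal(cl$variance_captured, 1.0)   # zero-variance convention
  expect_error(cluster_monomers(ident, eps = -1), "eps")
  expect_error(cluster_monomers(ident[1, , drop = FALSE]), "at least 2")
})

test_that("monomer stats equal brute-force recomputation", {
  seqs <- c("ACGT", "GGCC", "AATT", tastkit:::random_dna(100, 0.3))
  st <- monomer_stats(seqs)
  expect_equal(st$min_length, min(nchar(seqs)))
  expect_equal(st$max_length, max(nchar(seqs)))
  expect_equal(st$mean_length, mean(nchar(seqs)))
  gc_brute <- mean(vapply(
    strsplit(seqs, ""), function(x) mean(x %in% c("G", "C")), 0
  ))
  expect_equal(st$mean_gc, gc_brute)
  expect_equal(monomer_stats("ACGT")$mean_gc, 0.5)
  expect_equal(monomer_stats(c("GGCC", "AATT"))$mean_gc, 0.5)
  expect_error(monomer_stats(character(0)), "empty")
})

test_that("adjusted Rand index scores partition agreement", {
  a <- rep(1:2, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  expect_equal(adjusted_rand_index(a, 3 - a), 1)   # label permutation
  expect_lt(abs(adjusted_rand_index(a, rep(c(1, 2), 10))), 0.3)
})
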