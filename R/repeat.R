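#' Self-alignment depth profile of a genomic sequence
#'
#' Builds a per-coordinate count of self-alignment coverage from the HSPs of a
#' sequence aligned against itself. The trivial full-identity diagonal (any
#' HSP whose query and subject intervals coincide) is excluded, and exact
#' (q,s)/(s,q) mirror pairs are counted once; every remaining HSP contributes
#' +1 over its query interval and +1 over its subject interval. High depth
#' marks repetitive structure; troughs within an array mark monomer
#' boundaries.
#'
#' @param hsps HSP tibble of a self-alignment (`query_id == subject_id`).
#' @param seq_length Length of the sequence in bp.
#' @return A `depth_profile` object: list with `seq_id`, `length`, and `depth`
#'   (integer vector, one entry per coordinate).
#' @export
self_alignment_depth <- function(hsps, seq_length) {
  validate_hsps(hsps)
  if (nrow(hsps) && !all(hsps$query_id == hsps$subject_id)) {
    abort("self_alignment_depth: expected a self-alignment (query_id == subject_id)")
  }
  seq_id <- if (nrow(hsps)) hsps$query_id[1] else NA_character_
  if (nrow(hsps) && (max(hsps$q_end) > seq_length || max(hsps$s_end) > seq_length)) {
    abort("self_alignment_depth: HSP exceeds seq_length")
  }
  h <- hsps
  # drop self-identity diagonals
  h <- h[!(h$q_start == h$s_start & h$q_end == h$s_end), , drop = FALSE]
  # dedupe (q,s)/(s,q) mirrors: canonical unordered interval pair + strand
  if (nrow(h)) {
    a <- pmin(h$q_start, h$s_start); a2 <- pmin(h$q_end, h$s_end)
    b <- pmax(h$q_start, h$s_start); b2 <- pmax(h$q_end, h$s_end)
    key <- paste(a, a2, b, b2, h$strand)
    h <- h[!duplicated(key), , drop = FALSE]
  }
  delta <- numeric(seq_length + 1L)
  for (i in seq_len(nrow(h))) {
    delta[h$q_start[i] + 1L] <- delta[h$q_start[i] + 1L] + 1
    delta[h$q_end[i] + 1L] <- delta[h$q_end[i] + 1L] - 1
    delta[h$s_start[i] + 1L] <- delta[h$s_start[i] + 1L] + 1
    delta[h$s_end[i] + 1L] <- delta[h$s_end[i] + 1L] - 1
  }
  structure(
    list(
      seq_id = seq_id, length = seq_length,
      depth = as.integer(cumsum(delta[seq_len(seq_length)]))
    ),
    class = "depth_profile"
  )
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(
    "<depth_profile> ", x$seq_id, ": ", x$length, " bp, max depth ",
    max(x$depth), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname self_alignment_depth
#' @param x A `depth_profile`.
#' @param ... Unused.
#' @export
tidy.depth_profile <- function(x, ...) {
  tibble(seq_id = x$seq_id, position = seq_len(x$length) - 1L, depth = x$depth)
}

#' Split a tandem-repeat region into monomers at depth troughs
#'
#' Automates the manual procedure of cutting a repeat array at the troughs of
#' its self-alignment depth: the profile is smoothed by a centred moving
#' average, and cut positions are the local minima of the smoothed profile
#' inside the region (a flat minimal plateau is cut at its centre). Only
#' genuine troughs count: a minimum qualifies when its smoothed depth falls
#' below `trough_frac` of the region's median smoothed depth, which rejects
#' the shallow dips produced by chance sub-repeats inside monomers. Explicit
#' breakpoints bypass detection and reproduce manual splits.
#'
#' @param seq Sequence tibble row (or character scalar) of the full sequence.
#' @param region Two-element vector `c(start, end)` (0-based half-open) of the
#'   repeat array.
#' @param profile `depth_profile` for the same sequence.
#' @param smoothing_window Moving-average window in bp.
#' @param trough_frac Fraction of the region's median smoothed depth below
#'   which a local minimum counts as a trough.
#' @param breakpoints Optional integer positions (0-based, within or at the
#'   edges of `region`) to cut at, bypassing trough detection.
#' @return Tibble with one monomer per row: `sequence`, `start`, `end`,
#'   `length`, `gc_content`.
#' @export
split_monomers_at_troughs <- function(seq, region, profile,
                                      smoothing_window = 25L,
                                      trough_frac = 0.5,
                                      breakpoints = NULL) {
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1)
    seq <- seq$seq
  }
  stopifnot(length(region) == 2, region[1] < region[2], region[2] <= nchar(seq))
  if (is.null(breakpoints)) {
    stopifnot(inherits(profile, "depth_profile"), profile$length == nchar(seq))
    reg_depth <- profile$depth[(region[1] + 1L):region[2]]
    if (all(reg_depth == 0)) {
      abort("split_monomers_at_troughs: no repeat signal (zero depth throughout region)")
    }
    sm <- moving_average(reg_depth, smoothing_window)
    minima <- plateau_minima(sm)
    minima <- minima[sm[minima] < trough_frac * stats::median(sm)]
    cuts <- region[1] + minima - 1L
  } else {
    cuts <- sort(unique(as.integer(breakpoints)))
    cuts <- cuts[cuts > region[1] & cuts < region[2]]
  }
  bounds <- unique(c(region[1], cuts, region[2]))
  starts <- head(bounds, -1)
  ends <- tail(bounds, -1)
  monomer_tbl(substring(seq, starts + 1L, ends), starts, ends)
}

monomer_tbl <- function(sequence, start, end) {
  gc <- stringr::str_count(sequence, "[GC]") / nchar(sequence)
  tibble(
    sequence = sequence, start = as.integer(start), end = as.integer(end),
    length = nchar(sequence), gc_content = gc
  )
}

moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  k <- rep(1 / window, window)
  as.numeric(stats::filter(c(rep(x[1], window), x, rep(x[length(x)], window)),
    k, sides = 2))[(window + 1):(window + length(x))]
}

# indices (1-based) of local minima; a minimal plateau bounded by strictly
# greater values on both sides is reported at its centre
plateau_minima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    if (i == 1 || i == k) next
    if (r$values[i] < r$values[i - 1] && r$values[i] < r$values[i + 1]) {
      out <- c(out, as.integer((starts[i] + ends[i]) %/% 2))
    }
  }
  out
}

#' Overlapping k-mer count matrix of repeat monomers
#'
#' Counts overlapping k-mers (decamers by default) in each monomer. Columns
#' are the union of k-mers observed in any monomer; monomers shorter than `k`
#' get an all-zero row. Row sums therefore equal
#' `max(0, length - k + 1)`.
#'
#' @param monomers Monomer tibble (column `sequence`) or character vector.
#' @param k K-mer length.
#' @return Integer matrix, monomers x distinct k-mers, with monomer rownames.
#' @export
kmer_feature_matrix <- function(monomers, k = 10L) {
  seqs <- if (is.data.frame(monomers)) monomers$sequence else monomers
  if (!length(seqs)) abort("kmer_feature_matrix: empty monomer list")
  stopifnot(k >= 1)
  kmer_lists <- purrr::map(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  })
  all_kmers <- sort(unique(unlist(kmer_lists)))
  mat <- matrix(0L, nrow = length(seqs), ncol = length(all_kmers),
                dimnames = list(NULL, all_kmers))
  for (i in seq_along(kmer_lists)) {
    if (!length(kmer_lists[[i]])) next
    tab <- table(kmer_lists[[i]])
    mat[i, names(tab)] <- as.integer(tab)
  }
  mat
}

#' Cluster repeat monomers by k-mer composition (PCA + DBSCAN)
#'
#' Mean-centres the k-mer count matrix (counts share units, so no unit-variance
#' scaling), projects onto the first two principal components, and clusters
#' the 2-D coordinates with DBSCAN (Euclidean distance). Noise points get
#' label -1. When `eps` is `NULL` it defaults to the maximum k-distance with
#' `k = min_samples` — the smallest radius at which every monomer is a core
#' point, so clusters are the connected components at the coarsest
#' all-core scale. (The textbook sorted-k-distance-knee heuristic is also
#' available via `eps = "knee"`, but on well-separated repeat families with
#' small `min_samples` it systematically undershoots and shatters clusters.)
#'
#' @param features K-mer count matrix from [kmer_feature_matrix()].
#' @param eps DBSCAN neighbourhood radius (> 0), or `NULL` for the k-distance
#'   knee.
#' @param min_samples Minimum neighbourhood size for a core point.
#' @param k K-mer length used to build `features` (metadata only).
#' @return A `monomer_clustering` object with `labels` (integer per monomer,
#'   -1 = noise), `pc_coordinates` (n x 2), `variance_captured` (fraction of
#'   variance in the first two PCs; 1 by convention for zero-variance input),
#'   `eps`, `min_samples`, `k`, `n_clusters`.
#' @export
cluster_monomers <- function(features, eps = NULL, min_samples = 2L, k = 10L) {
  stopifnot(is.matrix(features))
  if (nrow(features) < 2) abort("cluster_monomers: need at least 2 monomers")
  if (is.numeric(eps) && eps <= 0) abort("cluster_monomers: eps must be > 0")
  centred <- scale(features, center = TRUE, scale = FALSE)
  totvar <- sum(centred^2)
  if (totvar == 0) {
    pcs <- matrix(0, nrow = nrow(features), ncol = 2)
    varcap <- 1.0                       # zero-variance convention
  } else {
    p <- prcomp(features, center = TRUE, scale. = FALSE)
    npc <- min(2L, ncol(p$x))
    pcs <- cbind(p$x[, seq_len(npc), drop = FALSE],
                 matrix(0, nrow(features), 2 - npc))
    varcap <- sum(p$sdev[seq_len(npc)]^2) / sum(p$sdev^2)
  }
  colnames(pcs) <- c("PC1", "PC2")
  if (is.null(eps)) eps <- kdist_max_eps(pcs, min_samples)
  else if (identical(eps, "knee")) eps <- kdist_knee_eps(pcs, min_samples)
  labels <- dbscan_labels(pcs, eps = eps, min_samples = min_samples)
  structure(
    list(
      labels = labels, pc_coordinates = pcs, variance_captured = varcap,
      eps = eps, min_samples = as.integer(min_samples), k = as.integer(k),
      n_clusters = length(setdiff(unique(labels), -1L))
    ),
    class = "monomer_clustering"
  )
}

#' @export
print.monomer_clustering <- function(x, ...) {
  cat(
    "<monomer_clustering> ", length(x$labels), " monomers, ",
    x$n_clusters, " cluster(s) (+", sum(x$labels == -1L), " noise), ",
    "eps = ", format(x$eps, digits = 4),
    ", 2-PC variance captured = ", format(x$variance_captured, digits = 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' @rdname cluster_monomers
#' @param x A `monomer_clustering`.
#' @param ... Unused.
#' @export
tidy.monomer_clustering <- function(x, ...) {
  tibble(
    monomer = seq_along(x$labels),
    PC1 = x$pc_coordinates[, 1], PC2 = x$pc_coordinates[, 2],
    cluster = x$labels
  )
}

#' @rdname cluster_monomers
#' @export
glance.monomer_clustering <- function(x, ...) {
  tibble(
    n_monomers = length(x$labels), n_clusters = x$n_clusters,
    n_noise = sum(x$labels == -1L), eps = x$eps,
    min_samples = x$min_samples, k = x$k,
    variance_captured = x$variance_captured
  )
}

# classic DBSCAN on a coordinate matrix; labels 1..k, noise -1
dbscan_labels <- function(coords, eps, min_samples) {
  n <- nrow(coords)
  d <- as.matrix(dist(coords))
  neigh <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- lengths(neigh) >= min_samples
  labels <- rep(0L, n)                  # 0 = unvisited
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != 0L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(neigh[[i]], i)
    while (length(queue)) {
      j <- queue[1]; queue <- queue[-1]
      if (labels[j] == -1L) labels[j] <- cl          # border previously noise
      if (labels[j] != 0L) next
      labels[j] <- cl
      if (core[j]) queue <- union(queue, setdiff(neigh[[j]], which(labels != 0L)))
    }
  }
  labels[labels == 0L] <- -1L
  labels
}

kdistances <- function(coords, min_samples) {
  d <- as.matrix(dist(coords))
  apply(d, 1, function(r) sort(r)[min(min_samples + 1L, length(r))])
}

# smallest eps at which every point is a core point
kdist_max_eps <- function(coords, min_samples) {
  max(kdistances(coords, min_samples), .Machine$double.eps)
}

# knee of the sorted k-distance curve: point of maximum distance to the chord
kdist_knee_eps <- function(coords, min_samples) {
  kdist <- kdistances(coords, min_samples)
  y <- sort(kdist, decreasing = TRUE)
  n <- length(y)
  if (n < 3 || diff(range(y)) == 0) return(max(y[1], .Machine$double.eps))
  x <- seq_len(n)
  dx <- n - 1; dy <- y[n] - y[1]
  dist_to_chord <- abs(dy * (x - 1) - dx * (y - y[1])) / sqrt(dx^2 + dy^2)
  eps <- y[which.max(dist_to_chord)]
  max(eps, .Machine$double.eps)
}

#' Summary statistics of a monomer set
#'
#' @param monomers Monomer tibble from [split_monomers_at_troughs()] (or any
#'   tibble with `length` and `gc_content`, or a character vector of
#'   sequences).
#' @return One-row tibble: `n`, `min_length`, `max_length`, `mean_length`,
#'   `mean_length_rounded` (nearest integer), `mean_gc` and `mean_gc_pct`
#'   (whole percent).
#' @export
monomer_stats <- function(monomers) {
  if (is.character(monomers)) {
    monomers <- monomer_tbl(monomers, rep(0L, length(monomers)), nchar(monomers))
  }
  if (nrow(monomers) == 0) abort("monomer_stats: empty monomer list")
  tibble(
    n = nrow(monomers),
    min_length = min(monomers$length),
    max_length = max(monomers$length),
    mean_length = mean(monomers$length),
    mean_length_rounded = as.integer(round_half_away(mean(monomers$length), 0)),
    mean_gc = mean(monomers$gc_content),
    mean_gc_pct = round_half_away(100 * mean(monomers$gc_content), 0)
  )
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items; 1 for
#' identical partitions (up to label permutation), approximately 0 for random
#' agreement. Used to score recovery of monomer template-of-origin labels.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

round_half_away <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}
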