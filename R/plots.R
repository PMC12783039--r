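#' Greedy row packing of transcript alignments
#'
#' Packs transcripts into plot rows greedily by leftmost genomic coordinate:
#' each transcript goes to the first row whose occupied span it does not
#' overlap. Transcripts sharing a row are later drawn in distinct colours.
#'
#' @param spans Tibble with `transcript_id`, `start`, `end` (genomic span per
#'   transcript), or a `tast_alignment`.
#' @param gap Minimum horizontal gap (bp) between co-row transcripts.
#' @return The input tibble with an integer `row` column (1-based).
#' @export
pack_rows <- function(spans, gap = 0) {
  if (inherits(spans, "tast_alignment")) {
    spans <- spans$blocks |>
      group_by(transcript_id = .data$transcript_id) |>
      summarise(start = min(.data$s_start), end = max(.data$s_end), .groups = "drop")
  }
  spans <- arrange(spans, .data$start, .data$end)
  ends <- numeric(0)                     # rightmost occupied coordinate per row
  row <- integer(nrow(spans))
  for (i in seq_len(nrow(spans))) {
    fit <- which(ends + gap <= spans$start[i])
    r <- if (length(fit)) fit[1] else length(ends) + 1L
    ends[r] <- spans$end[i]
    row[i] <- r
  }
  spans$row <- row
  spans
}

#' Plot a chained transcript-to-locus alignment
#'
#' Each transcript's blocks are rectangles linked by a line; fill encodes ORF
#' class (solid highlight for the longest ORF, highlight border for minor
#' ORFs), the transcript-order index is printed above each block, and
#' collinear runs are shaded. Transcripts are packed into rows greedily and
#' co-row transcripts get distinct line colours.
#'
#' @param object A `tast_alignment` (blocks may carry an `orf_class` column).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tast_alignment <- function(object, ...) {
  if (nrow(object$blocks) == 0) abort("autoplot.tast_alignment: no alignments to plot")
  blocks <- object$blocks
  if (!"orf_class" %in% names(blocks)) blocks$orf_class <- "non_orf"
  rows <- pack_rows(object)
  blocks <- left_join(
    blocks, rows[, c("transcript_id", "row")], by = "transcript_id"
  )
  runs <- detect_collinearity(blocks) |>
    filter(.data$n_blocks > 1) |>
    left_join(rows[, c("transcript_id", "row")], by = "transcript_id")
  ggplot2::ggplot(blocks) +
    {
      if (nrow(runs)) {
        ggplot2::geom_rect(
          data = runs,
          ggplot2::aes(
            xmin = .data$start, xmax = .data$end,
            ymin = .data$row - 0.42, ymax = .data$row + 0.42
          ),
          fill = "pink", alpha = 0.5
        )
      }
    } +
    ggplot2::geom_line(
      ggplot2::aes(
        x = (.data$s_start + .data$s_end) / 2, y = .data$row,
        group = .data$transcript_id, colour = .data$transcript_id
      ),
      linewidth = 0.4
    ) +
    ggplot2::geom_rect(
      ggplot2::aes(
        xmin = .data$s_start, xmax = .data$s_end,
        ymin = .data$row - 0.25, ymax = .data$row + 0.25,
        fill = .data$orf_class,
        colour = ifelse(.data$orf_class == "minor_orf", "minor_border", .data$transcript_id)
      ),
      linewidth = 0.4
    ) +
    ggplot2::geom_text(
      ggplot2::aes(
        x = (.data$s_start + .data$s_end) / 2, y = .data$row + 0.34,
        label = .data$order_index
      ),
      size = 2.6
    ) +
    ggplot2::scale_fill_manual(
      values = c(longest_orf = "gold", minor_orf = "firebrick", non_orf = "grey60")
    ) +
    ggplot2::labs(x = "genomic coordinate (bp)", y = NULL, fill = "ORF class") +
    ggplot2::guides(colour = "none") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Render a transcript-to-locus alignment plot to a file
#'
#' @param alignments A `tast_alignment`.
#' @param out Output image path (extension selects the device, e.g. `.png`).
#' @param width,height Image size in inches.
#' @param dpi Resolution for raster output.
#' @return `out`, invisibly.
#' @export
render_tast_plot <- function(alignments, out, width = 9, height = 4, dpi = 150) {
  p <- ggplot2::autoplot(alignments)
  ggplot2::ggsave(out, p, width = width, height = height, dpi = dpi)
  invisible(out)
}

#' Plot a self-alignment depth profile with optional monomer clusters
#'
#' @param object A `depth_profile`.
#' @param monomers Optional monomer tibble (with `start`, `end`).
#' @param labels Optional cluster label per monomer (e.g. from
#'   [cluster_monomers()]); must match the monomer count.
#' @param annotations Optional tibble of feature rectangles (`start`, `end`,
#'   `label`) drawn above the depth track.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.depth_profile <- function(object, monomers = NULL, labels = NULL,
                                   annotations = NULL, ...) {
  if (!is.null(monomers) && !is.null(labels) && length(labels) != nrow(monomers)) {
    abort("autoplot.depth_profile: label/monomer count mismatch")
  }
  df <- tidy(object)
  top <- max(object$depth, 1)
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_area(
      ggplot2::aes(x = .data$position, y = .data$depth),
      fill = "firebrick", alpha = 0.7
    ) +
    ggplot2::labs(
      x = "coordinate (bp)", y = "self-alignment depth", colour = "cluster"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(monomers)) {
    m <- monomers
    m$cluster <- factor(if (is.null(labels)) rep(1L, nrow(m)) else labels)
    p <- p + ggplot2::geom_rect(
      data = m,
      ggplot2::aes(
        xmin = .data$start, xmax = .data$end,
        ymin = -0.12 * top, ymax = -0.04 * top, fill = .data$cluster
      ),
      inherit.aes = FALSE, colour = "white", linewidth = 0.2
    ) +
      ggplot2::guides(fill = ggplot2::guide_legend(title = "monomer cluster"))
  }
  if (!is.null(annotations)) {
    p <- p + ggplot2::geom_rect(
      data = annotations,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = 1.05 * top, ymax = 1.15 * top,
      fill = "steelblue", inherit.aes = FALSE
    ) +
      ggplot2::geom_text(
        data = annotations,
        ggplot2::aes(x = (.data$start + .data$end) / 2, label = .data$label),
        y = 1.2 * top, size = 2.6, inherit.aes = FALSE
      )
  }
  p
}

#' Render a repeat-architecture map to a file
#'
#' Depth curve plus per-monomer colour blocks by cluster and optional gene
#' annotations.
#'
#' @inheritParams autoplot.depth_profile
#' @param profile A `depth_profile`.
#' @param out Output image path.
#' @param width,height,dpi Image geometry.
#' @return `out`, invisibly.
#' @export
render_repeat_map <- function(profile, out, monomers = NULL, labels = NULL,
                              annotations = NULL, width = 9, height = 3.5,
                              dpi = 150) {
  p <- ggplot2::autoplot(
    profile, monomers = monomers, labels = labels, annotations = annotations
  )
  ggplot2::ggsave(out, p, width = width, height = height, dpi = dpi)
  invisible(out)
}

#' Plot a pairwise comparison of two sequences from their HSPs
#'
#' Merged alignment blocks are drawn on one lane per sequence; each unmerged
#' HSP is a connector whose width and opacity are proportional to its
#' bitscore (normalised to the maximum in the set) and whose colour encodes
#' strand. The per-coordinate best-identity curves are drawn above and below
#' the lanes, the shorter sequence gets end borders, and the scalar T = I/L
#' is printed on the figure.
#'
#' @param object An `identity_comparison` from [total_identity()].
#' @param hsps The HSP tibble the comparison was built from (query =
#'   sequence A, subject = sequence B).
#' @param exons Optional tibble of exon annotations with `seq_id`, `start`,
#'   `end` (0-based half-open; BED-style).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.identity_comparison <- function(object, hsps, exons = NULL, ...) {
  if (nrow(hsps) == 0) abort("autoplot.identity_comparison: empty HSP list")
  la <- object$track_a$length
  lb <- object$track_b$length
  y_a <- 3; y_b <- 0
  blocks_a <- merge_alignment_intervals(tibble(start = hsps$q_start, end = hsps$q_end))
  blocks_b <- merge_alignment_intervals(tibble(start = hsps$s_start, end = hsps$s_end))
  conn <- hsps |>
    mutate(
      w = .data$bitscore / max(.data$bitscore),
      xa = (.data$q_start + .data$q_end) / 2,
      xb = (.data$s_start + .data$s_end) / 2
    )
  id_a <- tidy(object$track_a) |> mutate(y = y_a + 0.35 + 0.6 * .data$best_identity)
  id_b <- tidy(object$track_b) |> mutate(y = y_b - 0.35 - 0.6 * .data$best_identity)
  short_len <- min(la, lb)
  short_y <- if (la <= lb) y_a else y_b
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = conn,
      ggplot2::aes(
        x = .data$xa, xend = .data$xb, colour = .data$strand,
        linewidth = .data$w, alpha = .data$w
      ),
      y = y_a - 0.15, yend = y_b + 0.15
    ) +
    ggplot2::geom_rect(
      data = blocks_a,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = y_a - 0.15, ymax = y_a + 0.15, fill = "firebrick"
    ) +
    ggplot2::geom_rect(
      data = blocks_b,
      ggplot2::aes(xmin = .data$start, xmax = .data$end),
      ymin = y_b - 0.15, ymax = y_b + 0.15, fill = "firebrick"
    ) +
    ggplot2::geom_line(data = id_a, ggplot2::aes(x = .data$position, y = .data$y)) +
    ggplot2::geom_line(data = id_b, ggplot2::aes(x = .data$position, y = .data$y)) +
    ggplot2::annotate(
      "segment",
      x = c(0, short_len), xend = c(0, short_len),
      y = short_y - 0.25, yend = short_y + 0.25, linewidth = 0.8
    ) +
    ggplot2::annotate(
      "text", x = max(la, lb) / 2, y = (y_a + y_b) / 2,
      label = sprintf("T = I/L = %.1f%%", 100 * object$T), fontface = "bold"
    ) +
    ggplot2::scale_colour_manual(
      values = c(forward = "red", reverse = "blue"), drop = FALSE
    ) +
    ggplot2::scale_linewidth(range = c(0.1, 1.2), guide = "none") +
    ggplot2::scale_alpha(range = c(0.15, 0.9), guide = "none") +
    ggplot2::labs(x = "coordinate (bp)", y = NULL, colour = "strand") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(exons) && nrow(exons)) {
    ex <- exons
    ex$y <- ifelse(ex$seq_id == object$track_a$seq_id, y_a, y_b)
    p <- p + ggplot2::geom_rect(
      data = ex,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = .data$y - 0.15, ymax = .data$y + 0.15),
      fill = "gold", inherit.aes = FALSE
    )
  }
  p
}

#' Render a pairwise comparison figure to a file
#'
#' @inheritParams autoplot.identity_comparison
#' @param comparison An `identity_comparison`.
#' @param out Output image path.
#' @param width,height,dpi Image geometry.
#' @return `out`, invisibly.
#' @export
render_pairwise_comparison <- function(comparison, hsps, out, exons = NULL,
                                       width = 9, height = 4, dpi = 150) {
  p <- ggplot2::autoplot(comparison, hsps = hsps, exons = exons)
  ggplot2::ggsave(out, p, width = width, height = height, dpi = dpi)
  invisible(out)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
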