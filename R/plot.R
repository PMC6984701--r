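#' Graphical genotypes of selected lines
#'
#' Draws the classic graphical-genotype figure: one panel per line, the 21
#' chromosomes as horizontal ideograms scaled to physical length, a vertical
#' tick at each cultivar-vs-line SNP, with donor-assigned ticks coloured
#' distinctly from non-donor ones. Layout is deterministic for fixed input.
#'
#' @param assignments Named list of `origin_assignment`s (one per line); an
#'   unnamed single assignment is also accepted.
#' @param genome A [genome_spec()].
#' @param path Optional output path (extension picks the device, e.g. `.png`
#'   or `.svg`); when `NULL` the ggplot object is returned without writing.
#' @param width,height Device size in inches.
#' @return The ggplot object, invisibly when written to `path`.
#' @export
plot_graphical_genotype <- function(assignments, genome, path = NULL,
                                    width = 8, height = 1.2 * 21 / 4) {
  if (nrow(genome) == 0L) stop_invalid("empty genome")
  if (inherits(assignments, "origin_assignment")) assignments <- list(assignments)
  if (is.null(names(assignments)) || any(names(assignments) == "")) {
    names(assignments) <- vapply(seq_along(assignments), function(i) {
      attr(assignments[[i]], "line_id") %||% paste0("line", i)
    }, character(1))
  }
  chrom_f <- factor(genome$chrom, levels = rev(chrom_levels()))
  ideo <- data.frame(chrom = chrom_f, length_bp = genome$length_bp)
  ticks <- do.call(rbind, lapply(names(assignments), function(nm) {
    a <- as.data.frame(assignments[[nm]])
    if (nrow(a) == 0L) return(NULL)
    data.frame(line = nm, chrom = factor(a$chrom, levels = rev(chrom_levels())),
               pos = a$pos,
               origin = if (is.null(a$origin)) "diff" else a$origin,
               stringsAsFactors = FALSE)
  }))
  p <- ggplot2::ggplot() +
    ggplot2::geom_rect(
      data = ideo,
      ggplot2::aes(xmin = 0, xmax = .data$length_bp / 1e6,
                   ymin = as.integer(.data$chrom) - 0.35,
                   ymax = as.integer(.data$chrom) + 0.35),
      fill = "grey92", colour = "grey40", linewidth = 0.2)
  if (!is.null(ticks)) {
    p <- p + ggplot2::geom_segment(
      data = ticks,
      ggplot2::aes(x = .data$pos / 1e6, xend = .data$pos / 1e6,
                   y = as.integer(.data$chrom) - 0.35,
                   yend = as.integer(.data$chrom) + 0.35,
                   colour = .data$origin),
      linewidth = 0.3) +
      ggplot2::scale_colour_manual(
        values = c(donor = "#d7301f", non_donor = "#2b8cbe", diff = "#2b8cbe"),
        name = "SNP origin")
  }
  p <- p +
    ggplot2::scale_y_continuous(breaks = seq_along(levels(chrom_f)),
                                labels = levels(chrom_f),
                                expand = ggplot2::expansion(add = 0.6)) +
    ggplot2::labs(x = "Position (Mbp)", y = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(panel.grid.minor = ggplot2::element_blank())
  if (!is.null(ticks)) p <- p + ggplot2::facet_wrap(~line)
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width,
                    height = max(height, 4) * max(1, ceiling(length(assignments) / 2)),
                    limitsize = FALSE)
    return(invisible(p))
  }
  p
}
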