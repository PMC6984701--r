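#' Write introgression blocks as BED
#'
#' Coordinates convert from the 1-based inclusive variant convention to
#' BED's 0-based half-open intervals. Optional `#` header comments carry a
#' provenance tag (e.g. a config hash or seed).
#'
#' @param blocks An `introgression_blocks` data frame.
#' @param path Output path.
#' @param header_comment Optional character vector of comment lines
#'   (written as `# ...`).
#' @return `path`, invisibly.
#' @export
write_blocks_bed <- function(blocks, path, header_comment = NULL) {
  lines <- character(0)
  if (!is.null(header_comment)) lines <- paste0("# ", header_comment)
  if (nrow(blocks) > 0L) {
    lines <- c(lines, paste(blocks$chrom, format(blocks$start - 1, scientific = FALSE, trim = TRUE),
                            format(blocks$end, scientific = FALSE, trim = TRUE),
                            blocks$donor, blocks$n_markers, sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write ground-truth donor segments as BED
#'
#' Columns: chrom, start (0-based), end, zygosity, line id.
#'
#' @param truth A [true_donor_segments()] data frame.
#' @param line_id Line label for the fifth column.
#' @param path Output path.
#' @param append Append to an existing file.
#' @return `path`, invisibly.
#' @export
write_truth_bed <- function(truth, line_id, path, append = FALSE) {
  lines <- if (nrow(truth) == 0L) character(0) else {
    paste(truth$chrom, format(truth$start - 1, scientific = FALSE, trim = TRUE),
          format(truth$end, scientific = FALSE, trim = TRUE),
          truth$zygosity, line_id, sep = "\t")
  }
  if (!append && length(lines) == 0L) file.create(path)
  else cat(paste0(lines, "\n"), file = path, sep = "", append = append)
  invisible(path)
}

#' Write / read a per-chromosome SNP count table as TSV
#'
#' Rows are the 21 chromosomes in order 1A..7A, 1B..7B, 1D..7D followed by
#' a `Total` row.
#'
#' @param counts A `chrom_counts` data frame from [count_by_chromosome()].
#' @param path File path.
#' @return `read_chrom_counts_tsv` returns a `chrom_counts` data frame.
#' @export
write_chrom_counts_tsv <- function(counts, path) {
  df <- rbind(as.data.frame(counts),
              data.frame(chrom = "Total", n_snps = attr(counts, "total")))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_chrom_counts_tsv
#' @export
read_chrom_counts_tsv <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(chrom = "character"))
  total_row <- df$chrom == "Total"
  out <- df[!total_row, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, total = if (any(total_row)) df$n_snps[total_row] else sum(out$n_snps),
            class = c("chrom_counts", "data.frame"))
}

#' Read a run configuration
#'
#' YAML key/value configuration driving the pipeline; unspecified keys fall
#' back to package defaults. All randomness derives from the single
#' `seed` entry.
#'
#' @param path YAML config path.
#' @return A named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  defaults <- default_run_config()
  merge_cfg <- function(def, got) {
    for (k in names(got)) {
      def[[k]] <- if (is.list(def[[k]]) && is.list(got[[k]])) {
        merge_cfg(def[[k]], got[[k]])
      } else got[[k]]
    }
    def
  }
  merge_cfg(defaults, cfg %||% list())
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = "intrograph_out",
    genome = list(scale_factor = 0.003, genetic_length_cm = 150,
                  sites_per_chromosome = 200),
    founders = list(recurrent = "cultivar", donor_ab = "Ldn", donor_d = "AT47",
                    recurrent_alt_fraction = 0.2, donor_alt_fraction = 0.8),
    plan = list(n_backcrosses = 2, n_selfings = 5,
                population_size = 24, n_selected = 3),
    heading = list(baseline_days = 195, noise_sd = 1,
                   qtl = list(list(chrom = "5D", pos_frac = 0.5, effect_days = -1.75))),
    observation = list(mean_depth = 20, error_rate = 0.005,
                       diploid_coverage_scale = 1),
    rule = list(min_depth = 10, min_fraction = 0.8, strict = FALSE),
    segmentation = list(max_gap_bp = NULL, min_markers = 3)
  )
}
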