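#' RNA-seq-like observation model
#'
#' Converts an individual's genotype at the panel sites into per-site
#' reference/alternate read counts. Per-site depth is Poisson with mean
#' `mean_depth * expression_weight * coverage_scale`; each read samples one
#' of the two homologs uniformly and reports the other allele with
#' probability `error_rate`. `coverage_scale` emulates per-sample platform
#' and coverage differences (e.g. a shallow legacy-platform accession can be
#' given a small scale).
#'
#' @param mean_depth Expected reads per unit expression weight.
#' @param error_rate Per-read probability of reporting the other allele
#'   (0 <= error_rate < 0.5).
#' @param coverage_scale Per-sample depth multiplier (>= 0).
#' @return An `observation_model` list.
#' @export
observation_model <- function(mean_depth = 20, error_rate = 0.005,
                              coverage_scale = 1) {
  if (mean_depth < 0) stop_invalid("mean_depth must be >= 0")
  if (error_rate < 0 || error_rate >= 0.5) stop_invalid("need 0 <= error_rate < 0.5")
  if (coverage_scale < 0) stop_invalid("coverage_scale must be >= 0")
  structure(list(mean_depth = mean_depth, error_rate = error_rate,
                 coverage_scale = coverage_scale),
            class = "observation_model")
}

new_allele_counts <- function(df, sample_id, reference) {
  rownames(df) <- NULL
  structure(df, sample_id = sample_id, reference = reference,
            class = c("allele_counts", "data.frame"))
}

#' Simulate per-site allele counts for one sample
#'
#' @param ind An `individual` defined over the panel's genome.
#' @param panel A [sample_founder_panel()] panel.
#' @param model An [observation_model()].
#' @param sample_id Sample label (defaults to the individual's id).
#' @param chromosomes Optional subset of chromosomes with read coverage;
#'   sites elsewhere get zero depth. Used to emulate samples whose reads
#'   cover only some subgenomes (a tetraploid parent has no D-genome
#'   transcripts, a diploid no A/B).
#' @param seed Optional integer seed.
#' @return An `allele_counts` data frame: `chrom`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count` over all panel sites.
#' @export
simulate_allele_counts <- function(ind, panel, model, sample_id = ind$id,
                                   chromosomes = NULL, seed = NULL) {
  local_seed(seed)
  sites <- panel$sites
  n <- nrow(sites)
  ref_count <- alt_count <- integer(n)
  covered <- if (is.null(chromosomes)) rep(TRUE, n) else sites$chrom %in% chromosomes
  e <- model$error_rate
  for (chrom in unique(sites$chrom[covered])) {
    idx <- which(sites$chrom == chrom & covered)
    hh <- ind$homologs[[chrom]]
    if (is.null(hh)) stop_invalid("individual lacks chromosome ", chrom)
    pos <- sites$pos[idx]
    a1 <- founder_allele(panel, founder_at(hh[[1L]], pos), idx)
    a2 <- founder_allele(panel, founder_at(hh[[2L]], pos), idx)
    depth <- stats::rpois(length(idx), model$mean_depth *
                            sites$expression_weight[idx] * model$coverage_scale)
    p_alt <- (ifelse(a1 == 1L, 1 - e, e) + ifelse(a2 == 1L, 1 - e, e)) / 2
    alt <- stats::rbinom(length(idx), depth, p_alt)
    alt_count[idx] <- alt
    ref_count[idx] <- depth - alt
  }
  df <- data.frame(chrom = sites$chrom, pos = sites$pos, ref = sites$ref,
                   alt = sites$alt, ref_count = ref_count, alt_count = alt_count,
                   stringsAsFactors = FALSE)
  new_allele_counts(df, sample_id, attr(panel$genome, "reference"))
}

same_sites <- function(a, b) {
  nrow(a) == nrow(b) && all(a$chrom == b$chrom) && all(a$pos == b$pos) &&
    all(a$ref == b$ref) && all(a$alt == b$alt)
}

#' Combine allele-count tables by site-wise summation
#'
#' Emulates pooling the RNA-seq read sets of the synthetic hexaploid's two
#' parents (tetraploid A/B + diploid D) into one combined sample before
#' genotype calling.
#'
#' @param tables List of `allele_counts` over the identical site panel.
#' @param combined_id Sample label for the result.
#' @return An `allele_counts` table with summed counts.
#' @export
combine_counts <- function(tables, combined_id = "combined") {
  if (length(tables) == 0L) stop_invalid("no tables to combine")
  base <- tables[[1L]]
  for (t in tables[-1L]) {
    if (!same_sites(base, t)) stop_invalid("allele-count tables are on different site panels")
    if (!identical(attr(base, "reference"), attr(t, "reference"))) {
      stop_invalid("allele-count tables use different references")
    }
  }
  out <- as.data.frame(base)
  for (t in tables[-1L]) {
    out$ref_count <- out$ref_count + t$ref_count
    out$alt_count <- out$alt_count + t$alt_count
  }
  new_allele_counts(out, combined_id, attr(base, "reference"))
}

#' Write / read allele counts as TSV
#'
#' Column layout: `sample`, `chrom`, `pos` (1-based), `ref`, `alt`,
#' `ref_count`, `alt_count`.
#'
#' @param counts An `allele_counts` table.
#' @param path File path.
#' @return `read_counts_tsv` returns an `allele_counts` table;
#'   `write_counts_tsv_counts` returns `path` invisibly.
#' @export
write_allele_counts_tsv <- function(counts, path) {
  df <- data.frame(sample = attr(counts, "sample_id"), as.data.frame(counts),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param reference Reference label to attach on read (default "CS").
#' @rdname write_allele_counts_tsv
#' @export
read_allele_counts_tsv <- function(path, reference = "CS") {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c(sample = "character", chrom = "character",
                                         ref = "character", alt = "character"))
  need <- c("sample", "chrom", "pos", "ref", "alt", "ref_count", "alt_count")
  if (!all(need %in% names(df))) {
    stop_invalid("counts TSV must have columns: ", paste(need, collapse = ", "))
  }
  if (any(df$ref_count < 0) || any(df$alt_count < 0)) {
    stop_invalid("negative read counts in ", path)
  }
  sid <- unique(df$sample)
  if (length(sid) != 1L) stop_invalid("counts TSV must contain exactly one sample")
  new_allele_counts(df[, need[-1L]], sid, reference)
}

#' @export
print.allele_counts <- function(x, ...) {
  cat(sprintf("allele_counts for '%s' (%d sites, median depth %g)\n",
              attr(x, "sample_id"), nrow(x),
              stats::median(x$ref_count + x$alt_count)))
  print.data.frame(utils::head(as.data.frame(x), 4))
  invisible(x)
}
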