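#' Difference the SNP calls of a selected line against its cultivar
#'
#' Membership rule: a site enters the difference set exactly when both
#' samples are callable there (no `no_call`) and their called alleles
#' differ. Requiring callability in both samples prevents coverage dropouts
#' in either sample from masquerading as polymorphism.
#'
#' @param line,cultivar `call_set`s over the same site panel and reference.
#' @return A `diff_set` data frame: `chrom`, `pos`, `ref`, `alt`,
#'   `line_allele`, `cultivar_allele`; attributes `line_id`, `cultivar_id`.
#' @export
diff_snps <- function(line, cultivar) {
  if (!identical(attr(line, "reference"), attr(cultivar, "reference"))) {
    stop_invalid("call sets were made against different references")
  }
  if (!same_sites(line, cultivar)) {
    stop_invalid("call sets cover different site panels")
  }
  called_allele <- function(cs) ifelse(cs$call == "alternate", cs$alt, cs$ref)
  keep <- line$call != "no_call" & cultivar$call != "no_call" &
    line$call != cultivar$call
  df <- data.frame(chrom = line$chrom[keep], pos = line$pos[keep],
                   ref = line$ref[keep], alt = line$alt[keep],
                   line_allele = called_allele(line)[keep],
                   cultivar_allele = called_allele(cultivar)[keep],
                   stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, line_id = attr(line, "sample_id"),
            cultivar_id = attr(cultivar, "sample_id"),
            reference = attr(line, "reference"),
            class = c("diff_set", "data.frame"))
}

#' Build the synthetic-donor SNP set from its two parents' read counts
#'
#' Pools the tetraploid (A/B) and diploid (D) parents' allele counts into
#' one combined sample — the in-silico synthetic hexaploid — then calls
#' genotypes under `rule` and keeps the alternate calls. On chromosomes
#' covered by only one parent, the combined call reduces to that parent's
#' own call.
#'
#' @param tetraploid_counts,diploid_counts `allele_counts` of the two donor
#'   parents on the shared panel.
#' @param rule A [call_rule()].
#' @param donor_id Label for the combined donor sample.
#' @return A `snp_set` of the synthetic donor relative to the reference.
#' @export
build_donor_snpset <- function(tetraploid_counts, diploid_counts,
                               rule = call_rule(),
                               donor_id = paste(attr(tetraploid_counts, "sample_id"),
                                                attr(diploid_counts, "sample_id"),
                                                sep = "/")) {
  combined <- combine_counts(list(tetraploid_counts, diploid_counts), donor_id)
  snps_vs_reference(call_genotypes(combined, rule))
}

#' Assign cultivar-vs-line SNPs to the synthetic donor
#'
#' A difference-set member is labelled `donor` exactly when the line's
#' called allele matches the donor SNP set at that site — i.e. the line
#' carries the synthetic parent's variant. The match is allele-exact: the
#' line merely differing from both cultivar and reference is not enough.
#'
#' @param diff A [diff_snps()] result.
#' @param donor A `snp_set` for the synthetic donor.
#' @return An `origin_assignment`: the diff set plus an `origin` column
#'   (`donor` / `non_donor`).
#' @export
assign_origin <- function(diff, donor) {
  if (!identical(attr(diff, "reference"), attr(donor, "reference"))) {
    stop_invalid("diff set and donor SNP set use different references")
  }
  m <- match(site_key(diff$chrom, diff$pos), site_key(donor$chrom, donor$pos))
  is_donor <- !is.na(m) & diff$line_allele == donor$allele[ifelse(is.na(m), 1L, m)]
  out <- as.data.frame(diff)
  out$origin <- c("non_donor", "donor")[as.integer(is_donor) + 1L]
  rownames(out) <- NULL
  structure(out, line_id = attr(diff, "line_id"),
            cultivar_id = attr(diff, "cultivar_id"),
            donor_id = attr(donor, "sample_id"),
            reference = attr(diff, "reference"),
            class = c("origin_assignment", "data.frame"))
}

#' Per-chromosome SNP counts
#'
#' Tallies difference-set members per chromosome in the fixed order
#' 1A..7A, 1B..7B, 1D..7D, optionally restricted to donor-assigned members.
#'
#' @param assignment An `origin_assignment` (or `diff_set`; then
#'   `donor_only` must be FALSE).
#' @param genome A [genome_spec()].
#' @param donor_only Count only members with `origin == "donor"`.
#' @return A `chrom_counts` data frame `chrom`, `n_snps` with a `total`
#'   attribute equal to the column sum.
#' @export
count_by_chromosome <- function(assignment, genome, donor_only = FALSE) {
  df <- as.data.frame(assignment)
  if (donor_only) {
    if (is.null(df$origin)) stop_invalid("donor_only requires an origin_assignment")
    df <- df[df$origin == "donor", , drop = FALSE]
  }
  unknown <- setdiff(unique(df$chrom), genome$chrom)
  if (length(unknown) > 0L) {
    stop_invalid("SNPs on chromosomes absent from the genome: ",
                 paste(unknown, collapse = ", "))
  }
  n <- vapply(genome$chrom, function(ch) sum(df$chrom == ch), 0L)
  out <- data.frame(chrom = genome$chrom, n_snps = as.integer(n),
                    stringsAsFactors = FALSE)
  structure(out, total = sum(n), class = c("chrom_counts", "data.frame"))
}

#' Segmentation parameters for introgression blocks
#'
#' @param max_gap_bp Maximum base-pair gap between consecutive donor-origin
#'   markers within one block. `NULL` (default) uses 5% of each chromosome's
#'   length, which adapts the gap tolerance to the sparse, unevenly spaced
#'   markers that transcriptome genotyping yields.
#' @param min_markers Minimum markers supporting a block (default 3).
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(max_gap_bp = NULL, min_markers = 3) {
  if (!is.null(max_gap_bp) && max_gap_bp <= 0) stop_invalid("max_gap_bp must be > 0")
  if (min_markers < 1) stop_invalid("min_markers must be >= 1")
  structure(list(max_gap_bp = max_gap_bp, min_markers = as.integer(min_markers)),
            class = "segmentation_params")
}

#' Segment donor-origin markers into introgression blocks
#'
#' Per chromosome, donor-assigned markers sorted by position are chained
#' greedily: a new marker joins the current chain while its gap to the
#' previous marker is at most `max_gap_bp`, otherwise a new chain starts.
#' Chains with at least `min_markers` markers become blocks spanning their
#' first to last marker. For gap-constrained chaining this greedy rule
#' yields the unique partition into the fewest chains, so it coincides with
#' exhaustive-search segmentation.
#'
#' @param assignment An `origin_assignment`.
#' @param params A [segmentation_params()].
#' @param genome A [genome_spec()].
#' @return An `introgression_blocks` data frame: `chrom`, `start`, `end`,
#'   `n_markers`, `donor` — sorted, non-overlapping within a chromosome.
#' @export
segment_blocks <- function(assignment, params = segmentation_params(),
                           genome = NULL) {
  donor_id <- attr(assignment, "donor_id") %||% "donor"
  df <- as.data.frame(assignment)
  df <- df[df$origin == "donor", , drop = FALSE]
  if (is.null(params$max_gap_bp) && is.null(genome)) {
    stop_invalid("default max_gap_bp (5% of chromosome length) needs a genome")
  }
  out <- lapply(unique(df$chrom), function(ch) {
    pos <- sort(df$pos[df$chrom == ch])
    gap <- params$max_gap_bp %||% (0.05 * chrom_length(genome, ch))
    chain <- cumsum(c(1, diff(pos) > gap))
    starts <- tapply(pos, chain, min)
    ends <- tapply(pos, chain, max)
    nm <- tapply(pos, chain, length)
    keep <- nm >= params$min_markers
    if (!any(keep)) return(NULL)
    data.frame(chrom = ch, start = as.numeric(starts[keep]),
               end = as.numeric(ends[keep]), n_markers = as.integer(nm[keep]),
               donor = donor_id, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_markers = integer(), donor = character())
  }
  ord <- order(match(out$chrom, chrom_levels()), out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("introgression_blocks", "data.frame")
  out
}

#' Score detected blocks against ground-truth donor segments
#'
#' Base-pair overlap metrics between truth intervals and detected blocks:
#' `precision_bp` (overlap / detected bp), `recall_bp` (overlap / truth bp),
#' `jaccard` (overlap / union) and `breakpoint_error_bp`, the mean absolute
#' coordinate error over the start/end of each detected block matched to the
#' truth segment it overlaps most.
#'
#' @param truth Data frame `chrom`, `start`, `end` of true donor segments
#'   (e.g. [true_donor_segments()], any zygosity filtering already applied).
#' @param blocks An `introgression_blocks` data frame.
#' @return Named list of the four metrics. Undefined ratios (empty truth or
#'   empty detection) are `NA`, except `jaccard = 1` when both are empty.
#' @export
evaluate_recovery <- function(truth, blocks) {
  ir <- function(df, ch) {
    d <- df[df$chrom == ch, , drop = FALSE]
    IRanges::reduce(IRanges::IRanges(start = d$start, end = d$end))
  }
  chroms <- union(unique(truth$chrom), unique(blocks$chrom))
  ov <- tr <- bl <- un <- 0
  bp_err <- numeric(0)
  for (ch in chroms) {
    t_ir <- ir(truth, ch); b_ir <- ir(blocks, ch)
    ov <- ov + sum(IRanges::width(IRanges::intersect(t_ir, b_ir)))
    tr <- tr + sum(IRanges::width(t_ir))
    bl <- bl + sum(IRanges::width(b_ir))
    un <- un + sum(IRanges::width(IRanges::union(t_ir, b_ir)))
    if (length(t_ir) > 0 && length(b_ir) > 0) {
      hits <- IRanges::findOverlaps(b_ir, t_ir)
      if (length(hits) > 0) {
        ovw <- IRanges::width(IRanges::pintersect(
          b_ir[S4Vectors::queryHits(hits)], t_ir[S4Vectors::subjectHits(hits)]))
        best <- tapply(seq_along(ovw), S4Vectors::queryHits(hits),
                       function(i) i[which.max(ovw[i])])
        q <- S4Vectors::queryHits(hits)[best]; s <- S4Vectors::subjectHits(hits)[best]
        bp_err <- c(bp_err,
                    abs(IRanges::start(b_ir[q]) - IRanges::start(t_ir[s])),
                    abs(IRanges::end(b_ir[q]) - IRanges::end(t_ir[s])))
      }
    }
  }
  list(precision_bp = if (bl > 0) ov / bl else NA_real_,
       recall_bp = if (tr > 0) ov / tr else NA_real_,
       jaccard = if (un > 0) ov / un else 1,
       breakpoint_error_bp = if (length(bp_err) > 0) mean(bp_err) else NA_real_)
}
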