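#' Depth/allele-fraction genotype-calling rule
#'
#' The transcriptome genotyping rule: a site is callable only when read depth
#' is at least `min_depth` (default 10); a variant (alternate) genotype is
#' called when at least `min_fraction` (default 0.80, ties included) of the
#' aligned reads carry the non-reference allele. Callable sites below the
#' fraction threshold are reported as reference. With `strict = TRUE`,
#' callable sites with an intermediate alternate fraction in
#' `(1 - min_fraction, min_fraction)` are set to `no_call` instead — useful
#' when the substrate is expected to be fully inbred and intermediate
#' fractions signal artefacts.
#'
#' @param min_depth Minimum read depth for any call (>= 1).
#' @param min_fraction Minimum alternate-read fraction for an alternate call.
#' @param strict Treat intermediate-fraction sites as `no_call`.
#' @return A `call_rule` list.
#' @export
call_rule <- function(min_depth = 10, min_fraction = 0.80, strict = FALSE) {
  if (min_depth < 1) stop_invalid("min_depth must be >= 1")
  if (min_fraction <= 0 || min_fraction > 1) stop_invalid("need 0 < min_fraction <= 1")
  structure(list(min_depth = as.integer(min_depth), min_fraction = min_fraction,
                 strict = isTRUE(strict)),
            class = "call_rule")
}

new_call_set <- function(df, sample_id, reference, rule) {
  rownames(df) <- NULL
  structure(df, sample_id = sample_id, reference = reference, rule = rule,
            class = c("call_set", "data.frame"))
}

#' Call genotypes from allele counts
#'
#' Applies the depth/fraction rule site by site: depth below `min_depth`
#' gives `no_call`; otherwise `alternate` when the alternate-read fraction
#' meets `min_fraction`, else `reference` (or `no_call` for intermediate
#' fractions in strict mode).
#'
#' @param counts An `allele_counts` table.
#' @param rule A [call_rule()].
#' @return A `call_set` data frame: `chrom`, `pos`, `ref`, `alt`,
#'   `ref_count`, `alt_count`, `depth`, `alt_fraction`, `call`.
#' @examples
#' # depth 10 with 8 alternate reads is exactly at both thresholds -> alternate
#' @export
call_genotypes <- function(counts, rule = call_rule()) {
  if (any(counts$ref_count < 0) || any(counts$alt_count < 0)) {
    stop_invalid("negative read counts")
  }
  depth <- counts$ref_count + counts$alt_count
  frac <- ifelse(depth > 0, counts$alt_count / depth, NA_real_)
  call <- rep("reference", length(depth))
  call[which(frac >= rule$min_fraction)] <- "alternate"
  if (rule$strict) {
    call[which(frac > 1 - rule$min_fraction & frac < rule$min_fraction)] <- "no_call"
  }
  call[depth < rule$min_depth] <- "no_call"
  df <- data.frame(chrom = counts$chrom, pos = counts$pos, ref = counts$ref,
                   alt = counts$alt, ref_count = counts$ref_count,
                   alt_count = counts$alt_count, depth = depth,
                   alt_fraction = frac, call = call, stringsAsFactors = FALSE)
  new_call_set(df, attr(counts, "sample_id"), attr(counts, "reference"), rule)
}

#' SNPs of a sample relative to the reference
#'
#' @param calls A `call_set`.
#' @return A `snp_set` data frame `chrom`, `pos`, `allele` (the alternate
#'   base carried by the sample) with the sample id as attribute.
#' @export
snps_vs_reference <- function(calls) {
  keep <- calls$call == "alternate"
  df <- data.frame(chrom = calls$chrom[keep], pos = calls$pos[keep],
                   allele = calls$alt[keep], stringsAsFactors = FALSE)
  rownames(df) <- NULL
  structure(df, sample_id = attr(calls, "sample_id"),
            reference = attr(calls, "reference"),
            class = c("snp_set", "data.frame"))
}

#' @export
print.call_set <- function(x, ...) {
  cat(sprintf("call_set for '%s': %d sites (%d alternate, %d no_call)\n",
              attr(x, "sample_id"), nrow(x), sum(x$call == "alternate"),
              sum(x$call == "no_call")))
  invisible(x)
}

# ---- VCF interchange -------------------------------------------------------

#' Write a call set as a single-sample VCF
#'
#' Emits VCF 4.2 with GT:DP:AD genotype fields (`0/0` reference, `1/1`
#' alternate, `./.` no call) so the depth/fraction rule can be re-applied on
#' read-back.
#'
#' @param calls A `call_set`.
#' @param path Output path (plain text).
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  sid <- attr(calls, "sample_id") %||% "sample"
  gt <- c(reference = "0/0", alternate = "1/1", no_call = "./.")[calls$call]
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##reference=%s", attr(calls, "reference") %||% "unknown"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths (ref,alt)\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sid), collapse = "\t")
  )
  body <- if (nrow(calls) == 0L) character(0) else {
    paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".", "PASS", ".",
          "GT:DP:AD",
          sprintf("%s:%d:%d,%d", gt, calls$depth, calls$ref_count, calls$alt_count),
          sep = "\t")
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a single-sample VCF into a call set
#'
#' Uses vcfR for parsing. Records must carry GT, DP and AD genotype fields;
#' multi-allelic records are skipped with a warning. Calls are taken from GT
#' (`0/0` reference, `1/1` alternate, anything with `.` no_call); depth and
#' allele depths come from DP/AD.
#'
#' @param path VCF path (plain or bgzipped).
#' @param reference Reference label if the header lacks a `##reference` line.
#' @return A `call_set`.
#' @export
read_calls_vcf <- function(path, reference = NULL) {
  lines <- readLines(path)
  data_lines <- which(!startsWith(lines, "#"))
  bad <- data_lines[vapply(strsplit(lines[data_lines], "\t", fixed = TRUE),
                           length, 0L) < 10L]
  if (length(bad) > 0L) {
    stop_invalid("malformed VCF record at line ", bad[1L], " of ", path)
  }
  col_line <- lines[startsWith(lines, "#CHROM")]
  if (length(col_line) != 1L) stop_invalid("VCF without a #CHROM header line: ", path)
  ref_line <- grep("^##reference=", lines, value = TRUE)
  if (is.null(reference) && length(ref_line) == 1L) {
    reference <- sub("^##reference=", "", ref_line)
  }
  sid <- utils::tail(strsplit(col_line, "\t", fixed = TRUE)[[1L]], 1L)

  empty <- function() new_call_set(
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), ref_count = integer(), alt_count = integer(),
               depth = integer(), alt_fraction = numeric(), call = character()),
    sid, reference, NULL)
  if (length(data_lines) == 0L) return(empty())

  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped in ", path)
  }
  keep <- !multi
  if (!any(keep)) return(empty())
  gt <- vcfR::extract.gt(v, element = "GT")[keep, 1L]
  dp <- suppressWarnings(as.integer(vcfR::extract.gt(v, element = "DP")[keep, 1L]))
  ad <- vcfR::extract.gt(v, element = "AD")[keep, 1L]
  ad_mat <- do.call(rbind, lapply(strsplit(ad, ",", fixed = TRUE), function(x) {
    suppressWarnings(as.integer(x[1:2]))
  }))
  call <- ifelse(is.na(gt) | grepl(".", gt, fixed = TRUE), "no_call",
                 ifelse(gt %in% c("1/1", "1|1"), "alternate", "reference"))
  depth <- ifelse(is.na(dp), ad_mat[, 1L] + ad_mat[, 2L], dp)
  df <- data.frame(chrom = fix$CHROM[keep], pos = as.integer(fix$POS[keep]),
                   ref = fix$REF[keep], alt = fix$ALT[keep],
                   ref_count = ad_mat[, 1L], alt_count = ad_mat[, 2L],
                   depth = as.integer(depth),
                   alt_fraction = ifelse(depth > 0, ad_mat[, 2L] / depth, NA_real_),
                   call = call, stringsAsFactors = FALSE)
  new_call_set(df, sid, reference, NULL)
}
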