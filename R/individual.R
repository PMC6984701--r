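#' Individuals as founder-origin chromosome mosaics
#'
#' An `individual` stores, for each of the 21 chromosomes, two homologs, each
#' a list of contiguous segments `(start, end, founder)` tiling
#' `[1, length_bp]` with no gaps or overlaps. This mosaic is the simulation's
#' ground truth: every base of every homolog knows which founder it descends
#' from, so introgression detection can be scored exactly.
#'
#' @name individual
NULL

new_homolog <- function(start, end, founder) {
  list(start = as.numeric(start), end = as.numeric(end),
       founder = as.character(founder))
}

new_individual <- function(id, homologs, generation = NA_character_) {
  structure(list(id = id, generation = generation, homologs = homologs),
            class = "individual")
}

#' Construct a homozygous founder individual
#'
#' @param genome A [genome_spec()].
#' @param founder Either a single founder label, or a named character vector
#'   keyed by subgenome (`A`, `B`, `D`) — the latter builds a synthetic
#'   hexaploid carrying, e.g., Ldn on A/B and an *Ae. tauschii* accession on D.
#' @param id Individual label.
#' @param generation Generation tag (e.g. "P0").
#' @return An `individual`, homozygous everywhere.
#' @examples
#' g <- make_default_genome(0.003)
#' donor <- founder_individual(g, c(A = "Ldn", B = "Ldn", D = "AT47"), "Ldn/AT47")
#' @export
founder_individual <- function(genome, founder, id = paste(unique(founder), collapse = "/"),
                               generation = "P0") {
  homologs <- lapply(seq_len(nrow(genome)), function(i) {
    f <- if (length(founder) == 1L && is.null(names(founder))) founder
         else founder[[genome$subgenome[i]]]
    h <- new_homolog(1, genome$length_bp[i], f)
    list(h, h)
  })
  names(homologs) <- genome$chrom
  new_individual(id, homologs, generation)
}

validate_individual <- function(ind, genome) {
  for (i in seq_len(nrow(genome))) {
    chrom <- genome$chrom[i]
    for (h in ind$homologs[[chrom]]) {
      if (h$start[1] != 1 || h$end[length(h$end)] != genome$length_bp[i] ||
          (length(h$start) > 1L && any(h$start[-1L] != h$end[-length(h$end)] + 1))) {
        stop_invalid("homolog of ", chrom, " in '", ind$id,
                     "' does not tile [1, chromosome length]")
      }
    }
  }
  invisible(ind)
}

# Founder label of a homolog at positions `pos` (vectorised).
founder_at <- function(homolog, pos) {
  homolog$founder[findInterval(pos, homolog$start)]
}

#' Segments of an individual as a data frame
#'
#' @param ind An `individual`.
#' @return Data frame with columns `chrom`, `homolog` (1/2), `start`, `end`,
#'   `founder`.
#' @export
individual_segments <- function(ind) {
  out <- lapply(names(ind$homologs), function(chrom) {
    do.call(rbind, lapply(1:2, function(k) {
      h <- ind$homologs[[chrom]][[k]]
      data.frame(chrom = chrom, homolog = k, start = h$start, end = h$end,
                 founder = h$founder, stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Ground-truth donor-origin segments of an individual
#'
#' Projects the two homologs' donor-labelled segments onto the chromosome and
#' reports maximal intervals of constant zygosity: `het` where exactly one
#' homolog is donor-derived, `hom` where both are. Intervals are sorted and
#' non-overlapping.
#'
#' @param ind An `individual`.
#' @param donor_founders Character vector of founder labels counted as donor
#'   (typically the tetraploid and diploid parents of the synthetic).
#' @return Data frame `chrom`, `start`, `end`, `zygosity`.
#' @export
true_donor_segments <- function(ind, donor_founders) {
  out <- lapply(names(ind$homologs), function(chrom) {
    hh <- ind$homologs[[chrom]]
    # homologs tile the chromosome, so donor ploidy is piecewise constant
    # between the pooled segment starts: sweep the boundaries directly
    bounds <- sort(unique(c(hh[[1L]]$start, hh[[2L]]$start)))
    ends <- c(bounds[-1L] - 1, hh[[1L]]$end[length(hh[[1L]]$end)])
    ploidy <- (founder_at(hh[[1L]], bounds) %in% donor_founders) +
      (founder_at(hh[[2L]], bounds) %in% donor_founders)
    m <- merge_runs(bounds, ends, as.character(ploidy))
    keep <- m$founder != "0"
    if (!any(keep)) return(NULL)
    data.frame(chrom = chrom, start = m$start[keep], end = m$end[keep],
               zygosity = c("het", "hom")[as.integer(m$founder[keep])],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      zygosity = character())
  }
  rownames(out) <- NULL
  out
}

#' Fraction of an individual's genome derived from donor founders
#'
#' Donor base pairs over total base pairs, counting each homolog separately
#' (a heterozygous donor segment contributes half its length).
#'
#' @inheritParams true_donor_segments
#' @param genome A [genome_spec()].
#' @return A proportion in [0, 1].
#' @export
donor_genome_fraction <- function(ind, donor_founders, genome) {
  donor_bp <- 0
  for (chrom in names(ind$homologs)) {
    for (h in ind$homologs[[chrom]]) {
      keep <- h$founder %in% donor_founders
      donor_bp <- donor_bp + sum(h$end[keep] - h$start[keep] + 1)
    }
  }
  donor_bp / (2 * sum(genome$length_bp))
}

#' @export
print.individual <- function(x, ...) {
  nseg <- sum(vapply(x$homologs, function(hh) length(hh[[1]]$start) + length(hh[[2]]$start), 0))
  cat(sprintf("individual '%s' (%s): %d chromosomes, %d segments\n",
              x$id, x$generation, length(x$homologs), nseg))
  invisible(x)
}
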