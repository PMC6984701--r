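#' Genome specification for an allohexaploid (AABBDD) wheat-like genome
#'
#' A `genome_spec` is a data frame with one row per chromosome and columns
#' `chrom` (1A..7D), `subgenome` (A/B/D), `length_bp` (physical length) and
#' `length_cm` (genetic length). The reference cultivar name (default the
#' Chinese Spring reference, "CS") is kept as an attribute.
#'
#' @param chrom Character vector of the 21 chromosome names (1A..7D).
#' @param length_bp Positive physical lengths in base pairs.
#' @param length_cm Positive genetic lengths in centimorgans.
#' @param reference Label of the reference genome the panel is called against.
#' @return A `genome_spec` data frame.
#' @export
genome_spec <- function(chrom, length_bp, length_cm, reference = "CS") {
  chrom <- as.character(chrom)
  if (length(chrom) != 21L || anyDuplicated(chrom) ||
      !setequal(chrom, chrom_levels())) {
    stop_invalid("a genome_spec needs exactly the 21 chromosomes 1A..7D")
  }
  if (length(length_bp) != 21L || any(!is.finite(length_bp)) || any(length_bp <= 0)) {
    stop_invalid("physical lengths must be positive for all 21 chromosomes")
  }
  if (length(length_cm) != 21L || any(!is.finite(length_cm)) || any(length_cm < 0)) {
    stop_invalid("genetic lengths must be non-negative for all 21 chromosomes")
  }
  ord <- match(chrom_levels(), chrom)
  g <- data.frame(
    chrom = chrom[ord],
    subgenome = subgenome_of(chrom[ord]),
    length_bp = round(length_bp[ord]),
    length_cm = length_cm[ord],
    stringsAsFactors = FALSE
  )
  attr(g, "reference") <- reference
  class(g) <- c("genome_spec", "data.frame")
  g
}

# Relative physical sizes (Mb) of the 21 bread-wheat chromosomes in the
# Chinese Spring assembly, used as the built-in proportionality table.
.cs_chrom_mb <- c(
  `1A` = 594, `2A` = 781, `3A` = 751, `4A` = 745, `5A` = 710, `6A` = 618, `7A` = 737,
  `1B` = 690, `2B` = 801, `3B` = 831, `4B` = 674, `5B` = 713, `6B` = 721, `7B` = 751,
  `1D` = 496, `2D` = 652, `3D` = 616, `4D` = 510, `5D` = 566, `6D` = 474, `7D` = 638
)

#' Default wheat-like genome, scaled for desk-size simulation
#'
#' Builds a 21-chromosome genome whose physical lengths are proportional to
#' the Chinese Spring chromosome sizes, multiplied by `scale_factor`.
#' Genetic lengths are a flat 150 cM per chromosome and are not scaled:
#' recombination per meiosis is a property of the genetic map, so shrinking
#' the physical axis keeps crossover counts realistic while making
#' simulations fast.
#'
#' @param scale_factor Positive multiplier on the physical lengths.
#'   `scale_factor = 1` gives full CS-like sizes (in bp); the package's own
#'   simulations default to 0.003 (~2 Mbp mean per chromosome).
#' @param genetic_length_cm Genetic length per chromosome (cM), default 150.
#' @return A [genome_spec()].
#' @examples
#' g <- make_default_genome(0.003)
#' nrow(g)  # 21
#' @export
make_default_genome <- function(scale_factor = 1, genetic_length_cm = 150) {
  if (!is.numeric(scale_factor) || length(scale_factor) != 1L ||
      !is.finite(scale_factor) || scale_factor <= 0) {
    stop_invalid("scale_factor must be a positive number")
  }
  genome_spec(
    chrom = names(.cs_chrom_mb),
    length_bp = unname(.cs_chrom_mb) * 1e6 * scale_factor,
    length_cm = rep(genetic_length_cm, 21L)
  )
}

#' @export
print.genome_spec <- function(x, ...) {
  cat(sprintf("genome_spec: 21 chromosomes vs reference '%s'; total %.3g Mbp\n",
              attr(x, "reference"), sum(x$length_bp) / 1e6))
  print.data.frame(utils::head(as.data.frame(x), 4))
  if (nrow(x) > 4) cat("  ... ", nrow(x) - 4, " more chromosomes\n", sep = "")
  invisible(x)
}

chrom_length <- function(genome, chrom) {
  i <- match(chrom, genome$chrom)
  if (anyNA(i)) stop_invalid("unknown chromosome: ", paste(chrom[is.na(i)], collapse = ", "))
  genome$length_bp[i]
}
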