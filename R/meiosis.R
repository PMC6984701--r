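#' Meiosis under the Haldane (no-interference) model
#'
#' Crossover counts per chromosome are Poisson with mean equal to the genetic
#' length in Morgans; crossover positions are uniform on the genetic map and
#' converted to physical coordinates by linear interpolation. This is the
#' Haldane model: the recombination fraction between two loci d cM apart is
#' r = (1 - exp(-2d/100)) / 2.
#'
#' @name meiosis
NULL

# One meiotic product for a single chromosome. h1/h2 are homolog lists,
# length_bp/length_cm the chromosome's physical and genetic lengths.
meiose_chrom <- function(h1, h2, length_bp, length_cm) {
  n_xo <- stats::rpois(1L, length_cm / 100)
  phase <- sample.int(2L, 1L)
  if (n_xo == 0L) return(if (phase == 1L) h1 else h2)
  # map genetic positions to bp linearly; crossovers between bp b and b+1
  xo_bp <- floor(stats::runif(n_xo, 0, length_cm) / length_cm * (length_bp - 1)) + 1
  # double crossovers landing between the same two bases cancel
  if (anyDuplicated(xo_bp)) {
    tab <- table(xo_bp)
    xo_bp <- sort(as.numeric(names(tab)[tab %% 2 == 1L]))
  } else {
    xo_bp <- sort(xo_bp)
  }
  if (length(xo_bp) == 0L) return(if (phase == 1L) h1 else h2)
  bounds <- c(0, xo_bp, length_bp)  # piece i is (bounds[i], bounds[i+1]]
  pieces <- vector("list", length(bounds) - 1L)
  for (i in seq_along(pieces)) {
    a <- bounds[i] + 1
    b <- bounds[i + 1L]
    src <- if ((phase + i) %% 2L == 0L) h1 else h2
    j1 <- findInterval(a, src$start)
    j2 <- findInterval(b, src$start)
    s <- src$start[j1:j2]; e <- src$end[j1:j2]
    s[1L] <- a; e[length(e)] <- b
    pieces[[i]] <- list(start = s, end = e, founder = src$founder[j1:j2])
  }
  out <- list(start = unlist(lapply(pieces, `[[`, "start")),
              end = unlist(lapply(pieces, `[[`, "end")),
              founder = unlist(lapply(pieces, `[[`, "founder")))
  merge_runs(out$start, out$end, out$founder)
}

#' Simulate one gamete from a parent
#'
#' Performs an independent Haldane-model meiosis on each of the 21
#' chromosomes and returns the resulting single-homolog mosaic.
#'
#' @param parent An `individual` (see [founder_individual()]).
#' @param genome A [genome_spec()].
#' @param seed Optional integer seed.
#' @return Named list (by chromosome) of homolog segment lists
#'   `(start, end, founder)`.
#' @export
simulate_gamete <- function(parent, genome, seed = NULL) {
  validate_individual(parent, genome)
  local_seed(seed)
  g <- lapply(seq_len(nrow(genome)), function(i) {
    hh <- parent$homologs[[genome$chrom[i]]]
    meiose_chrom(hh[[1L]], hh[[2L]], genome$length_bp[i], genome$length_cm[i])
  })
  names(g) <- genome$chrom
  g
}

#' Cross two individuals
#'
#' @param mother,father `individual` parents.
#' @param genome A [genome_spec()].
#' @param id Offspring label.
#' @param generation Generation tag for the offspring.
#' @param seed Optional integer seed.
#' @return The offspring `individual`.
#' @export
cross_individuals <- function(mother, father, genome, id = "offspring",
                              generation = NA_character_, seed = NULL) {
  local_seed(seed)
  gm <- simulate_gamete(mother, genome)
  gf <- simulate_gamete(father, genome)
  homologs <- lapply(genome$chrom, function(chrom) list(gm[[chrom]], gf[[chrom]]))
  names(homologs) <- genome$chrom
  new_individual(id, homologs, generation)
}

#' Self-fertilise an individual
#'
#' @inheritParams cross_individuals
#' @param ind The selfed parent.
#' @return The offspring `individual`.
#' @export
self_individual <- function(ind, genome, id = paste0(ind$id, ".s"),
                            generation = NA_character_, seed = NULL) {
  cross_individuals(ind, ind, genome, id = id, generation = generation, seed = seed)
}
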