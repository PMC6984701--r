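#' Founder variant panel
#'
#' A `founder_panel` holds the biallelic variant sites segregating among the
#' three founders of the breeding scheme — the recurrent elite cultivar, the
#' tetraploid donor (A/B subgenomes, e.g. durum cv. Langdon "Ldn") and the
#' diploid donor (D subgenome, an *Aegilops tauschii* accession) — together
#' with the 0/1 (reference/alternate) allele carried by each founder at each
#' site. Alleles are coded against the common reference genome; the
#' tetraploid donor carries alternate alleles only on A/B chromosomes and
#' the diploid donor only on D chromosomes, mirroring the subgenome origins
#' of a synthetic hexaploid.
#'
#' @name founder_panel
NULL

new_founder_panel <- function(genome, roles, sites, alleles) {
  structure(
    list(genome = genome, roles = roles, sites = sites, alleles = alleles),
    class = "founder_panel"
  )
}

#' Sample a random founder variant panel
#'
#' Places `sites_per_chromosome` biallelic sites uniformly at random on each
#' chromosome (sorted, distinct positions), assigns founder alleles under the
#' subgenome constraints above, and draws a long-tailed per-site expression
#' weight (log-normal, mean 1) standing in for transcript abundance — only
#' expressed sites yield RNA-seq reads.
#'
#' @param genome A [genome_spec()].
#' @param sites_per_chromosome Number of variant sites per chromosome.
#' @param seed Optional integer seed (restores the RNG stream afterwards).
#' @param roles Named character vector with entries `recurrent`, `donor_ab`
#'   and `donor_d` giving the founder labels.
#' @param recurrent_alt_fraction Fraction of sites (all subgenomes) where the
#'   recurrent cultivar differs from the reference.
#' @param donor_alt_fraction Fraction of sites on a donor's own subgenome(s)
#'   where that donor differs from the reference; donors are wild-side
#'   material and so more divergent than elite cultivars.
#' @param expression_sdlog Log-sd of the expression-weight distribution.
#' @return A `founder_panel`.
#' @export
sample_founder_panel <- function(genome, sites_per_chromosome = 200, seed = NULL,
                                 roles = c(recurrent = "cultivar",
                                           donor_ab = "Ldn", donor_d = "AT47"),
                                 recurrent_alt_fraction = 0.2,
                                 donor_alt_fraction = 0.8,
                                 expression_sdlog = 0.5) {
  if (!inherits(genome, "genome_spec")) stop_invalid("genome must be a genome_spec")
  if (sites_per_chromosome < 0) stop_invalid("sites_per_chromosome must be >= 0")
  if (!all(c("recurrent", "donor_ab", "donor_d") %in% names(roles))) {
    stop_invalid("roles must name 'recurrent', 'donor_ab' and 'donor_d'")
  }
  local_seed(seed)
  bases <- c("A", "C", "G", "T")
  site_list <- vector("list", nrow(genome))
  for (i in seq_len(nrow(genome))) {
    n <- sites_per_chromosome
    if (n == 0) next
    pos <- sort(sample.int(genome$length_bp[i], n))
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L), character(1))
    site_list[[i]] <- data.frame(
      chrom = genome$chrom[i], pos = pos, ref = ref, alt = unname(alt),
      expression_weight = stats::rlnorm(n, meanlog = -expression_sdlog^2 / 2,
                                        sdlog = expression_sdlog),
      stringsAsFactors = FALSE
    )
  }
  sites <- do.call(rbind, site_list)
  if (is.null(sites)) {
    sites <- data.frame(chrom = character(), pos = integer(), ref = character(),
                        alt = character(), expression_weight = numeric())
  }
  rownames(sites) <- NULL
  ns <- nrow(sites)
  founders <- unname(roles[c("recurrent", "donor_ab", "donor_d")])
  alleles <- matrix(0L, nrow = 3L, ncol = ns, dimnames = list(founders, NULL))
  if (ns > 0) {
    sg <- subgenome_of(sites$chrom)
    alleles[1L, ] <- as.integer(stats::runif(ns) < recurrent_alt_fraction)
    on_ab <- sg %in% c("A", "B")
    alleles[2L, on_ab] <- as.integer(stats::runif(sum(on_ab)) < donor_alt_fraction)
    alleles[3L, !on_ab] <- as.integer(stats::runif(sum(!on_ab)) < donor_alt_fraction)
  }
  new_founder_panel(genome, roles, sites, alleles)
}

#' @export
print.founder_panel <- function(x, ...) {
  cat(sprintf("founder_panel: %d sites on %d chromosomes; founders: %s\n",
              nrow(x$sites), length(unique(x$sites$chrom)),
              paste(rownames(x$alleles), collapse = ", ")))
  invisible(x)
}

# Allele (0/1) of `founder` at panel site indices `idx`.
founder_allele <- function(panel, founder, idx) {
  i <- match(founder, rownames(panel$alleles))
  if (anyNA(i)) stop_invalid("unknown founder: ", paste(founder[is.na(i)], collapse = ", "))
  panel$alleles[cbind(i, idx)]
}
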