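#' Backcross breeding plan
#'
#' Describes the BCnFm scheme used to introgress synthetic-hexaploid material
#' into an elite cultivar: the F1 (donor x recurrent) is backcrossed
#' `n_backcrosses` times to the recurrent cultivar, then selfed `n_selfings`
#' times, with phenotype-based selection of the earliest-heading individuals
#' at every post-F1 generation.
#'
#' @param n_backcrosses Number of backcrosses to the recurrent parent
#'   (2 or 3 in the emulated breeding programme).
#' @param n_selfings Number of selfing generations after the last backcross
#'   (5 or 6).
#' @param population_size Offspring raised per generation.
#' @param n_selected Individuals kept at each selection step; setting it
#'   equal to `population_size` disables selection.
#' @return A `cross_plan` list.
#' @export
cross_plan <- function(n_backcrosses = 2, n_selfings = 5,
                       population_size = 24, n_selected = 6) {
  if (n_backcrosses < 1) stop_invalid("n_backcrosses must be >= 1")
  if (n_selfings < 0) stop_invalid("n_selfings must be >= 0")
  if (n_selected < 1 || n_selected > population_size) {
    stop_invalid("need 1 <= n_selected <= population_size")
  }
  structure(list(n_backcrosses = as.integer(n_backcrosses),
                 n_selfings = as.integer(n_selfings),
                 population_size = as.integer(population_size),
                 n_selected = as.integer(n_selected)),
            class = "cross_plan")
}

#' Heading-date phenotype model
#'
#' Days to heading are modelled as the recurrent cultivar's baseline plus
#' additive QTL effects — each donor-derived allele at a QTL shifts heading
#' by `effect_days` (negative for the early-heading donor alleles being
#' selected) — plus Gaussian noise.
#'
#' @param baseline_days Days to heading of the recurrent cultivar.
#' @param qtl Data frame with columns `chrom`, `pos`, `effect_days`
#'   (per donor allele; negative = earlier heading).
#' @param noise_sd Environmental noise SD in days.
#' @return A `heading_model` list.
#' @export
heading_model <- function(baseline_days = 195,
                          qtl = data.frame(chrom = "5D", pos = 1, effect_days = -1.75),
                          noise_sd = 1) {
  if (noise_sd < 0) stop_invalid("noise_sd must be >= 0")
  if (nrow(qtl) > 0 && any(qtl$effect_days > 0)) {
    stop_invalid("donor-allele QTL effects must be <= 0 (early-heading selection)")
  }
  structure(list(baseline_days = baseline_days, qtl = qtl, noise_sd = noise_sd),
            class = "heading_model")
}

#' Simulate an individual's heading date
#'
#' @param ind An `individual`.
#' @param model A [heading_model()].
#' @param donor_founders Founder labels whose alleles carry the QTL effects.
#' @param seed Optional integer seed.
#' @return Days to heading (numeric scalar).
#' @examples
#' g <- make_default_genome(0.003)
#' rec <- founder_individual(g, "cultivar")
#' hm <- heading_model(195, data.frame(chrom = "5D", pos = 1e5, effect_days = -3.5), 0)
#' heading_phenotype(rec, hm, "AT47")  # 195: no donor alleles
#' @export
heading_phenotype <- function(ind, model, donor_founders, seed = NULL) {
  local_seed(seed)
  days <- model$baseline_days
  if (nrow(model$qtl) > 0) {
    for (i in seq_len(nrow(model$qtl))) {
      hh <- ind$homologs[[model$qtl$chrom[i]]]
      if (is.null(hh)) stop_invalid("QTL on unknown chromosome ", model$qtl$chrom[i])
      n_donor <- sum(vapply(hh, function(h) {
        founder_at(h, model$qtl$pos[i]) %in% donor_founders
      }, logical(1)))
      days <- days + n_donor * model$qtl$effect_days[i]
    }
  }
  days + stats::rnorm(1L, 0, model$noise_sd)
}

# Phenotype-rank selection: earliest n kept, ties broken by id.
select_earliest <- function(pop, days, n) {
  ids <- vapply(pop, `[[`, character(1), "id")
  pop[order(days, ids)[seq_len(n)]]
}

#' Run the backcross-and-self breeding scheme
#'
#' Simulates F1 = donor x recurrent, then `n_backcrosses` backcross
#' generations (each offspring crosses a selected individual to the
#' recurrent parent) and `n_selfings` selfing generations, selecting the
#' `n_selected` earliest-heading individuals at every post-F1 generation.
#' Returns the final selected lines, tagged `BC{n}F{m+1}` as in breeding
#' nomenclature (the last backcross progeny is F1 of the selfing series),
#' together with their ground-truth donor segments.
#'
#' @param plan A [cross_plan()].
#' @param recurrent Homozygous recurrent-cultivar `individual`.
#' @param donor Homozygous donor `individual` (synthetic hexaploid: the
#'   tetraploid founder on A/B, the diploid on D).
#' @param heading A [heading_model()].
#' @param genome A [genome_spec()].
#' @param seed Optional integer seed.
#' @return List with `lines` (list of `individual`s), `truth` (named list of
#'   donor-segment data frames from [true_donor_segments()]) and
#'   `donor_founders`.
#' @export
run_cross_plan <- function(plan, recurrent, donor, heading, genome, seed = NULL) {
  local_seed(seed)
  rec_founders <- unique(unlist(lapply(recurrent$homologs, function(hh)
    c(hh[[1]]$founder, hh[[2]]$founder))))
  donor_founders <- setdiff(unique(unlist(lapply(donor$homologs, function(hh)
    c(hh[[1]]$founder, hh[[2]]$founder)))), rec_founders)
  if (length(donor_founders) == 0L) {
    stop_invalid("donor shares all founders with the recurrent parent")
  }

  f1 <- cross_individuals(donor, recurrent, genome, id = "F1", generation = "F1")
  selected <- list(f1)

  breed_generation <- function(selected, gen_tag, backcross) {
    pop <- vector("list", plan$population_size)
    for (k in seq_len(plan$population_size)) {
      parent <- selected[[sample.int(length(selected), 1L)]]
      id <- sprintf("%s.%03d", gen_tag, k)
      pop[[k]] <- if (backcross) {
        cross_individuals(parent, recurrent, genome, id = id, generation = gen_tag)
      } else {
        self_individual(parent, genome, id = id, generation = gen_tag)
      }
    }
    days <- vapply(pop, heading_phenotype, numeric(1),
                   model = heading, donor_founders = donor_founders)
    sel <- select_earliest(pop, days, plan$n_selected)
    if (length(sel) == 0L) stop_invalid("empty population after selection")
    sel
  }

  for (b in seq_len(plan$n_backcrosses)) {
    selected <- breed_generation(selected, sprintf("BC%d", b), backcross = TRUE)
  }
  if (plan$n_selfings > 0) {
    for (m in seq_len(plan$n_selfings)) {
      tag <- sprintf("BC%dF%d", plan$n_backcrosses, m + 1L)
      selected <- breed_generation(selected, tag, backcross = FALSE)
    }
  }
  final_tag <- sprintf("BC%dF%d", plan$n_backcrosses, plan$n_selfings + 1L)
  lines <- lapply(seq_along(selected), function(k) {
    ind <- selected[[k]]
    ind$generation <- final_tag
    ind$id <- sprintf("%s.L%02d", final_tag, k)
    ind
  })
  truth <- lapply(lines, true_donor_segments, donor_founders = donor_founders)
  names(truth) <- vapply(lines, `[[`, character(1), "id")
  list(lines = lines, truth = truth, donor_founders = donor_founders)
}
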