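toy_calls <- function(call, sample_id, alt = "G") {
  make_calls("1A", seq_along(call) * 100, call, sample_id = sample_id, alt = alt)
}

test_that("diff membership equals brute-force enumeration over toy panels", {
  states <- c("reference", "alternate", "no_call")
  set.seed(51)
  for (rep in 1:40) {
    a <- toy_calls(sample(states, 10, replace = TRUE), "line")
    b <- toy_calls(sample(states, 10, replace = TRUE), "cultivar")
    d <- diff_snps(a, b)
    expect_equal(d$pos, a$pos[oracle_diff(a, b)])
  }
  # identity: diff(x, x) is empty
  x <- toy_calls(sample(states, 6, replace = TRUE), "x")
  expect_identical(nrow(diff_snps(x, x)), 0L)
})

test_that("diff records the called alleles and is symmetric in membership", {
  line <- toy_calls(c("alternate", "reference", "no_call", "reference"), "L")
  cult <- toy_calls(c("reference", "reference", "reference", "no_call"), "C")
  d <- diff_snps(line, cult)
  expect_equal(d$pos, 100)
  expect_identical(d$line_allele, "G")
  expect_identical(d$cultivar_allele, "A")
  # swapping arguments swaps the allele columns on the same member set
  d2 <- diff_snps(cult, line)
  expect_equal(d2$pos, d$pos)
  expect_identical(d2$line_allele, d$cultivar_allele)
  expect_identical(d2$cultivar_allele, d$line_allele)
  # mismatched references refuse to compare
  attr(cult, "reference") <- "other"
  expect_error(diff_snps(line, cult), "references")
})

test_that("the combined donor SNP set matches per-parent calling where coverage is exclusive", {
  g <- desk_genome()
  panel <- desk_panel(g, sites = 30, seed = 52)
  donor <- founder_individual(g, c(A = "Ldn", B = "Ldn", D = "AT47"), "syn")
  ab <- g$chrom[g$subgenome %in% c("A", "B")]
  dd <- g$chrom[g$subgenome == "D"]
  ldn <- simulate_allele_counts(donor, panel, observation_model(25, 0),
                                sample_id = "Ldn", chromosomes = ab, seed = 1)
  tau <- simulate_allele_counts(donor, panel, observation_model(25, 0),
                                sample_id = "AT47", chromosomes = dd, seed = 2)
  combined <- build_donor_snpset(ldn, tau, call_rule())
  # two-route check: each parent called separately, then unioned
  route2 <- rbind(plain(snps_vs_reference(call_genotypes(ldn, call_rule()))),
                  plain(snps_vs_reference(call_genotypes(tau, call_rule()))))
  route2 <- route2[order(match(route2$chrom, intrograph:::chrom_levels()), route2$pos), ]
  expect_equal(plain(combined), route2, ignore_attr = TRUE)
  # D-chromosome donor SNPs derive solely from the diploid parent
  d_snps <- combined[substr(combined$chrom, 2, 2) == "D", ]
  expect_true(all(intrograph:::site_key(d_snps$chrom, d_snps$pos) %in%
                    intrograph:::site_key(tau$chrom, tau$pos)[tau$alt_count > 0]))
  # zero coverage from both parents -> empty donor set
  zero <- make_counts(ldn$chrom, ldn$pos, 0L, 0L, ref = ldn$ref, alt = ldn$alt,
                      sample_id = "z")
  expect_identical(nrow(build_donor_snpset(zero, zero)), 0L)
})

test_that("origin assignment is allele-exact against the donor set", {
  line <- toy_calls(c("alternate", "alternate", "reference"), "L", alt = c("G", "T", "C"))
  cult <- toy_calls(c("reference", "reference", "alternate"), "C", alt = c("G", "T", "C"))
  d <- diff_snps(line, cult)
  donor <- structure(data.frame(chrom = "1A", pos = c(100, 300), allele = c("G", "C"),
                                stringsAsFactors = FALSE),
                     sample_id = "syn", reference = "CS",
                     class = c("snp_set", "data.frame"))
  a <- assign_origin(d, donor)
  # pos 100: line allele G matches donor G -> donor
  # pos 200: site absent from donor set -> non_donor
  # pos 300: line called reference (A), donor allele C -> allele mismatch
  expect_identical(a$origin, c("donor", "non_donor", "non_donor"))
  # empty donor set -> everything non_donor
  empty_donor <- donor[0, ]
  attr(empty_donor, "reference") <- "CS"
  expect_true(all(assign_origin(d, empty_donor)$origin == "non_donor"))
  expect_identical(nrow(a), nrow(d))
})

test_that("per-chromosome counts match a brute-force tally", {
  g <- desk_genome()
  set.seed(53)
  for (rep in 1:20) {
    chroms <- sample(g$chrom, 25, replace = TRUE)
    a <- structure(data.frame(chrom = chroms, pos = sample.int(1e5, 25),
                              origin = sample(c("donor", "non_donor"), 25, TRUE),
                              stringsAsFactors = FALSE),
                   class = c("origin_assignment", "data.frame"))
    tab <- count_by_chromosome(a, g)
    expect_equal(tab$n_snps, unname(vapply(g$chrom, function(ch)
      sum(chroms == ch), 0L)))
    expect_identical(attr(tab, "total"), nrow(a))
    donor_tab <- count_by_chromosome(a, g, donor_only = TRUE)
    expect_identical(attr(donor_tab, "total"), sum(a$origin == "donor"))
  }
  empty <- structure(data.frame(chrom = character(), pos = numeric(),
                                origin = character()),
                     class = c("origin_assignment", "data.frame"))
  tab0 <- count_by_chromosome(empty, g)
  expect_true(all(tab0$n_snps == 0L) && attr(tab0, "total") == 0L)
  bad <- structure(data.frame(chrom = "8Z", pos = 1, origin = "donor"),
                   class = c("origin_assignment", "data.frame"))
  expect_error(count_by_chromosome(bad, g), "absent")
})

test_that("greedy gap-chaining matches hand-traced and exhaustive segmentation", {
  g <- desk_genome()
  mk_assign <- function(pos, chrom = "1A") {
    structure(data.frame(chrom = rep(chrom, length(pos)), pos = pos,
                         origin = rep("donor", length(pos)),
                         stringsAsFactors = FALSE),
              donor_id = "syn", class = c("origin_assignment", "data.frame"))
  }
  # hand trace: markers 100, 200, 10000; gap 500; min 2 -> one block [100, 200]
  b <- segment_blocks(mk_assign(c(100, 200, 10000)),
                      segmentation_params(max_gap_bp = 500, min_markers = 2))
  expect_equal(nrow(b), 1L)
  expect_equal(c(b$start, b$end, b$n_markers), c(100, 200, 2))
  # no donor markers -> no blocks
  expect_identical(nrow(segment_blocks(mk_assign(numeric(0)),
                                       segmentation_params(1000, 1))), 0L)
  # randomized equivalence with the exhaustive-search oracle
  set.seed(54)
  for (rep in 1:60) {
    n <- sample(1:30, 1)
    pos <- sort(sample.int(5e4, n))
    gap <- sample(c(500, 2000, 8000), 1)
    minm <- sample(1:4, 1)
    got <- segment_blocks(mk_assign(pos), segmentation_params(gap, minm))
    want <- oracle_segment(pos, gap, minm)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$n_markers, want$n_markers)
  }
})

test_that("recovery metrics agree with interval-algebra oracles", {
  blocks <- structure(data.frame(chrom = "1A", start = 51, end = 150,
                                 n_markers = 5L, donor = "syn"),
                      class = c("introgression_blocks", "data.frame"))
  truth <- data.frame(chrom = "1A", start = 101, end = 200, zygosity = "hom")
  m <- evaluate_recovery(truth, blocks)
  expect_equal(m$precision_bp, 0.5)
  expect_equal(m$recall_bp, 0.5)
  expect_equal(m$jaccard, oracle_jaccard(truth, blocks, 300))
  expect_equal(m$breakpoint_error_bp, 50)
  # perfect detection
  perfect <- evaluate_recovery(truth, structure(
    data.frame(chrom = "1A", start = 101, end = 200, n_markers = 3L, donor = "syn"),
    class = c("introgression_blocks", "data.frame")))
  expect_equal(unlist(perfect),
               c(precision_bp = 1, recall_bp = 1, jaccard = 1, breakpoint_error_bp = 0))
  # no detection: recall 0
  none <- evaluate_recovery(truth, blocks[0, ])
  expect_equal(none$recall_bp, 0)
  expect_true(is.na(none$precision_bp))
})

test_that("set identities hold on simulated scans", {
  g <- desk_genome()
  panel <- desk_panel(g, sites = 120, seed = 55)
  donor <- founder_individual(g, c(A = "Ldn", B = "Ldn", D = "AT47"), "syn")
  rec <- founder_individual(g, "cultivar")
  line <- planted_individual(g, "5D", 1, 8e5, id = "L1")
  obs <- observation_model(20, 0)
  rule <- call_rule()
  line_calls <- call_genotypes(simulate_allele_counts(line, panel, obs, seed = 1), rule)
  cult_calls <- call_genotypes(simulate_allele_counts(rec, panel, obs, seed = 2), rule)
  ab <- g$chrom[g$subgenome %in% c("A", "B")]
  dd <- g$chrom[g$subgenome == "D"]
  donor_snps <- build_donor_snpset(
    simulate_allele_counts(donor, panel, obs, sample_id = "Ldn", chromosomes = ab, seed = 3),
    simulate_allele_counts(donor, panel, obs, sample_id = "AT47", chromosomes = dd, seed = 4),
    rule)
  d <- diff_snps(line_calls, cult_calls)
  a <- assign_origin(d, donor_snps)
  expect_identical(nrow(a), nrow(d))
  expect_true(all(intrograph:::site_key(a$chrom[a$origin == "donor"], a$pos[a$origin == "donor"]) %in%
                    intrograph:::site_key(d$chrom, d$pos)))
  tab <- count_by_chromosome(a, g)
  expect_identical(attr(tab, "total"), sum(tab$n_snps))
})
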