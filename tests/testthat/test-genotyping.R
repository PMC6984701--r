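test_that("calls match the literal depth/fraction rule on an exhaustive grid", {
  # every (depth <= 30, alt <= depth) combination vs the plain-language rule
  grid <- do.call(rbind, lapply(0:30, function(d) data.frame(depth = d, alt = 0:d)))
  counts <- make_counts("1A", seq_len(nrow(grid)), grid$depth - grid$alt, grid$alt)
  got <- call_genotypes(counts, call_rule())$call
  want <- mapply(oracle_call, grid$depth - grid$alt, grid$alt)
  expect_identical(got, unname(want))
})

test_that("threshold edge cases behave as specified", {
  counts <- make_counts("1A", 1:4,
                        ref_count = c(1L, 2L, 3L, 0L),
                        alt_count = c(8L, 8L, 7L, 9L))
  calls <- call_genotypes(counts, call_rule())
  expect_identical(calls$call, c("no_call",     # depth 9
                                 "alternate",   # 8/10 = 0.80, tie counts
                                 "reference",   # 7/10 < 0.80
                                 "no_call"))    # depth 9, pure alternate
  expect_error(call_genotypes(make_counts("1A", 1, -1L, 5L)), "negative")
})

test_that("strict mode turns intermediate fractions into no_call", {
  counts <- make_counts("1A", 1:3, ref_count = c(10L, 6L, 2L),
                        alt_count = c(2L, 6L, 18L))
  lenient <- call_genotypes(counts, call_rule())$call
  strict <- call_genotypes(counts, call_rule(strict = TRUE))$call
  expect_identical(lenient, c("reference", "reference", "alternate"))
  expect_identical(strict, c("reference", "no_call", "alternate"))
})

test_that("adding alternate reads never flips alternate to reference", {
  rule <- call_rule()
  for (d in c(10, 15, 25)) {
    for (a in 0:d) {
      base <- call_genotypes(make_counts("1A", 1, d - a, a), rule)$call
      more <- call_genotypes(make_counts("1A", 1, d - a, a + 5L), rule)$call
      if (base == "alternate") expect_identical(more, "alternate")
    }
  }
})

test_that("heterozygous alternate-call rate equals the binomial tail", {
  # truly heterozygous site, error-free reads: P(call = alternate)
  # = P(Binom(depth, 1/2) >= 0.8 * depth) for fixed depth
  set.seed(31)
  depth <- 12L
  n <- 4000
  alt <- rbinom(n, depth, 0.5)
  counts <- make_counts("1A", seq_len(n), depth - alt, alt)
  got <- mean(call_genotypes(counts, call_rule())$call == "alternate")
  p_tail <- sum(dbinom(ceiling(0.8 * depth):depth, depth, 0.5))
  expect_lt(abs(got - p_tail), 3 * sqrt(p_tail * (1 - p_tail) / n))
})

test_that("snps_vs_reference selects exactly the alternate calls", {
  counts <- make_counts("2D", 1:5, ref_count = c(0L, 20L, 5L, 0L, 1L),
                        alt_count = c(20L, 0L, 5L, 3L, 19L))
  calls <- call_genotypes(counts, call_rule())
  snps <- snps_vs_reference(calls)
  expect_equal(snps$pos, c(1, 5))
  expect_identical(snps$allele, calls$alt[c(1, 5)])
  # idempotent on unchanged calls; empty on all-reference input
  expect_identical(snps_vs_reference(calls), snps_vs_reference(calls))
  all_ref <- call_genotypes(make_counts("1A", 1:3, 20L, 0L), call_rule())
  expect_identical(nrow(snps_vs_reference(all_ref)), 0L)
})

test_that("VCF writing and reading round-trip the call set", {
  counts <- make_counts("5D", c(100L, 250L, 900L), ref_count = c(0L, 12L, 4L),
                        alt_count = c(15L, 1L, 5L), sample_id = "SB12.1",
                        ref = c("A", "C", "G"), alt = c("G", "T", "A"))
  calls <- call_genotypes(counts, call_rule())
  path <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(calls, path)
  back <- read_calls_vcf(path)
  expect_equal(plain(back), plain(calls))
  expect_identical(attr(back, "sample_id"), "SB12.1")
  expect_identical(attr(back, "reference"), "CS")
  # the rule re-applied to the read-back counts reproduces the calls
  reapplied <- call_genotypes(make_counts(back$chrom, back$pos, back$ref_count,
                                          back$alt_count, sample_id = "SB12.1",
                                          ref = back$ref, alt = back$alt),
                              call_rule())
  expect_identical(reapplied$call, calls$call)
})

test_that("VCF edge cases: empty body, multi-allelic skip, malformed line", {
  empty_path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1"), collapse = "\t")), empty_path)
  expect_identical(nrow(read_calls_vcf(empty_path)), 0L)

  multi_path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"g\">",
               "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
               "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"a\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1"), collapse = "\t"),
               "1A\t10\t.\tA\tG,T\t.\tPASS\t.\tGT:DP:AD\t1/1:20:0,20",
               "1A\t20\t.\tA\tG\t.\tPASS\t.\tGT:DP:AD\t1/1:20:0,20"),
             multi_path)
  expect_warning(cs <- read_calls_vcf(multi_path), "multi-allelic")
  expect_identical(cs$pos, 20L)

  bad_path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", "s1"), collapse = "\t"),
               "1A\t10\tbroken"), bad_path)
  expect_error(read_calls_vcf(bad_path), "line 3")
})
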