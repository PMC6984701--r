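---
title: "Mapping synthetic-wheat introgressions from transcriptome SNPs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping synthetic-wheat introgressions from transcriptome SNPs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(intrograph)
```

## The analysis in one paragraph

Backcross-derived bread wheat lines carry a mosaic genome: mostly the
recurrent elite cultivar, with a few chromosome segments inherited from a
synthetic hexaploid donor (durum × *Aegilops tauschii*). `intrograph`
locates those segments from transcriptome SNPs. Genotypes are called from
per-site allele counts with a hard depth/fraction rule; the donor's SNP set
is constructed by pooling its two parents' reads; each line is differenced
against its cultivar; differing SNPs whose line allele matches the donor
set are labelled donor-origin; and runs of donor markers are chained into
introgression blocks. A forward simulator of the breeding scheme supplies
ground truth for every one of these steps.

## The genotype-calling rule

A site is callable at depth ≥ `min_depth` (default 10) and called
alternate when the alternate-read fraction is ≥ `min_fraction` (default
0.80, ties included: 8 alternate reads out of 10 is an alternate call).
Callable sites below the fraction threshold are reported as the reference
genotype: the rule defines when a variant *is* called, and on fully inbred
material everything else is effectively reference. Because truly
heterozygous sites produce alternate fractions near 0.5, the 80% threshold
suppresses them — at depth 12, the probability that a balanced
heterozygote is miscalled alternate is the binomial tail
$P(\mathrm{Bin}(12, 0.5) \ge 10) \approx 0.019$, and it vanishes as depth
grows. This is deliberate: residual heterozygous donor segments in an
F₆ line are largely invisible to the rule, a limitation quantified below.
For substrates where intermediate fractions signal artefacts (e.g.
homoeolog cross-mapping), `call_rule(strict = TRUE)` turns the 20–80%
band into no-calls instead; the default keeps the literal rule.

Coordinates are 1-based inclusive everywhere in the variant domain (VCF
convention); BED outputs are 0-based half-open.

## Differencing and donor assignment

`diff_snps()` admits a site only when *both* samples are callable there and
their called alleles differ. Requiring joint callability stops coverage
dropouts from masquerading as polymorphism — the practical failure mode of
shallow samples, where a low-coverage parent yields sparse SNPs on whole
subgenomes. `assign_origin()` is allele-exact: a difference SNP is
donor-origin only if the line's allele equals the donor set's alternate
allele at that position, not merely because the line differs from both
cultivar and reference. Novel or residual variation therefore stays
`non_donor`, and both the all-differences and donor-only chromosome count
tables are emitted, since either can be of interest.

The donor SNP set itself is built by summing the tetraploid parent's and
the diploid parent's allele counts site-wise (`combine_counts()`) and
calling the pooled sample. On chromosomes covered by only one parent this
reduces to that parent's own call; on a real hexaploid transcriptome the
pooling mirrors how the combined donor read set is produced. Setting the
diploid parent's `coverage_scale` low reproduces the known failure mode of
a shallow legacy-platform accession: its subgenome simply stops yielding
callable donor markers, and joint callability keeps the result honest.

## Block segmentation

Transcribed markers are sparse and unevenly spaced, so blocks are defined
by gap chaining: per chromosome, donor markers sorted by position join the
current chain while the gap to the previous marker is at most
`max_gap_bp`, and chains with at least `min_markers` markers become blocks
spanning first to last marker. The defaults — `max_gap_bp` = 5% of the
chromosome's length, `min_markers = 3` — adapt the gap tolerance to
chromosome size and make a single stray marker (or two) insufficient to
declare an introgression. For gap-constrained chaining the greedy rule
provably yields the unique partition into the fewest chains, which is why
the test suite can check it against an exhaustive dynamic-programming
search. We chose chaining over an HMM: it matches how marker-density plots
are read by eye, has no tuned transition probabilities, and admits a
brute-force oracle. The cost is that breakpoints are placed at the
outermost markers, so block edges systematically undershoot true
recombination points by about half a marker spacing per side.

`evaluate_recovery()` scores detected blocks against truth in base pairs:
precision (detected bp that are truly donor), recall (truth bp covered),
Jaccard, and mean absolute breakpoint error over best-overlap matches.

## The simulator and its defaults

The simulator's role is to generate data under the breeding scheme's own
assumptions with exact bookkeeping, not to imitate every artefact of real
transcriptomes. Choices, with rationale:

* **Genome.** 21 chromosomes named 1A..7D, physical lengths proportional
  to the CS assembly's chromosome sizes. Simulations default to
  `scale_factor = 0.003` (~2 Mbp mean per chromosome, ~14 Mbp genome),
  which keeps a few hundred replicate pedigrees in the seconds-to-minutes
  range; the genetic map (150 cM per chromosome, flat) is *not* scaled, so
  per-meiosis crossover counts stay realistic. The genetic→physical map is
  linear per chromosome — no data here constrain nonlinearity.
* **Meiosis.** Haldane model: crossover count Poisson(`length_cm`/100),
  positions uniform in genetic coordinates, no interference. Chosen for
  its closed-form recombination fraction
  $r = (1 - e^{-2d/100})/2$, which the tests verify directly at 50 cM
  (r ≈ 0.3161) over 2×10⁴ meioses.
* **Cross plan.** F₁ = donor × recurrent, then `n_backcrosses` backcross
  generations and `n_selfings` selfings, the earliest-heading `n_selected`
  of `population_size` kept each generation (ties broken by id). Final
  lines are tagged BC{n}F{m+1} and taken as-is, without forcing
  homozygosity — residual heterozygosity is handled (i.e. mostly
  suppressed) downstream by the call rule. Population sizes and selection
  intensities per generation are not documented for the emulated
  programme, so they are plain configuration with defaults (24 raised, a
  handful kept) of the order a small field programme would use.
* **Heading model.** `days = baseline + Σ (donor alleles at QTL) × effect
  + N(0, noise_sd)`, with negative effects for the early-heading donor
  alleles under selection; defaults baseline 195 d, one 5D QTL at −1.75
  d/allele, noise 1 d. A line fixed for that QTL heads 3.5 d early;
  drawing effects in [−4, −1] d/allele spans the 2–8 d advance window
  that motivates the selection.
* **Founder panel.** The recurrent cultivar differs from the reference at
  20% of sites on all chromosomes; each donor differs at 80% of sites on
  its own subgenomes (tetraploid on A/B, diploid on D, zero elsewhere by
  construction). The 4:1 donor:cultivar divergence ratio matches the
  relative SNP yields observed when wild-side donors and elite cultivars
  are called against the same reference. 200 sites per chromosome is the
  desk-scale default.
* **Expression weights.** Sites carry log-normal weights (mean 1, sdlog
  0.5) multiplying expected depth. The moderate dispersion reflects that
  panel sites model variant positions *discoverable by RNA-seq
  genotyping* — i.e. already conditioned on adequate transcript coverage —
  not the raw transcriptome-wide expression distribution, whose silent
  tail would simply never enter a SNP panel.
* **Observation.** Depth Poisson(`mean_depth × weight × coverage_scale`);
  each read picks one homolog uniformly and flips with `error_rate`
  (default 0.005). Reads are site-independent: genotyping is per-site, so
  linkage enters only through the genome mosaic. Indels are not simulated;
  the pipeline treats biallelic variants generically. Homoeologous
  mis-mapping between subgenomes — a real source of artifactual
  heterozygosity in hexaploid transcriptomes — is *not* modelled, so
  passing simulations say nothing about that failure mode; the strict call
  mode exists for it.

All randomness flows from one master seed; per-stage child seeds are
derived stably so stages can be rerun in isolation, and two runs with the
same config and seed produce byte-identical metrics.

## What the validation shows

With selection off, single-descent lines recover the Mendelian
expectations — mean donor genome fraction 1/8 after two backcrosses, 1/16
after three, and per-locus heterozygosity halving per selfing — within
three standard errors, and the *detected* donor-marker fraction tracks the
true fraction to within two percentage points at depth 20. Planted
homozygous donor segments spanning ~24 diagnostic markers are recovered
with precision ≈ 1 and recall ≈ 0.93 at default segmentation parameters;
the missing recall is edge trimming (blocks end at the outermost detected
marker) plus occasional chain splits where marker dropout opens a gap
beyond the 5% threshold. Re-sequenced pure-cultivar lines yield zero donor
markers and zero blocks at a 0.005 error rate — the binomial probability
of an ≥80%-error pileup at depth ≥10 is negligible. Selection on a single
D-genome QTL drives its donor-allele frequency in final lines far above
the 12.5% no-selection expectation.

Two caveats frame these numbers. Recall against *full* truth (as reported
per line by `run_full_pipeline()`) is substantially lower than against
homozygous truth, because F₆ lines still carry heterozygous donor
residues that the 80% rule deliberately refuses to call — that is a
property of the published rule, not of the implementation. And all of the
above concerns simulated data with independent per-site reads; real
hexaploid RNA-seq adds mapping bias and homoeolog collapse that no test
here exercises.

## Numerical notes

Degenerate inputs are defined, not special-cased: zero-depth sites are
no-calls with `NA` alternate fraction; empty marker sets segment into zero
blocks; recovery metrics return `NA` for undefined ratios (empty truth or
empty detection) and Jaccard 1 when both are empty. Crossovers falling
between the same two bases cancel pairwise (parity rule). Exact 80%
alternate fractions are alternate calls. Chromosome tables are always
emitted in the fixed order 1A..7A, 1B..7B, 1D..7D with a trailing total.
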