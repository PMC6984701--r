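# Shared fixtures and independent oracles, built in code at test time.

desk_genome <- function(scale = 0.003) make_default_genome(scale)

desk_roles <- c(recurrent = "cultivar", donor_ab = "Ldn", donor_d = "AT47")

desk_panel <- function(genome = desk_genome(), sites = 200, seed = 11) {
  sample_founder_panel(genome, sites, seed = seed, roles = desk_roles)
}

# Build an allele_counts table directly from vectors (bypasses simulation).
make_counts <- function(chrom, pos, ref_count, alt_count, sample_id = "s",
                        ref = "A", alt = "G", reference = "CS") {
  df <- data.frame(chrom = chrom, pos = pos,
                   ref = rep_len(ref, length(pos)), alt = rep_len(alt, length(pos)),
                   ref_count = ref_count, alt_count = alt_count,
                   stringsAsFactors = FALSE)
  structure(df, sample_id = sample_id, reference = reference,
            class = c("allele_counts", "data.frame"))
}

# Build a call_set directly from per-site calls.
make_calls <- function(chrom, pos, call, sample_id = "s", ref = "A", alt = "G",
                       depth = 20, reference = "CS") {
  df <- data.frame(chrom = chrom, pos = pos,
                   ref = rep_len(ref, length(pos)), alt = rep_len(alt, length(pos)),
                   ref_count = ifelse(call == "alternate", 0L, depth),
                   alt_count = ifelse(call == "alternate", depth, 0L),
                   depth = rep_len(depth, length(pos)),
                   alt_fraction = ifelse(call == "alternate", 1, 0),
                   call = call, stringsAsFactors = FALSE)
  structure(df, sample_id = sample_id, reference = reference,
            class = c("call_set", "data.frame"))
}

# Plant a homozygous donor segment into an otherwise-recurrent individual.
# The donor founder follows the subgenome: the tetraploid parent contributes
# A/B material, the diploid parent D material.
planted_individual <- function(genome, chrom, start, end, donor = NULL,
                               recurrent = "cultivar", id = "planted") {
  if (is.null(donor)) {
    donor <- if (substr(chrom, 2, 2) == "D") "AT47" else "Ldn"
  }
  ind <- founder_individual(genome, recurrent, id = id)
  L <- genome$length_bp[match(chrom, genome$chrom)]
  seg <- function() {
    s <- c(if (start > 1) 1, start, if (end < L) end + 1)
    e <- c(if (start > 1) start - 1, end, if (end < L) L)
    f <- c(if (start > 1) recurrent, donor, if (end < L) recurrent)
    list(start = as.numeric(s), end = as.numeric(e), founder = f)
  }
  ind$homologs[[chrom]] <- list(seg(), seg())
  ind
}

# Drop class/attribute decoration so content can be compared across routes.
plain <- function(d) data.frame(as.data.frame(d))

# --- independent oracles ----------------------------------------------------

# Literal statement of the genotype-calling rule, evaluated per site.
oracle_call <- function(ref_count, alt_count, min_depth = 10, min_fraction = 0.8) {
  depth <- ref_count + alt_count
  if (depth < min_depth) return("no_call")
  if (alt_count / depth >= min_fraction) return("alternate")
  "reference"
}

# Exhaustive-search segmentation: enumerate partitions of the sorted marker
# positions into contiguous runs whose internal gaps are all <= max_gap,
# minimising the number of runs (dynamic programme over prefix minima),
# then apply the min_markers filter. Independent of the greedy chaining.
oracle_segment <- function(pos, max_gap, min_markers) {
  pos <- sort(pos)
  n <- length(pos)
  if (n == 0L) return(data.frame(start = numeric(0), end = numeric(0),
                                 n_markers = integer(0)))
  ok_run <- function(i, j) i == j || all(diff(pos[i:j]) <= max_gap)
  best <- rep(Inf, n + 1L); best[1L] <- 0
  prev <- rep(NA_integer_, n + 1L)
  for (j in seq_len(n)) {
    for (i in seq_len(j)) {
      if (ok_run(i, j) && best[i] + 1 < best[j + 1L]) {
        best[j + 1L] <- best[i] + 1
        prev[j + 1L] <- i
      }
    }
  }
  runs <- list(); j <- n
  while (j > 0L) {
    i <- prev[j + 1L]
    runs[[length(runs) + 1L]] <- c(i, j)
    j <- i - 1L
  }
  runs <- rev(runs)
  out <- do.call(rbind, lapply(runs, function(r) {
    data.frame(start = pos[r[1L]], end = pos[r[2L]], n_markers = r[2L] - r[1L] + 1L)
  }))
  out[out$n_markers >= min_markers, , drop = FALSE]
}

# Brute-force diff membership over all panel sites.
oracle_diff <- function(line, cultivar) {
  hits <- integer(0)
  for (i in seq_len(nrow(line))) {
    a <- line$call[i]; b <- cultivar$call[i]
    if (a != "no_call" && b != "no_call" && a != b) hits <- c(hits, i)
  }
  hits
}

# Base-pair interval metrics by literal per-bp membership testing (tiny scale).
oracle_jaccard <- function(truth, blocks, length_bp) {
  in_set <- function(df, x) {
    any(df$start <= x & x <= df$end)
  }
  inter <- union_ <- 0
  for (x in seq_len(length_bp)) {
    t <- in_set(truth, x); b <- in_set(blocks, x)
    inter <- inter + (t && b)
    union_ <- union_ + (t || b)
  }
  if (union_ == 0) 1 else inter / union_
}
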