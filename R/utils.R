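# Internal helpers shared across modules.

# Canonical chromosome order: 1A..7A, 1B..7B, 1D..7D (matches the
# per-chromosome SNP count table layout).
chrom_levels <- function() {
  as.vector(vapply(c("A", "B", "D"), function(g) paste0(1:7, g), character(7)))
}

subgenome_of <- function(chrom) substr(chrom, nchar(chrom), nchar(chrom))

#' @importFrom stats runif
derive_seed <- function(master, tag) {
  # Stable child-seed derivation so stages are reproducible in isolation.
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483647L)
}

# Set the RNG locally; restore the caller's stream on exit.
local_seed <- function(seed, env = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) runif(1)
  old <- get(".Random.seed", globalenv())
  assign(".seed_restore", old, envir = env)
  do.call(on.exit, list(quote(assign(".Random.seed", .seed_restore, globalenv())),
                        add = TRUE), envir = env)
  set.seed(seed)
  invisible(NULL)
}

stop_invalid <- function(...) stop(..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Merge adjacent runs with equal labels in a segment vector triple.
merge_runs <- function(start, end, founder) {
  n <- length(founder)
  if (n <= 1L) return(list(start = start, end = end, founder = founder))
  change <- founder[-1L] != founder[-n]
  i_start <- c(1L, which(change) + 1L)
  i_end <- c(which(change), n)
  list(start = start[i_start], end = end[i_end], founder = founder[i_start])
}

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")
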