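# Shared builders for tests. Everything is generated in code; no stored
# data files.

library(GenomicRanges)

# a fragment library straight from a coordinate table
lib_from_table <- function(chrom, start, end, copy = 1L, id = "toy",
                           targeted = FALSE, dedup = FALSE) {
  n <- max(length(chrom), length(start), length(end))
  fragment_library(
    data.frame(chrom = rep_len(chrom, n), start = rep_len(start, n),
               end = rep_len(end, n), copy_count = rep_len(copy, n)),
    library_id = id, targeted = targeted, deduplicated = dedup)
}

# a coverage track directly from per-chromosome bin values
track_from_values <- function(values, bin_size = 50L, chrom_lengths = NULL,
                              id = "track") {
  if (is.null(chrom_lengths)) {
    chrom_lengths <- setNames(vapply(values, length, 1L) * bin_size,
                              names(values))
  }
  structure(list(bin_size = as.integer(bin_size), values = values,
                 normalization = "raw", mode = "span", library_id = id,
                 chrom_lengths = chrom_lengths),
            class = "coverage_track")
}

# a track whose signal blocks have exactly these AUCs (one bin per block,
# zero gap bins between)
track_with_aucs <- function(aucs, bin_size = 50L, id = "aucs") {
  v <- numeric(2 * length(aucs))
  v[seq(1, by = 2, length.out = length(aucs))] <- aucs / bin_size
  track_from_values(list(chr1 = v), bin_size = bin_size, id = id)
}

# a count matrix directly from a counts matrix
cm_from_counts <- function(counts, size_factors = rep(1, ncol(counts))) {
  ids <- paste0("lib", seq_len(ncol(counts)))
  regions <- GRanges("chr1", IRanges(start = seq_len(nrow(counts)) * 1000,
                                     width = 100))
  structure(list(regions = regions,
                 counts = matrix(as.integer(round(counts)),
                                 nrow = nrow(counts),
                                 dimnames = list(NULL, ids)),
                 size_factors = setNames(as.numeric(size_factors), ids)),
            class = "count_matrix")
}

# random interval set on a toy genome (for brute-force oracle comparisons)
random_intervals <- function(n, genome_bp = 10000L, max_width = 300L) {
  start <- sample.int(genome_bp - max_width, n, replace = TRUE)
  GRanges("chr1", IRanges(start = start,
                          width = sample.int(max_width, n, replace = TRUE)))
}

# per-base-pair membership counting oracle for consensus derivation
brute_consensus_bp <- function(sets, min_count, genome_bp = 10000L) {
  depth <- integer(genome_bp)
  for (g in sets) {
    covered <- logical(genome_bp)
    for (i in seq_along(g)) {
      covered[start(g)[i]:end(g)[i]] <- TRUE
    }
    depth <- depth + covered
  }
  which(depth >= min_count)
}

# brute-force 1-bp-overlap test between two 1-based closed intervals
overlaps1 <- function(s1, e1, s2, e2) s1 <= e2 & s2 <= e1

# independent per-interval overlap counting (double loop)
brute_hits <- function(q, r) {
  vapply(seq_along(q), function(i) {
    any(overlaps1(start(q)[i], end(q)[i], start(r), end(r)) &
          as.character(seqnames(q))[i] == as.character(seqnames(r)))
  }, logical(1))
}

# the default synthetic scenario, computed once and shared by the tests
# that probe it (peak-calling strategy contrast, differential contrast,
# shuffled-null separation)
scenario_cache <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- run_scenario(scenario_config(seed = 1))
    }
    cache
  }
})
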