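#' Bin a fragment library into a coverage track
#'
#' Divides every chromosome into `bin_size` bins (the final bin may be
#' shorter) and accumulates read-weighted fragment signal. `"span"` mode
#' increments every bin a fragment overlaps and is the input of signal
#' block detection; `"midpoint"` mode increments only the bin containing
#' the fragment midpoint (left-biased for even lengths), the analog of
#' centred-read visualization, and conserves total counts exactly.
#' `"cpm"` normalization scales bins by `1e6 / total reads`, so a
#' midpoint-mode CPM track sums to one million.
#'
#' Each record contributes its `copy_count`; for deduplicated libraries
#' this is one per molecule.
#'
#' @param lib a [fragment_library()].
#' @param layout a [genome_layout()].
#' @param bin_size bin width in base pairs.
#' @param mode `"span"` or `"midpoint"`.
#' @param normalization `"raw"` or `"cpm"`.
#' @return an object of class `coverage_track`: list with `bin_size`,
#'   `values` (named list of per-chromosome numeric vectors),
#'   `normalization`, `mode`, `library_id` and `chrom_lengths`.
#' @export
#' @examples
#' layout <- genome_layout(data.frame(name = "chr1", length = 300L))
#' f <- data.frame(chrom = "chr1", start = 100L, end = 260L, copy_count = 1L)
#' tr <- fragments_to_coverage(fragment_library(f, "toy"), layout,
#'                             bin_size = 50, mode = "span")
#' tr$values$chr1
fragments_to_coverage <- function(lib, layout, bin_size = 50L,
                                  mode = c("span", "midpoint"),
                                  normalization = c("raw", "cpm")) {
  stopifnot(inherits(lib, "fragment_library"),
            inherits(layout, "genome_layout"),
            is_count(bin_size), bin_size >= 1)
  mode <- match.arg(mode)
  normalization <- match.arg(normalization)
  sl <- setNames(layout$chromosomes$length, layout$chromosomes$name)
  f <- lib$fragments
  if (nrow(f)) {
    bad <- !(f$chrom %in% names(sl)) | f$end > sl[f$chrom] | f$start < 0
    if (any(bad)) {
      i <- which(bad)[1]
      stop("fragment outside chromosome bounds: ", f$chrom[i], ":",
           f$start[i], "-", f$end[i])
    }
  }
  values <- lapply(names(sl), function(ch) {
    n_bins <- ceiling(sl[[ch]] / bin_size)
    v <- numeric(n_bins)
    rows <- f[f$chrom == ch, , drop = FALSE]
    if (nrow(rows) == 0L) return(v)
    w <- rows$copy_count
    if (mode == "midpoint") {
      mid <- rows$start + (rows$end - rows$start - 1L) %/% 2L  # 0-based bp
      idx <- mid %/% bin_size + 1L
      add <- tabulate_weighted(idx, w, n_bins)
      v <- v + add
    } else {
      first <- rows$start %/% bin_size + 1L
      last <- (rows$end - 1L) %/% bin_size + 1L
      # difference-array accumulation of [first, last] runs
      d <- numeric(n_bins + 1L)
      d_add <- tabulate_weighted(first, w, n_bins + 1L)
      d_sub <- tabulate_weighted(last + 1L, w, n_bins + 1L)
      v <- cumsum(d_add - d_sub)[seq_len(n_bins)]
    }
    v
  })
  names(values) <- names(sl)
  total <- sum(f$copy_count)
  if (normalization == "cpm") {
    if (total == 0) stop("cannot CPM-normalize an empty library")
    values <- lapply(values, function(v) v * 1e6 / total)
  }
  structure(list(bin_size = as.integer(bin_size), values = values,
                 normalization = normalization, mode = mode,
                 library_id = lib$library_id, chrom_lengths = sl),
            class = "coverage_track")
}

tabulate_weighted <- function(idx, w, nbins) {
  out <- numeric(nbins)
  agg <- rowsum(as.numeric(w), idx)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf(
    "coverage_track '%s': bin %d bp, %s, %s; %d bins over %d chromosomes\n",
    x$library_id, x$bin_size, x$mode, x$normalization,
    sum(lengths(x$values)), length(x$values)))
  invisible(x)
}

# bin widths for one chromosome (last bin may be short)
bin_widths <- function(chrom_length, bin_size, n_bins) {
  w <- rep.int(bin_size, n_bins)
  w[n_bins] <- chrom_length - (n_bins - 1) * bin_size
  w
}

#' Coverage track as a GRanges of bins
#'
#' @param track a `coverage_track`.
#' @param drop_zero omit zero-valued bins.
#' @return GRanges with a `score` metadata column; runs of equal value
#'   are collapsed.
#' @export
track_granges <- function(track, drop_zero = TRUE) {
  stopifnot(inherits(track, "coverage_track"))
  pieces <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    if (length(v) == 0L) return(NULL)
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths + 1L
    start1 <- (starts_bin - 1L) * track$bin_size + 1
    end1 <- pmin(ends_bin * track$bin_size, track$chrom_lengths[[ch]])
    keep <- if (drop_zero) r$values != 0 else rep(TRUE, length(r$values))
    if (!any(keep)) return(NULL)
    GRanges(ch, IRanges(start = start1[keep], end = end1[keep]),
            score = r$values[keep])
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  gr <- if (length(pieces)) do.call(c, pieces) else GRanges()
  seqlevels(gr) <- names(track$chrom_lengths)
  seqlengths(gr) <- track$chrom_lengths
  gr
}

#' Fraction of reads in peaks
#'
#' Fraction of a library's fragments overlapping any peak by at least
#' one base pair; the standard signal-to-noise proxy. By convention the
#' library should be deduplicated so fragments are molecules.
#'
#' @param lib a [fragment_library()].
#' @param peaks a [GenomicRanges::GRanges] of peaks.
#' @return proportion in \[0, 1\].
#' @export
frip <- function(lib, peaks) {
  stopifnot(inherits(lib, "fragment_library"), methods::is(peaks, "GRanges"))
  if (nrow(lib$fragments) == 0L) {
    stop("FRiP is undefined for an empty library")
  }
  gr <- fragments_granges(lib)
  mean(countOverlaps(gr, peaks, ignore.strand = TRUE) > 0)
}

#' Count fragments in regions across libraries
#'
#' Entry (r, l) is the number of fragments (molecules) of library l
#' overlapping region r by at least one base pair; a fragment spanning
#' two regions counts in both. Regions must be non-overlapping (merge
#' first with [GenomicRanges::reduce()]).
#'
#' @param libs list of [fragment_library()] objects.
#' @param regions non-overlapping [GenomicRanges::GRanges].
#' @param size_factors optional per-library positive scalars attached to
#'   the result (see [background_size_factors()]).
#' @return an object of class `count_matrix`: list with `regions`,
#'   `counts` (regions x libraries integer matrix) and `size_factors`.
#' @export
count_matrix <- function(libs, regions, size_factors = NULL) {
  stopifnot(is.list(libs), length(libs) >= 1, methods::is(regions, "GRanges"))
  if (length(regions) > 1 &&
      length(findOverlaps(regions, drop.self = TRUE)) > 0) {
    stop("regions overlap; merge them first (GenomicRanges::reduce)")
  }
  ids <- vapply(libs, function(l) l$library_id, character(1))
  counts <- matrix(0L, nrow = length(regions), ncol = length(libs),
                   dimnames = list(NULL, ids))
  for (j in seq_along(libs)) {
    counts[, j] <- countOverlaps(regions, fragments_granges(libs[[j]]),
                                 ignore.strand = TRUE)
  }
  if (!is.null(size_factors)) {
    stopifnot(length(size_factors) == length(libs), all(size_factors > 0))
    size_factors <- setNames(as.numeric(size_factors), ids)
  }
  structure(list(regions = regions, counts = counts,
                 size_factors = size_factors),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d regions x %d libraries%s\n",
              nrow(x$counts), ncol(x$counts),
              if (is.null(x$size_factors)) "" else ", with size factors"))
  invisible(x)
}

#' Background-bin median-of-ratios size factors
#'
#' Counts fragment midpoints in large background bins (default 15 kb,
#' much larger than a fragment) for every library, drops bins with a
#' zero count in any library, and takes for each library the median
#' across bins of its count divided by the bin's geometric mean across
#' libraries. This is median-of-ratios normalization computed on
#' genome-wide background rather than peaks, so depth differences are
#' measured where targeting does not reach.
#'
#' @param libs list of at least two [fragment_library()] objects.
#' @param layout a [genome_layout()].
#' @param background_bin bin width in base pairs.
#' @return named numeric vector of positive size factors.
#' @export
background_size_factors <- function(libs, layout, background_bin = 15000L) {
  stopifnot(is.list(libs), length(libs) >= 2,
            inherits(layout, "genome_layout"),
            is_count(background_bin), background_bin >= 1)
  mats <- vapply(libs, function(l) {
    tr <- fragments_to_coverage(l, layout, bin_size = background_bin,
                                mode = "midpoint", normalization = "raw")
    unlist(tr$values, use.names = FALSE)
  }, numeric(sum(ceiling(layout$chromosomes$length / background_bin))))
  keep <- rowSums(mats == 0) == 0
  if (!any(keep)) {
    stop("no background bin has nonzero counts in every library")
  }
  m <- mats[keep, , drop = FALSE]
  gm <- apply(m, 1, geometric_mean)
  sf <- apply(m / gm, 2, median)
  setNames(sf, vapply(libs, function(l) l$library_id, character(1)))
}

#' Pearson correlation of normalized counts
#'
#' Divides counts by size factors (when present) and returns the
#' library-by-library Pearson correlation matrix. Libraries with zero
#' count variance yield `NA` coefficients and are flagged via the
#' `"flagged"` attribute rather than silently reported as 0.
#'
#' @param m a [count_matrix()].
#' @return symmetric correlation matrix with unit diagonal; attribute
#'   `"flagged"` names zero-variance libraries, if any.
#' @export
correlation_matrix <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  if (ncol(m$counts) < 2 || nrow(m$counts) < 2) {
    stop("need at least two libraries and two regions")
  }
  x <- m$counts
  if (!is.null(m$size_factors)) {
    x <- sweep(x, 2, m$size_factors, "/")
  }
  flagged <- colnames(x)[apply(x, 2, function(v) var(v) == 0)]
  cc <- suppressWarnings(cor(x))
  diag(cc) <- 1
  attr(cc, "flagged") <- flagged
  cc
}
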