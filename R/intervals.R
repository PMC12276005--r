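#' Default consensus membership count
#'
#' The consensus rule keeps genomic intervals present in at least half of
#' the input libraries; for `n` libraries this is `ceiling(fraction * n)`
#' with `fraction = 0.5` by default.
#'
#' @param n_sets number of input interval sets.
#' @param fraction minimum fraction of sets an interval must appear in.
#' @return integer minimum membership count.
#' @export
#' @examples
#' consensus_min_count(8)  # 4
consensus_min_count <- function(n_sets, fraction = 0.5) {
  stopifnot(is_count(n_sets), n_sets >= 1, fraction > 0, fraction <= 1)
  as.integer(ceiling(fraction * n_sets))
}

# harmonize a list of GRanges onto shared seqlevels (union)
harmonize_sets <- function(sets) {
  lvls <- unique(unlist(lapply(sets, function(g) as.character(seqlevels(g)))))
  sl <- rep(NA_integer_, length(lvls))
  names(sl) <- lvls
  for (g in sets) {
    known <- seqlengths(g)[!is.na(seqlengths(g))]
    sl[names(known)] <- pmax(sl[names(known)], known, na.rm = TRUE)
  }
  lapply(sets, function(g) {
    seqlevels(g) <- lvls
    seqlengths(g) <- sl
    g
  })
}

#' Multi-library consensus intervals
#'
#' Partitions the genome at the union of all interval breakpoints,
#' keeps the atoms covered by at least `min_count` of the input sets
#' (each set contributing membership at most once per base pair), and
#' merges directly adjacent (book-ended) retained atoms. With
#' `min_count = 1` this is the merged union of all sets.
#'
#' @param sets non-empty list of [GenomicRanges::GRanges].
#' @param min_count minimum number of sets covering a retained base
#'   pair, between 1 and `length(sets)`.
#' @return merged [GenomicRanges::GRanges] of consensus intervals.
#' @export
#' @examples
#' a <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
#' b <- GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 250))
#' multi_consensus(list(a, b), min_count = 2)
multi_consensus <- function(sets, min_count) {
  if (!is.list(sets) || length(sets) == 0L) {
    stop("sets must be a non-empty list of GRanges")
  }
  stopifnot(all(vapply(sets, function(g) methods::is(g, "GRanges"),
                       logical(1))),
            is_count(min_count), min_count >= 1, min_count <= length(sets))
  sets <- harmonize_sets(lapply(sets, reduce))
  sl <- seqlengths(sets[[1]])
  if (anyNA(sl)) {
    # no declared lengths: use the largest end observed per chromosome
    maxend <- Reduce(pmax, lapply(sets, function(g) {
      vapply(names(sl), function(ch) {
        e <- end(g)[as.character(seqnames(g)) == ch]
        if (length(e)) max(e) else 0L
      }, numeric(1))
    }))
    sl <- ifelse(is.na(sl), maxend, sl)
  }
  covs <- lapply(sets, function(g) coverage(g, width = sl))
  total <- Reduce(`+`, covs)
  hits <- IRanges::slice(total, lower = min_count, rangesOnly = TRUE)
  gr <- GRanges(hits)
  seqlevels(gr) <- seqlevels(sets[[1]])
  seqlengths(gr) <- seqlengths(sets[[1]])
  sort(reduce(gr))
}

#' Peak-level precision, recall and F1
#'
#' Precision is the fraction of query intervals overlapping at least one
#' reference interval by >= 1 bp (a precision of 0.9 means 90% of query
#' peaks overlapped some reference peak); recall is the fraction of
#' reference intervals overlapped by at least one query interval. Each
#' interval counts once regardless of how many partners it touches. F1
#' is the harmonic mean, defined as 0 when precision + recall = 0.
#' Empty query or reference leaves the corresponding measure `NA` with a
#' `flagged` note rather than silently reporting 0.
#'
#' @param query,reference merged [GenomicRanges::GRanges].
#' @return list with `precision`, `recall`, `f1`, `n_query`,
#'   `n_reference`, and `flagged` (character vector naming undefined
#'   measures, empty when all are defined).
#' @export
precision_recall_f1 <- function(query, reference) {
  stopifnot(methods::is(query, "GRanges"), methods::is(reference, "GRanges"))
  flagged <- character()
  if (length(query) == 0L) flagged <- c(flagged, "precision")
  if (length(reference) == 0L) flagged <- c(flagged, "recall")
  precision <- if (length(query)) {
    mean(countOverlaps(query, reference, ignore.strand = TRUE) > 0)
  } else {
    NA_real_
  }
  recall <- if (length(reference)) {
    mean(countOverlaps(reference, query, ignore.strand = TRUE) > 0)
  } else {
    NA_real_
  }
  f1 <- if (length(flagged)) {
    NA_real_
  } else if (precision + recall == 0) {
    0
  } else {
    2 * precision * recall / (precision + recall)
  }
  list(precision = precision, recall = recall, f1 = f1,
       n_query = length(query), n_reference = length(reference),
       flagged = flagged)
}

#' Jaccard index of two interval sets
#'
#' Intersection base pairs divided by union base pairs; symmetric, 0 for
#' disjoint sets, 1 for identical sets. Undefined (NA, with a warning)
#' when both sets are empty.
#'
#' @param a,b [GenomicRanges::GRanges]; reduced internally.
#' @return proportion in \[0, 1\], or `NA`.
#' @export
jaccard_index <- function(a, b) {
  stopifnot(methods::is(a, "GRanges"), methods::is(b, "GRanges"))
  if (length(a) == 0L && length(b) == 0L) {
    warning("jaccard undefined for two empty sets")
    return(NA_real_)
  }
  hs <- harmonize_sets(list(reduce(a), reduce(b)))
  inter <- sum(width(GenomicRanges::intersect(hs[[1]], hs[[2]],
                                              ignore.strand = TRUE)))
  uni <- sum(width(reduce(c(hs[[1]], hs[[2]]), ignore.strand = TRUE)))
  inter / uni
}

#' Shuffle intervals onto allowed genome space
#'
#' Re-places every interval uniformly at random on the layout's
#' chromosomes, preserving its width, rejecting placements that leave
#' chromosome bounds, overlap the exclusion set (by default the
#' blacklist) or overlap an already-placed shuffled interval. Used to
#' build width-matched null interval sets for overlap statistics.
#'
#' @param x [GenomicRanges::GRanges] to shuffle.
#' @param layout a [genome_layout()].
#' @param exclude [GenomicRanges::GRanges] that shuffled intervals must
#'   avoid; defaults to the layout blacklist.
#' @param seed integer seed; the same seed reproduces the placement.
#' @param max_tries rejection-sampling attempts allowed per interval.
#' @return sorted [GenomicRanges::GRanges] with the same width multiset
#'   as `x`.
#' @export
shuffle_intervals <- function(x, layout, exclude = layout$blacklist,
                              seed = 1L, max_tries = 1000L) {
  stopifnot(methods::is(x, "GRanges"), inherits(layout, "genome_layout"),
            methods::is(exclude, "GRanges"), is_count(max_tries),
            max_tries >= 1)
  sl <- setNames(layout$chromosomes$length, layout$chromosomes$name)
  widths <- width(x)
  exclude <- reduce(exclude, ignore.strand = TRUE)
  # per-chromosome plain-vector interval tables keep the rejection loop fast
  excl <- lapply(names(sl), function(ch) {
    e <- exclude[as.character(seqnames(exclude)) == ch]
    list(start = start(e), end = end(e))
  })
  names(excl) <- names(sl)
  cum <- cumsum(sl)
  total <- sum(sl)
  with_seed(seed, {
    placed <- lapply(names(sl), function(ch) {
      list(start = numeric(), end = numeric())
    })
    names(placed) <- names(sl)
    for (i in seq_along(widths)) {
      ok <- FALSE
      for (try in seq_len(max_tries)) {
        pos <- runif(1, 0, total)
        ci <- findInterval(pos, cum) + 1L
        start1 <- floor(pos - c(0, cum)[ci]) + 1
        end1 <- start1 + widths[i] - 1
        if (end1 > sl[[ci]]) next
        ch <- names(sl)[ci]
        ex <- excl[[ch]]
        if (length(ex$start) && any(ex$start <= end1 & start1 <= ex$end)) {
          next
        }
        pl <- placed[[ch]]
        if (length(pl$start) && any(pl$start <= end1 & start1 <= pl$end)) {
          next
        }
        placed[[ch]]$start <- c(pl$start, start1)
        placed[[ch]]$end <- c(pl$end, end1)
        ok <- TRUE
        break
      }
      if (!ok) {
        stop("failed to place shuffled interval ", i, " (width ",
             widths[i], " bp) after ", max_tries, " attempts")
      }
    }
    out <- GRanges(
      rep(factor(names(sl), levels = names(sl)),
          vapply(placed, function(p) length(p$start), integer(1))),
      IRanges(start = unlist(lapply(placed, `[[`, "start")),
              end = unlist(lapply(placed, `[[`, "end"))),
      seqlengths = sl)
    sort(out)
  })
}

#' Fisher's exact test of interval-set association
#'
#' Builds a 2x2 table from interval overlaps: `n11` counts overlapping
#' a-b pairs, `n12` the a intervals touching no b interval, `n21` the b
#' intervals touching no a interval, and `n22` estimates the number of
#' genomic slots carrying neither set as
#' `round(genome bp / mean interval width) - n11 - n12 - n21` (floored at
#' 0) — the genome-segmentation heuristic used by interval-overlap Fisher
#' tests. The two-sided p-value sums hypergeometric tables at most as
#' probable as the observed one. Because `n22` is a heuristic, shuffled
#' nulls (see [shuffle_intervals()]) are the preferred significance
#' device; the Fisher p is reported alongside them.
#'
#' @param a,b non-empty merged [GenomicRanges::GRanges].
#' @param layout a [genome_layout()] supplying the genome size.
#' @return list with `table` (2x2 integer matrix) and `p` (two-sided
#'   Fisher exact p-value).
#' @export
fisher_overlap <- function(a, b, layout) {
  stopifnot(methods::is(a, "GRanges"), methods::is(b, "GRanges"),
            inherits(layout, "genome_layout"))
  if (length(a) == 0L || length(b) == 0L) {
    stop("fisher_overlap requires non-empty interval sets")
  }
  hs <- harmonize_sets(list(a, b))
  n11 <- length(findOverlaps(hs[[1]], hs[[2]], ignore.strand = TRUE))
  a_hit <- sum(countOverlaps(hs[[1]], hs[[2]], ignore.strand = TRUE) > 0)
  b_hit <- sum(countOverlaps(hs[[2]], hs[[1]], ignore.strand = TRUE) > 0)
  n12 <- length(a) - a_hit
  n21 <- length(b) - b_hit
  mean_w <- mean(width(c(granges(hs[[1]]), granges(hs[[2]]))))
  slots <- round(genome_size(layout) / mean_w)
  n22 <- max(0, slots - n11 - n12 - n21)
  tab <- matrix(as.numeric(c(n11, n12, n21, n22)), nrow = 2, byrow = TRUE,
                dimnames = list(a = c("b_overlap", "b_none"),
                                b = c("a_overlap", "a_none")))
  p <- fisher.test(tab)$p.value
  list(table = tab, p = p)
}
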