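#' Find signal blocks in a coverage track
#'
#' A signal block is a maximal run of consecutive bins with value > 0 —
#' the unit thresholded by sparse-enrichment peak calling. Each block
#' records its total area under the curve (`auc`, bin value times bin
#' width summed over the run) and maximum bin height.
#'
#' @param track a `coverage_track` (typically span mode).
#' @return data.frame sorted by coordinate with columns `chrom`, `start`,
#'   `end` (0-based half-open, bin-aligned), `auc`, `max_height`.
#' @export
#' @examples
#' layout <- genome_layout(data.frame(name = "chr1", length = 300L))
#' f <- data.frame(chrom = "chr1", start = c(60, 100, 210),
#'                 end = c(150, 150, 240), copy_count = 1L)
#' tr <- fragments_to_coverage(fragment_library(f, "toy"), layout, 50)
#' find_signal_blocks(tr)
find_signal_blocks <- function(track) {
  stopifnot(inherits(track, "coverage_track"))
  pieces <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    if (length(v) == 0L || all(v == 0)) return(NULL)
    r <- rle(v > 0)
    run_end <- cumsum(r$lengths)
    run_start <- run_end - r$lengths + 1L
    pos <- which(r$values)
    bw <- bin_widths(track$chrom_lengths[[ch]], track$bin_size, length(v))
    data.frame(
      chrom = ch,
      start = (run_start[pos] - 1L) * track$bin_size,
      end = pmin(run_end[pos] * track$bin_size, track$chrom_lengths[[ch]]),
      auc = vapply(pos, function(i) {
        idx <- run_start[i]:run_end[i]
        sum(v[idx] * bw[idx])
      }, numeric(1)),
      max_height = vapply(pos, function(i) {
        max(v[run_start[i]:run_end[i]])
      }, numeric(1)),
      stringsAsFactors = FALSE)
  })
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0L) {
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), auc = numeric(),
                      max_height = numeric()))
  }
  out <- do.call(rbind, pieces)
  out[order(match(out$chrom, names(track$chrom_lengths)), out$start), ,
      drop = FALSE]
}

blocks_to_granges <- function(blocks, chrom_lengths) {
  gr <- GRanges(blocks$chrom,
                IRanges(start = blocks$start + 1, end = blocks$end))
  if (length(gr)) {
    mcols(gr)$score <- blocks$auc
    names(gr) <- paste0("peak_", seq_along(gr))
  }
  seqlevels(gr) <- names(chrom_lengths)
  seqlengths(gr) <- chrom_lengths
  gr
}

#' Call peaks by AUC threshold (no control)
#'
#' Retains the top fraction `f` of signal blocks by AUC: with `n` blocks
#' the `k = ceiling(f * n)` highest-AUC blocks are kept, and any block
#' tied with the k-th largest AUC is kept as well. With distinct AUCs
#' this makes "top 5% of signal blocks" exact (a threshold of 0.05
#' retains exactly 50 of 1000 blocks).
#'
#' @param track a `coverage_track`.
#' @param f fraction of blocks to retain, in (0, 1].
#' @return [GenomicRanges::GRanges] of peaks with the block AUC as
#'   `score`; empty when the track has no signal.
#' @export
call_peaks_threshold <- function(track, f) {
  stopifnot(inherits(track, "coverage_track"),
            is.numeric(f), length(f) == 1L, f > 0, f <= 1)
  blocks <- find_signal_blocks(track)
  if (nrow(blocks) == 0L) {
    return(blocks_to_granges(blocks, track$chrom_lengths))
  }
  k <- ceiling(f * nrow(blocks))
  cutoff <- sort(blocks$auc, decreasing = TRUE)[k]
  blocks_to_granges(blocks[blocks$auc >= cutoff, , drop = FALSE],
                    track$chrom_lengths)
}

#' Call peaks against an untargeted control track
#'
#' Simplified control-mode sparse-enrichment calling. The control's
#' block AUCs are scaled by `s = total AUC(target) / total AUC(control)`
#' so both tracks have equal total signal. Every observed block AUC of
#' either track is a candidate threshold `t`; the retained threshold
#' maximizes the difference between the fraction of target blocks and
#' the fraction of (scaled) control blocks exceeding `t`. `"stringent"`
#' keeps target blocks above the maximizing threshold (the largest such
#' threshold under ties); `"relaxed"` uses the smallest candidate
#' achieving at least 90% of the maximum difference, so its calls are a
#' superset of the stringent calls. If no threshold separates target
#' from control (maximum difference <= 0, e.g. the control is the target
#' itself), no peaks are called.
#'
#' @param target,control `coverage_track`s with identical layout and bin
#'   size, on the same normalization.
#' @param stringency `"stringent"` or `"relaxed"`.
#' @return [GenomicRanges::GRanges] of target blocks called as peaks.
#' @export
call_peaks_control <- function(target, control,
                               stringency = c("stringent", "relaxed")) {
  stopifnot(inherits(target, "coverage_track"),
            inherits(control, "coverage_track"))
  stringency <- match.arg(stringency)
  if (target$bin_size != control$bin_size ||
      !identical(target$chrom_lengths, control$chrom_lengths)) {
    stop("target and control tracks must share layout and bin size")
  }
  tb <- find_signal_blocks(target)
  cb <- find_signal_blocks(control)
  if (nrow(tb) == 0L) return(blocks_to_granges(tb, target$chrom_lengths))
  if (nrow(cb) == 0L || sum(cb$auc) == 0) {
    stop("control track has zero total signal; use call_peaks_threshold")
  }
  s <- sum(tb$auc) / sum(cb$auc)
  c_auc <- sort(cb$auc * s)
  t_auc <- sort(tb$auc)
  candidates <- sort(unique(c(t_auc, c_auc)))
  # fraction of blocks with auc strictly above each candidate
  frac_above <- function(sorted, t) {
    (length(sorted) - findInterval(t, sorted)) / length(sorted)
  }
  d <- frac_above(t_auc, candidates) - frac_above(c_auc, candidates)
  max_d <- max(d)
  if (max_d <= 0) {
    empty <- tb[0, , drop = FALSE]
    return(blocks_to_granges(empty, target$chrom_lengths))
  }
  t_star <- if (stringency == "stringent") {
    max(candidates[d == max_d])
  } else {
    min(candidates[d >= 0.9 * max_d])
  }
  blocks_to_granges(tb[tb$auc > t_star, , drop = FALSE],
                    target$chrom_lengths)
}

#' Precision-recall sweep over peak-calling thresholds
#'
#' For each threshold fraction, calls peaks in every replicate track,
#' intersects the replicate calls into a consensus (intervals present in
#' all replicates, book-ended pieces merged) and scores the consensus
#' against a reference interval set.
#'
#' @param tracks list of replicate `coverage_track`s.
#' @param f_values numeric vector of threshold fractions in (0, 1].
#' @param reference merged [GenomicRanges::GRanges] of reference
#'   intervals (for example ground-truth G4 sites).
#' @return data.frame with columns `f`, `n_peaks`, `precision`,
#'   `recall`, `f1` (`NA` where undefined, e.g. no consensus peaks).
#' @export
threshold_sweep <- function(tracks, f_values, reference) {
  stopifnot(is.list(tracks), length(tracks) >= 1,
            is.numeric(f_values), all(f_values > 0 & f_values <= 1),
            methods::is(reference, "GRanges"))
  rows <- lapply(f_values, function(f) {
    calls <- lapply(tracks, call_peaks_threshold, f = f)
    consensus <- multi_consensus(calls, min_count = length(calls))
    pr <- precision_recall_f1(consensus, reference)
    data.frame(f = f, n_peaks = length(consensus),
               precision = pr$precision, recall = pr$recall, f1 = pr$f1)
  })
  do.call(rbind, rows)
}
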