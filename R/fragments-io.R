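#' Write a fragment library to disk
#'
#' Two plain-text formats are supported, both 0-based half-open:
#' `"bed"` writes one line per unique molecule as
#' `chrom start end copy_count`; `"bedpe"` expands each molecule to
#' `copy_count` records of
#' `chrom1 start1 end1 chrom2 start2 end2 name` with `chrom1 == chrom2`
#' and both mate intervals spanning the whole fragment, the convention
#' produced by converting name-sorted paired-end alignments.
#'
#' @param lib a [fragment_library()].
#' @param path output file path.
#' @param format `"bed"` or `"bedpe"`.
#' @return `path`, invisibly.
#' @export
write_fragments <- function(lib, path, format = c("bed", "bedpe")) {
  stopifnot(inherits(lib, "fragment_library"))
  format <- match.arg(format)
  f <- lib$fragments
  if (format == "bed") {
    out <- f
  } else {
    idx <- rep.int(seq_len(nrow(f)), f$copy_count)
    out <- data.frame(chrom1 = f$chrom[idx], start1 = f$start[idx],
                      end1 = f$end[idx], chrom2 = f$chrom[idx],
                      start2 = f$start[idx], end2 = f$end[idx],
                      name = sprintf("m%07d.%d", idx,
                                     sequence(f$copy_count)),
                      stringsAsFactors = FALSE)
  }
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a fragment library from disk
#'
#' Inverse of [write_fragments()]; the (chrom, start, end, copy_count)
#' multiset round-trips exactly in either format.
#'
#' @param path input file path.
#' @param format `"bed"` or `"bedpe"`.
#' @param library_id identifier for the library read.
#' @param targeted,deduplicated metadata flags for the new library.
#' @param layout optional [genome_layout()] for bounds validation.
#' @return a [fragment_library()].
#' @export
read_fragments <- function(path, format = c("bed", "bedpe"),
                           library_id = basename(path), targeted = FALSE,
                           deduplicated = FALSE, layout = NULL) {
  format <- match.arg(format)
  n_col <- if (format == "bed") 4L else 7L
  if (file.size(path) == 0) {
    return(fragment_library(
      data.frame(chrom = character(), start = integer(), end = integer(),
                 copy_count = integer()),
      library_id = library_id, targeted = targeted,
      deduplicated = deduplicated, layout = layout))
  }
  raw <- read.table(path, sep = "\t", header = FALSE,
                    colClasses = "character", fill = TRUE)
  if (ncol(raw) < n_col) {
    stop("expected at least ", n_col, " columns in ", format, " file: ", path)
  }
  parse_int <- function(col, what) {
    x <- suppressWarnings(as.integer(raw[[col]]))
    bad <- which(is.na(x))
    if (length(bad)) {
      stop("malformed ", what, " at line ", bad[1], " of ", path)
    }
    x
  }
  if (format == "bed") {
    f <- data.frame(chrom = raw[[1]],
                    start = parse_int(2, "start"),
                    end = parse_int(3, "end"),
                    copy_count = parse_int(4, "copy_count"),
                    stringsAsFactors = FALSE)
  } else {
    start1 <- parse_int(2, "start1")
    end2 <- parse_int(6, "end2")
    if (any(raw[[1]] != raw[[4]])) {
      stop("malformed bedpe record (chrom1 != chrom2) at line ",
           which(raw[[1]] != raw[[4]])[1], " of ", path)
    }
    key <- paste(raw[[1]], start1, end2)
    tab <- table(key)
    first <- !duplicated(key)
    f <- data.frame(chrom = raw[[1]][first], start = start1[first],
                    end = end2[first],
                    copy_count = as.integer(tab[key[first]]),
                    stringsAsFactors = FALSE)
  }
  bad <- which(f$start >= f$end)
  if (length(bad)) {
    stop("malformed record (start >= end) at line ", bad[1], " of ", path)
  }
  fragment_library(f, library_id = library_id, targeted = targeted,
                   deduplicated = deduplicated, layout = layout)
}

#' Write an interval set as BED
#'
#' @param x a [GenomicRanges::GRanges]; a `score` metadata column and
#'   names, when present, populate BED columns 5 and 4.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  stopifnot(methods::is(x, "GRanges"))
  keep <- intersect(c("name", "score"), names(mcols(x)))
  mcols(x) <- mcols(x)[, keep, drop = FALSE]
  rtracklayer::export(x, path, format = "BED")
  invisible(path)
}

#' Read a BED file as a GRanges
#'
#' @param path input path.
#' @param layout optional [genome_layout()]; when given, seqlengths are
#'   attached, bounds validated and (with `standard_only`) records on
#'   chromosomes absent from the layout dropped.
#' @param standard_only drop records on chromosomes not in the layout
#'   instead of erroring (mirrors restriction to standard chromosomes).
#' @return a sorted GRanges.
#' @export
read_bed <- function(path, layout = NULL, standard_only = FALSE) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(layout)) {
    sl <- setNames(layout$chromosomes$length, layout$chromosomes$name)
    if (standard_only) {
      gr <- gr[as.character(seqnames(gr)) %in% names(sl)]
      seqlevels(gr) <- seqlevels(gr)[seqlevels(gr) %in% names(sl)]
    }
    gr <- as_layout_granges(gr, sl, what = basename(path))
  }
  sort(gr)
}

#' Write a coverage track as bedGraph
#'
#' Runs of equal bin value are collapsed; zero-valued runs are omitted
#' from the file (the track itself retains them).
#'
#' @param track a coverage track from [fragments_to_coverage()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "coverage_track"))
  gr <- track_granges(track, drop_zero = TRUE)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}
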