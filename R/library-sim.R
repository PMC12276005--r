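#' Construct a fragment library
#'
#' A fragment library is the universal input of the pipeline: a multiset
#' of paired-end tagmentation fragments in 0-based half-open coordinates
#' with an integer `copy_count` recording how many times each unique
#' molecule was sequenced.
#'
#' @param fragments data.frame with columns `chrom` (character), `start`,
#'   `end` (0-based half-open integers, `start < end`) and `copy_count`
#'   (integer >= 1). One row per unique molecule.
#' @param library_id character identifier.
#' @param targeted logical; whether the library is target-derived.
#' @param deduplicated logical; if `TRUE` all copy counts must be 1 and
#'   all coordinates distinct.
#' @param layout optional [genome_layout()] used to validate bounds.
#' @return an object of class `fragment_library`.
#' @export
fragment_library <- function(fragments, library_id, targeted = FALSE,
                             deduplicated = FALSE, layout = NULL) {
  stopifnot(is.data.frame(fragments),
            all(c("chrom", "start", "end", "copy_count") %in% names(fragments)))
  fragments <- fragments[, c("chrom", "start", "end", "copy_count")]
  fragments$chrom <- as.character(fragments$chrom)
  fragments$start <- as.integer(fragments$start)
  fragments$end <- as.integer(fragments$end)
  fragments$copy_count <- as.integer(fragments$copy_count)
  if (nrow(fragments)) {
    if (any(fragments$start >= fragments$end)) {
      stop("fragment start must be < end")
    }
    if (any(fragments$start < 0) || any(fragments$copy_count < 1)) {
      stop("fragment coordinates must be >= 0 and copy counts >= 1")
    }
  }
  if (!is.null(layout)) {
    sl <- setNames(layout$chromosomes$length, layout$chromosomes$name)
    if (!all(fragments$chrom %in% names(sl)) ||
        any(fragments$end > sl[fragments$chrom])) {
      stop("fragments outside layout chromosome bounds")
    }
  }
  key <- paste(fragments$chrom, fragments$start, fragments$end)
  if (deduplicated &&
      (any(fragments$copy_count != 1L) || anyDuplicated(key))) {
    stop("deduplicated libraries must have distinct fragments with copy_count 1")
  }
  o <- order(fragments$chrom, fragments$start, fragments$end)
  structure(list(fragments = fragments[o, , drop = FALSE],
                 library_id = as.character(library_id),
                 targeted = isTRUE(targeted),
                 deduplicated = isTRUE(deduplicated)),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf(
    "fragment_library '%s': %d molecules, %d reads (%s%s)\n",
    x$library_id, nrow(x$fragments), total_reads(x),
    if (x$targeted) "targeted" else "untargeted",
    if (x$deduplicated) ", deduplicated" else ""))
  invisible(x)
}

#' Total read count of a library
#'
#' Sum of copy counts (sequenced reads); equals the number of molecules
#' for a deduplicated library.
#'
#' @param lib a [fragment_library()].
#' @return integer read count.
#' @export
total_reads <- function(lib) {
  stopifnot(inherits(lib, "fragment_library"))
  sum(lib$fragments$copy_count)
}

#' Number of distinct molecules observed in a library
#'
#' @param lib a [fragment_library()].
#' @return integer count of unique (chrom, start, end) fragments.
#' @export
observed_unique <- function(lib) {
  stopifnot(inherits(lib, "fragment_library"))
  f <- lib$fragments
  length(unique(paste(f$chrom, f$start, f$end)))
}

#' Fragments as a GRanges
#'
#' Converts a library's 0-based half-open fragments to 1-based closed
#' [GenomicRanges::GRanges] (one range per molecule, `copy_count` kept as
#' a metadata column).
#'
#' @param lib a [fragment_library()].
#' @param layout optional [genome_layout()] supplying seqlengths.
#' @return a GRanges.
#' @export
fragments_granges <- function(lib, layout = NULL) {
  stopifnot(inherits(lib, "fragment_library"))
  f <- lib$fragments
  gr <- GRanges(f$chrom, IRanges(start = f$start + 1L, end = f$end))
  mcols(gr)$copy_count <- f$copy_count
  if (!is.null(layout)) {
    sl <- setNames(layout$chromosomes$length, layout$chromosomes$name)
    gr <- as_layout_granges(gr, sl, what = "fragments")
  }
  gr
}

# draw fragment lengths ~ Normal(mean, sd) truncated below at 30 bp
draw_lengths <- function(n, mean, sd) {
  len <- round(rnorm(n, mean, sd))
  bad <- which(len < 30)
  guard <- 0L
  while (length(bad)) {
    len[bad] <- round(rnorm(length(bad), mean, sd))
    bad <- bad[len[bad] < 30]
    guard <- guard + 1L
    if (guard > 1000L) {  # pathological sd; clamp remainder
      len[bad] <- 30L
      break
    }
  }
  as.integer(len)
}

# allowed (non-blacklist) space per chromosome, as 0-based interval table
allowed_space <- function(layout) {
  sl <- setNames(layout$chromosomes$length, layout$chromosomes$name)
  gaps <- gaps(reduce(layout$blacklist))
  gaps <- gaps[GenomicRanges::strand(gaps) == "*"]
  if (length(layout$blacklist) == 0L) {
    gaps <- GRanges(names(sl), IRanges(1, sl), seqlengths = sl)
  }
  data.frame(chrom = as.character(seqnames(gaps)),
             start = start(gaps) - 1L,  # 0-based
             end = end(gaps),
             stringsAsFactors = FALSE)
}

#' Simulate a tagmentation fragment library
#'
#' Draws `n_unique_molecules` distinct fragments from the three-way
#' mixture described in [sim_config()], then assigns each molecule a
#' Poisson(`mean_depth_per_molecule`) number of sequencing draws;
#' molecules drawn zero times are dropped, so the observed unique count
#' is below `n_unique_molecules` for small lambda. Target-derived
#' molecules are centred on a true G4 site (chosen proportionally to its
#' capture weight) with Gaussian jitter; accessible background
#' midpoints fall uniformly within an accessible site chosen by weight;
#' the remainder falls uniformly on the non-blacklisted genome.
#'
#' @param layout a [genome_layout()].
#' @param sites a `site_map` from [simulate_genome()].
#' @param config a [sim_config()]; `config$seed` (xor `seed`) controls
#'   reproducibility.
#' @param library_id identifier for the new library.
#' @param seed optional integer overriding `config$seed`.
#' @param targeted role flag recorded on the library; defaults to
#'   whether the capture mixture is active (`config$p_target > 0`) but
#'   may be set explicitly, e.g. for a targeted arm simulated with zero
#'   capture efficiency.
#' @return a non-deduplicated [fragment_library()].
#' @export
#' @examples
#' sim <- simulate_genome(sim_config(n_accessible = 20, seed = 1))
#' cfg <- sim_config(n_accessible = 20, n_unique_molecules = 500, seed = 1)
#' lib <- simulate_library(sim$layout, sim$sites, cfg, "toy")
#' observed_unique(lib)
simulate_library <- function(layout, sites, config,
                             library_id = "lib", seed = NULL,
                             targeted = config$p_target > 0) {
  stopifnot(inherits(layout, "genome_layout"), inherits(sites, "site_map"),
            inherits(config, "sim_config"))
  if (config$p_target > 0 && length(sites$g4_true) == 0L) {
    stop("p_target > 0 but the site map has no true G4 sites")
  }
  seed <- if (is.null(seed)) config$seed else as.integer(seed)
  sl <- setNames(layout$chromosomes$length, layout$chromosomes$name)
  allowed <- allowed_space(layout)
  allowed_w <- allowed$end - allowed$start
  allowed_cum <- cumsum(allowed_w)
  acc <- sites$accessible
  acc_weight <- mcols(acc)$weight
  g4 <- sites$g4_true
  g4_weight <- if (length(g4)) {
    w <- mcols(g4)$capture_weight
    if (is.null(w)) w <- rep(1, length(g4))
    w / sum(w)
  } else {
    numeric()
  }
  n <- config$n_unique_molecules
  jitter_weights <- function(w, sd) {
    if (sd == 0 || length(w) == 0) return(w)
    w <- w * rlnorm(length(w), meanlog = -sd^2 / 2, sdlog = sd)
    w / sum(w)
  }

  draw <- function(m) {
    comp <- sample(c("target", "accessible", "uniform"), m, replace = TRUE,
                   prob = c(config$p_target,
                            (1 - config$p_target) * config$p_accessible_bg,
                            (1 - config$p_target) *
                              (1 - config$p_accessible_bg)))
    mid <- numeric(m)
    chrom <- character(m)
    i <- comp == "target"
    if (any(i)) {
      si <- sample.int(length(g4), sum(i), replace = TRUE, prob = g4_weight)
      centre <- (start(g4)[si] - 1L + end(g4)[si]) / 2
      mid[i] <- round(centre + rnorm(sum(i), 0, config$target_jitter_sd))
      chrom[i] <- as.character(seqnames(g4))[si]
    }
    i <- comp == "accessible"
    if (any(i)) {
      si <- sample.int(length(acc), sum(i), replace = TRUE, prob = acc_weight)
      mid[i] <- start(acc)[si] - 1L + floor(runif(sum(i)) * width(acc)[si])
      chrom[i] <- as.character(seqnames(acc))[si]
    }
    i <- comp == "uniform"
    if (any(i)) {
      pos <- runif(sum(i), 0, sum(allowed_w))
      ai <- findInterval(pos, allowed_cum) + 1L
      mid[i] <- allowed$start[ai] + floor(pos - c(0, allowed_cum)[ai])
      chrom[i] <- allowed$chrom[ai]
    }
    len <- draw_lengths(m, config$fragment_length_mean,
                        config$fragment_length_sd)
    start0 <- mid - len %/% 2L
    end0 <- start0 + len
    # shift fragments protruding past chromosome ends back inside
    lim <- sl[chrom]
    shift <- pmax(0, -start0) - pmax(0, end0 - lim)
    start0 <- start0 + shift
    end0 <- end0 + shift
    start0 <- pmax(start0, 0)
    end0 <- pmin(end0, lim)
    data.frame(chrom = chrom, start = as.integer(start0),
               end = as.integer(end0), stringsAsFactors = FALSE)
  }

  with_seed(stage_seed(seed, paste0("library:", library_id)), {
    # library-level replicate variability of per-site intensity
    acc_weight <- jitter_weights(acc_weight, config$site_noise_sd)
    g4_weight <- jitter_weights(g4_weight, config$site_noise_sd)
    frags <- draw(n)
    guard <- 0L
    repeat {
      key <- paste(frags$chrom, frags$start, frags$end)
      dup <- which(duplicated(key))
      if (length(dup) == 0L) break
      guard <- guard + 1L
      if (guard > 100L) {
        stop("could not draw ", n, " distinct molecules; genome or site ",
             "space too small for the requested library size")
      }
      frags[dup, ] <- draw(length(dup))
    }
    lambda <- config$mean_depth_per_molecule
    if (config$amplification_sd > 0) {
      s <- config$amplification_sd
      lambda <- lambda * rlnorm(n, meanlog = -s^2 / 2, sdlog = s)
    }
    copies <- rpois(n, lambda)
    keep <- copies > 0L
    frags <- frags[keep, , drop = FALSE]
    frags$copy_count <- as.integer(copies[keep])
    fragment_library(frags, library_id = library_id, targeted = targeted,
                     deduplicated = FALSE, layout = layout)
  })
}
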