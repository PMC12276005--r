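#' Construct a synthetic genome layout
#'
#' A genome layout holds ordered chromosome lengths and a blacklist of
#' regions excluded from simulation and shuffling, mirroring the role the
#' ENCODE blacklist plays for real assemblies.
#'
#' @param chromosomes data.frame with columns `name` (unique character)
#'   and `length` (positive integer base pairs).
#' @param blacklist [GenomicRanges::GRanges] of excluded regions, within
#'   chromosome bounds. May be empty.
#' @return an object of class `genome_layout`: a list with elements
#'   `chromosomes` (data.frame) and `blacklist` (GRanges with seqlengths).
#' @export
#' @examples
#' layout <- genome_layout(data.frame(name = "chrT", length = 10000L))
#' genome_size(layout)
genome_layout <- function(chromosomes,
                          blacklist = GenomicRanges::GRanges()) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "length") %in% names(chromosomes)))
  chromosomes$name <- as.character(chromosomes$name)
  chromosomes$length <- as.numeric(chromosomes$length)
  if (anyDuplicated(chromosomes$name)) {
    stop("chromosome names must be unique")
  }
  if (any(chromosomes$length <= 0)) {
    stop("chromosome lengths must be strictly positive")
  }
  sl <- setNames(chromosomes$length, chromosomes$name)
  blacklist <- as_layout_granges(blacklist, sl, what = "blacklist")
  structure(list(chromosomes = chromosomes, blacklist = blacklist),
            class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("genome_layout: %d chromosomes, %.1f Mb, %d blacklist regions\n",
              nrow(x$chromosomes), sum(x$chromosomes$length) / 1e6,
              length(x$blacklist)))
  invisible(x)
}

# coerce a GRanges onto the layout's seqlevels and validate bounds
as_layout_granges <- function(gr, seqlens, what = "interval set") {
  if (!methods::is(gr, "GRanges")) stop(what, " must be a GRanges")
  bad <- !(as.character(seqnames(gr)) %in% names(seqlens))
  if (any(bad)) {
    stop(what, " uses chromosomes absent from the layout: ",
         paste(unique(as.character(seqnames(gr))[bad]), collapse = ", "))
  }
  seqlevels(gr) <- names(seqlens)
  seqlengths(gr) <- seqlens
  if (any(start(gr) < 1) || any(end(gr) > seqlens[as.character(seqnames(gr))])) {
    stop(what, " contains intervals outside chromosome bounds")
  }
  sort(gr)
}

#' Total genome size of a layout
#'
#' @param layout a [genome_layout()].
#' @param exclude_blacklist if `TRUE`, subtract blacklisted base pairs.
#' @return numeric base-pair count.
#' @export
genome_size <- function(layout, exclude_blacklist = FALSE) {
  stopifnot(inherits(layout, "genome_layout"))
  total <- sum(layout$chromosomes$length)
  if (exclude_blacklist) {
    total <- total - sum(width(reduce(layout$blacklist)))
  }
  total
}

#' Default desk-scale synthetic genome
#'
#' Three chromosomes of 10 Mb with 1% of each chromosome blacklisted as
#' ten 10 kb blocks centred in successive megabases. Large enough to keep
#' simulated peaks sparse while staying fast to analyse.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in base pairs.
#' @return a [genome_layout()].
#' @export
default_genome_layout <- function(n_chrom = 3L, chrom_length = 1e7) {
  stopifnot(is_count(n_chrom), n_chrom >= 1, chrom_length >= 1e5)
  names <- paste0("chr", seq_len(n_chrom))
  n_blocks <- max(1L, floor(chrom_length * 0.01 / 1e4))
  spacing <- chrom_length / n_blocks
  starts0 <- floor((seq_len(n_blocks) - 0.5) * spacing - 5e3)  # 0-based
  bl <- GRanges(rep(names, each = n_blocks),
                IRanges(start = rep(starts0, n_chrom) + 1,
                        width = 1e4))
  genome_layout(data.frame(name = names, length = chrom_length), bl)
}

#' Simulation configuration
#'
#' Parameters of the synthetic tagmentation model. Fragments arise from a
#' three-way mixture: with probability `p_target` a molecule is captured
#' at a true target (G4) site; otherwise with probability
#' `p_accessible_bg` it is untargeted background at an accessible site
#' (chosen by accessibility weight); otherwise it falls uniformly on the
#' non-blacklisted genome. Each unique molecule is then sequenced a
#' Poisson(`mean_depth_per_molecule`) number of times and molecules with
#' zero draws are unobserved.
#'
#' @param n_accessible number of accessible (open chromatin) sites.
#' @param g4_fraction fraction of accessible sites carrying a true G4.
#' @param p_target probability a molecule is target-derived (0 for
#'   untargeted libraries).
#' @param p_accessible_bg probability a background molecule falls at an
#'   accessible site rather than uniformly on the genome.
#' @param n_unique_molecules number of unique molecules in the library.
#' @param mean_depth_per_molecule expected sequencing draws per molecule
#'   (the Poisson rate lambda; controls the PCR duplication rate).
#' @param fragment_length_mean,fragment_length_sd fragment length model
#'   in base pairs; lengths are Normal, truncated below at 30 bp.
#' @param accessible_width width of accessible sites (bp).
#' @param g4_width width of true G4 sites (bp), contained in their
#'   accessible site.
#' @param target_jitter_sd Gaussian jitter (bp) of target-derived
#'   fragment midpoints around the G4 site centre.
#' @param site_noise_sd standard deviation (log scale) of per-library
#'   multiplicative noise applied to site weights, modelling
#'   replicate-to-replicate variability of per-site capture and
#'   accessibility (0.3 corresponds to a coefficient of variation of
#'   about 30%, typical of replicate peak counts). 0 makes replicates
#'   exact statistical clones.
#' @param amplification_sd standard deviation (log scale) of an optional
#'   per-molecule log-normal amplification bias; 0 disables it, in which
#'   case the complexity estimator's sampling model is exact.
#' @param seed integer seed making the simulation reproducible.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_accessible = 50, n_unique_molecules = 1000, seed = 1)
sim_config <- function(n_accessible = 500L,
                       g4_fraction = 0.25,
                       p_target = 0,
                       p_accessible_bg = 0.7,
                       n_unique_molecules = 30000L,
                       mean_depth_per_molecule = 2,
                       fragment_length_mean = 200,
                       fragment_length_sd = 50,
                       accessible_width = 1000L,
                       g4_width = 200L,
                       target_jitter_sd = 50,
                       site_noise_sd = 0.3,
                       amplification_sd = 0,
                       seed = 1L) {
  stopifnot(is_count(n_accessible), n_accessible >= 1,
            is_prob(g4_fraction), is_prob(p_target), is_prob(p_accessible_bg),
            is_count(n_unique_molecules), n_unique_molecules >= 1,
            mean_depth_per_molecule > 0,
            fragment_length_mean >= 30, fragment_length_sd >= 0,
            is_count(accessible_width), accessible_width >= 1,
            is_count(g4_width), g4_width >= 1,
            target_jitter_sd >= 0, site_noise_sd >= 0,
            amplification_sd >= 0)
  structure(list(n_accessible = as.integer(n_accessible),
                 g4_fraction = g4_fraction,
                 p_target = p_target,
                 p_accessible_bg = p_accessible_bg,
                 n_unique_molecules = as.integer(n_unique_molecules),
                 mean_depth_per_molecule = mean_depth_per_molecule,
                 fragment_length_mean = fragment_length_mean,
                 fragment_length_sd = fragment_length_sd,
                 accessible_width = as.integer(accessible_width),
                 g4_width = as.integer(g4_width),
                 target_jitter_sd = target_jitter_sd,
                 site_noise_sd = site_noise_sd,
                 amplification_sd = amplification_sd,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a genome layout and site map
#'
#' Places `n_accessible` non-overlapping accessible sites outside the
#' blacklist, assigns each a log-normal relative accessibility weight
#' (normalized to sum to one), and flags `round(g4_fraction *
#' n_accessible)` of them as carrying a true G4: a `g4_width` interval
#' centred within the accessible site. Deterministic under
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param layout a [genome_layout()]; defaults to
#'   [default_genome_layout()].
#' @return list with elements `layout` (the input layout) and `sites`, a
#'   list of class `site_map` with `accessible` (GRanges with `weight`
#'   metadata column) and `g4_true` (GRanges).
#' @export
#' @examples
#' sim <- simulate_genome(sim_config(n_accessible = 20, seed = 7))
#' length(sim$sites$accessible)
simulate_genome <- function(config, layout = default_genome_layout()) {
  stopifnot(inherits(config, "sim_config"), inherits(layout, "genome_layout"))
  w <- config$accessible_width
  sl <- setNames(layout$chromosomes$length, layout$chromosomes$name)
  if (any(sl < w)) stop("accessible_width exceeds a chromosome length")
  with_seed(stage_seed(config$seed, "genome"), {
    placed <- GRanges()
    forbidden <- reduce(layout$blacklist)
    tries <- 0L
    max_tries <- 1000L * config$n_accessible
    cum <- cumsum(sl)
    total <- sum(sl)
    while (length(placed) < config$n_accessible) {
      need <- config$n_accessible - length(placed)
      n_draw <- max(2L * need, 32L)
      tries <- tries + n_draw
      if (tries > max_tries) {
        stop("failed to place ", config$n_accessible,
             " non-overlapping accessible sites; genome too small or ",
             "blacklist too dense")
      }
      pos <- runif(n_draw, 0, total)
      ci <- findInterval(pos, cum) + 1L
      offset <- pos - c(0, cum)[ci]
      start1 <- floor(offset) + 1
      cand <- GRanges(names(sl)[ci], IRanges(start = start1, width = w))
      cand <- cand[end(cand) <= sl[as.character(seqnames(cand))]]
      if (length(cand) == 0L) next
      cand <- cand[countOverlaps(cand, forbidden) == 0]
      cand <- cand[countOverlaps(cand, placed) == 0]
      if (length(cand) == 0L) next
      keep <- !logical(length(cand))
      self <- findOverlaps(cand, drop.self = TRUE, drop.redundant = FALSE)
      # greedy: drop later candidate of each overlapping pair
      keep[subjectHits(self)[subjectHits(self) > queryHits(self)]] <- FALSE
      cand <- cand[keep]
      cand <- head(cand, need)
      placed <- c(placed, cand)
    }
    accessible <- sort(placed)
    seqlevels(accessible) <- names(sl)
    seqlengths(accessible) <- sl
    mcols(accessible)$weight <- local({
      raw <- rlnorm(length(accessible), meanlog = 0, sdlog = 1)
      raw / sum(raw)
    })
    n_g4 <- round(config$g4_fraction * config$n_accessible)
    g4_idx <- sort(sample.int(length(accessible), n_g4))
    gw <- min(config$g4_width, w)
    g4 <- accessible[g4_idx]
    g4_start <- start(g4) + (width(g4) - gw) %/% 2L
    g4_true <- GRanges(seqnames(g4), IRanges(start = g4_start, width = gw))
    seqlevels(g4_true) <- names(sl)
    seqlengths(g4_true) <- sl
    mcols(g4_true)$accessible_index <- g4_idx
    # capture efficiency varies between G4 sites independently of local
    # accessibility (folding fraction, probe access), giving a continuum
    # of targeted enrichment strengths
    mcols(g4_true)$capture_weight <- if (n_g4 > 0) {
      raw <- rlnorm(n_g4, meanlog = 0, sdlog = 1)
      raw / sum(raw)
    } else {
      numeric()
    }
    sites <- structure(list(accessible = accessible, g4_true = g4_true),
                       class = "site_map")
    list(layout = layout, sites = sites)
  })
}

#' @export
print.site_map <- function(x, ...) {
  cat(sprintf("site_map: %d accessible sites, %d true G4 sites\n",
              length(x$accessible), length(x$g4_true)))
  invisible(x)
}
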