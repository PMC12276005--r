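#' Scenario configuration for the end-to-end synthetic experiments
#'
#' Bundles the parameters of the default synthetic study: matched
#' targeted and untargeted CUT&Tag replicate libraries sharing one
#' genome and site map, with the targeted libraries sequenced from a
#' deeper molecule pool (the depth asymmetry observed between targeted
#' G4-mapping libraries and their untargeted controls).
#'
#' @param n_targeted,n_untargeted replicate counts per group.
#' @param targeted_unique,untargeted_unique unique molecules per
#'   library; the 5:1 default encodes the depth asymmetry.
#' @param p_target targeted-capture mixture weight of targeted
#'   libraries.
#' @param f_values threshold sweep fractions.
#' @param f_headline threshold used for the headline threshold-mode vs
#'   control-mode comparison and for defining differential test regions.
#' @param stringency control-mode stringency.
#' @param bin_size coverage bin width (bp).
#' @param seed global scenario seed; all stage seeds derive from it via
#'   [stage_seed()].
#' @param ... further arguments passed to [sim_config()] (site counts,
#'   fragment model, lambda, ...).
#' @return an object of class `scenario_config`.
#' @export
scenario_config <- function(n_targeted = 3L, n_untargeted = 3L,
                            targeted_unique = 150000L,
                            untargeted_unique = 30000L,
                            p_target = 0.6,
                            f_values = c(0.001, 0.01, 0.1),
                            f_headline = 0.01,
                            stringency = "stringent",
                            bin_size = 50L,
                            seed = 1L, ...) {
  stopifnot(is_count(n_targeted), n_targeted >= 1,
            is_count(n_untargeted), n_untargeted >= 1,
            is_count(targeted_unique), is_count(untargeted_unique),
            is_prob(p_target), all(f_values > 0 & f_values <= 1),
            f_headline > 0, f_headline <= 1,
            stringency %in% c("stringent", "relaxed"),
            is_count(bin_size), bin_size >= 1)
  base <- sim_config(seed = as.integer(seed), ...)
  structure(list(n_targeted = as.integer(n_targeted),
                 n_untargeted = as.integer(n_untargeted),
                 targeted_unique = as.integer(targeted_unique),
                 untargeted_unique = as.integer(untargeted_unique),
                 p_target = p_target, f_values = f_values,
                 f_headline = f_headline, stringency = stringency,
                 bin_size = as.integer(bin_size), seed = as.integer(seed),
                 base = base),
            class = "scenario_config")
}

#' Read a scenario configuration from a YAML file
#'
#' The file may set any argument of [scenario_config()] / [sim_config()]
#' as a top-level key; unset keys keep their defaults.
#'
#' @param path YAML file path.
#' @return a `scenario_config`.
#' @export
read_scenario_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.list(raw)) stop("scenario config must be a YAML mapping: ", path)
  known <- union(names(formals(scenario_config)),
                 names(formals(sim_config)))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown scenario config keys: ", paste(bad, collapse = ", "))
  }
  do.call(scenario_config, raw)
}

# simulate the matched targeted/untargeted replicate libraries
scenario_libraries <- function(config, sim) {
  cfg_t <- config$base
  cfg_t$p_target <- config$p_target
  cfg_t$n_unique_molecules <- config$targeted_unique
  cfg_u <- config$base
  cfg_u$p_target <- 0
  cfg_u$n_unique_molecules <- config$untargeted_unique
  targeted <- lapply(seq_len(config$n_targeted), function(i) {
    simulate_library(sim$layout, sim$sites, cfg_t,
                     library_id = sprintf("targeted_%d", i),
                     seed = stage_seed(config$seed, sprintf("t%d", i)),
                     targeted = TRUE)
  })
  untargeted <- lapply(seq_len(config$n_untargeted), function(i) {
    simulate_library(sim$layout, sim$sites, cfg_u,
                     library_id = sprintf("untargeted_%d", i),
                     seed = stage_seed(config$seed, sprintf("u%d", i)),
                     targeted = FALSE)
  })
  list(targeted = targeted, untargeted = untargeted)
}

#' Run the default synthetic scenario end to end
#'
#' Simulates a genome with accessible and true-G4 sites and matched
#' targeted/untargeted replicate libraries, then reproduces the two
#' headline contrasts on them:
#'
#' * peak-calling strategy: threshold-mode peaks (top `f_headline`
#'   fraction of signal blocks per replicate, all-replicate consensus)
#'   versus control-mode peaks (each targeted replicate called against
#'   its matched untargeted control, all-replicate consensus), both
#'   benchmarked against the ground-truth G4 sites;
#' * differential-enrichment normalization: significant-up peak counts
#'   with deduplication only versus with complexity normalization
#'   (downsampling to the limiting library, then deduplication).
#'
#' All randomness derives from `config$seed`; rerunning with the same
#' config reproduces the summary exactly.
#'
#' @param config a [scenario_config()].
#' @param outdir optional directory; when given, per-stage artifacts
#'   (fragment BED files, complexity report, peak BED files, the
#'   threshold sweep and a JSON summary) are written there.
#' @return list with elements `summary` (named list: per-strategy
#'   precision/recall/F1 and peak counts against ground truth, and the
#'   two significant-up counts), `sweep` (threshold sweep data.frame),
#'   `complexity` (complexity report), `peaks` (per-strategy GRanges),
#'   `truth` (site map), `libraries` and `config`.
#' @export
run_scenario <- function(config = scenario_config(), outdir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  sim <- simulate_genome(config$base)
  libs <- scenario_libraries(config, sim)
  all_libs <- c(libs$targeted, libs$untargeted)

  complexity <- complexity_report(all_libs)

  dedup_t <- lapply(libs$targeted, deduplicate_library)
  dedup_u <- lapply(libs$untargeted, deduplicate_library)
  tracks_t <- lapply(dedup_t, fragments_to_coverage, layout = sim$layout,
                     bin_size = config$bin_size, mode = "span")
  tracks_u <- lapply(dedup_u, fragments_to_coverage, layout = sim$layout,
                     bin_size = config$bin_size, mode = "span")

  truth <- sim$sites$g4_true

  sweep <- threshold_sweep(tracks_t, config$f_values, truth)

  thr_calls <- lapply(tracks_t, call_peaks_threshold, f = config$f_headline)
  thr_consensus <- multi_consensus(thr_calls, min_count = length(thr_calls))
  pr_thr <- precision_recall_f1(thr_consensus, truth)

  n_pairs <- min(length(tracks_t), length(tracks_u))
  ctl_calls <- lapply(seq_len(n_pairs), function(i) {
    call_peaks_control(tracks_t[[i]], tracks_u[[i]],
                       stringency = config$stringency)
  })
  ctl_consensus <- multi_consensus(ctl_calls, min_count = length(ctl_calls))
  pr_ctl <- precision_recall_f1(ctl_consensus, truth)

  regions <- multi_consensus(
    c(thr_calls, lapply(tracks_u, call_peaks_threshold,
                        f = config$f_headline)),
    min_count = 1L)
  contrast <- complexity_contrast(all_libs, regions, sim$layout,
                                  seed = stage_seed(config$seed, "contrast"))

  summary <- list(
    n_true_g4 = length(truth),
    threshold = list(f = config$f_headline, n_peaks = length(thr_consensus),
                     precision = pr_thr$precision, recall = pr_thr$recall,
                     f1 = pr_thr$f1),
    control = list(stringency = config$stringency,
                   n_peaks = length(ctl_consensus),
                   precision = pr_ctl$precision, recall = pr_ctl$recall,
                   f1 = pr_ctl$f1),
    differential = list(
      n_regions = length(regions),
      n_sig_dedup_only = contrast$n_sig_dedup_only,
      n_sig_complexity_normalized = contrast$n_sig_complexity_normalized),
    seed = config$seed)

  result <- list(summary = summary, sweep = sweep, complexity = complexity,
                 peaks = list(threshold = thr_consensus,
                              control = ctl_consensus,
                              regions = regions),
                 truth = sim$sites, libraries = libs, config = config)

  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (l in all_libs) {
      write_fragments(l, file.path(outdir, paste0(l$library_id, ".bed")))
    }
    write.table(complexity, file.path(outdir, "complexity.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(sweep, file.path(outdir, "threshold_sweep.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(thr_consensus, file.path(outdir, "peaks_threshold.bed"))
    if (length(ctl_consensus)) {
      write_bed(ctl_consensus, file.path(outdir, "peaks_control.bed"))
    }
    write_bed(truth, file.path(outdir, "g4_truth.bed"))
    jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  result
}

#' Write a small deterministic fixture bundle
#'
#' Generates a toy genome with four untargeted and three targeted
#' libraries whose unique-read counts straddle a 3000-molecule
#' complexity filter, plus the ground-truth site BED files. Used by the
#' test suite; byte-identical across invocations with the same seed.
#'
#' @param dir output directory (created if needed).
#' @param seed integer seed.
#' @return named list of written file paths, invisibly; also returns
#'   the simulated objects in the `objects` element.
#' @export
make_fixtures <- function(dir, seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  layout <- default_genome_layout(n_chrom = 2L, chrom_length = 2e6)
  base <- sim_config(n_accessible = 60L, g4_fraction = 0.25,
                     n_unique_molecules = 4000L, seed = as.integer(seed))
  sim <- simulate_genome(base, layout)
  spec <- list(
    list(id = "untargeted_a", p_target = 0, n_unique = 4000L, lambda = 2),
    list(id = "untargeted_b", p_target = 0, n_unique = 4000L, lambda = 1),
    list(id = "untargeted_c", p_target = 0, n_unique = 2500L, lambda = 2),
    list(id = "untargeted_d", p_target = 0, n_unique = 1500L, lambda = 3),
    list(id = "targeted_a", p_target = 0.6, n_unique = 8000L, lambda = 2),
    list(id = "targeted_b", p_target = 0.6, n_unique = 8000L, lambda = 2),
    list(id = "targeted_c", p_target = 0.6, n_unique = 8000L, lambda = 2))
  libs <- lapply(spec, function(s) {
    cfg <- base
    cfg$p_target <- s$p_target
    cfg$n_unique_molecules <- s$n_unique
    cfg$mean_depth_per_molecule <- s$lambda
    simulate_library(sim$layout, sim$sites, cfg, library_id = s$id,
                     seed = stage_seed(seed, s$id))
  })
  paths <- c(
    lapply(libs, function(l) {
      write_fragments(l, file.path(dir, paste0(l$library_id, ".bed")))
      file.path(dir, paste0(l$library_id, ".bed"))
    }),
    list(accessible = write_bed(sim$sites$accessible,
                                file.path(dir, "accessible.bed")),
         g4_truth = write_bed(sim$sites$g4_true,
                              file.path(dir, "g4_truth.bed"))))
  names(paths)[seq_along(libs)] <- vapply(libs, function(l) l$library_id,
                                          character(1))
  invisible(list(paths = paths,
                 objects = list(layout = sim$layout, sites = sim$sites,
                                libraries = libs)))
}
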