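#' Duplication histogram of a library
#'
#' Tallies how many molecules were sequenced exactly `j` times, the input
#' of library-complexity estimation. The histogram satisfies
#' `sum(j * count_j) == total_reads(lib)` and `sum(count_j)` equals the
#' number of observed molecules.
#'
#' @param lib a [fragment_library()].
#' @return an object of class `dup_histogram`: list with `counts` (named
#'   integer vector, names the copy number `j`), `total_reads` and
#'   `observed_unique`.
#' @export
#' @examples
#' f <- data.frame(chrom = "chr1", start = c(0, 10, 20, 30),
#'                 end = c(5, 15, 25, 35), copy_count = c(1, 1, 2, 3))
#' dup_histogram(fragment_library(f, "toy"))
dup_histogram <- function(lib) {
  stopifnot(inherits(lib, "fragment_library"))
  cc <- lib$fragments$copy_count
  counts <- if (length(cc)) table(cc) else table(integer())
  counts <- setNames(as.integer(counts), names(counts))
  structure(list(counts = counts,
                 total_reads = sum(cc),
                 observed_unique = length(cc)),
            class = "dup_histogram")
}

#' @export
print.dup_histogram <- function(x, ...) {
  cat(sprintf("dup_histogram: %d reads over %d molecules (max copy %s)\n",
              x$total_reads, x$observed_unique,
              if (length(x$counts)) max(as.integer(names(x$counts))) else 0))
  invisible(x)
}

# lambda solving lambda / (1 - exp(-lambda)) = r, r > 1
ztp_lambda <- function(r) {
  stopifnot(r > 1)
  f <- function(l) l / (1 - exp(-l)) - r
  upper <- max(2 * r, 1)
  uniroot(f, lower = 1e-12, upper = upper,
          tol = .Machine$double.eps^0.75)$root
}

#' Estimate library complexity from a duplication histogram
#'
#' Models per-molecule sequencing depth as Poisson(lambda): a library of
#' N unique molecules sequenced to R total reads shows only
#' `u = N (1 - exp(-lambda))` of them, and the coupling
#' `lambda / (1 - exp(-lambda)) = R / u` identifies lambda from the mean
#' copy number of *observed* molecules (a zero-truncated Poisson mean).
#' The maximum-likelihood estimate is obtained by root finding to high
#' relative tolerance and converted to `N_hat = R / lambda_hat`, which is
#' never below the observed unique count.
#'
#' @param hist a [dup_histogram()], or a [fragment_library()] (converted
#'   internally).
#' @return an object of class `complexity_estimate`: list with
#'   `total_reads`, `observed_unique`, `estimated_unique`,
#'   `proportion_unique` (`estimated_unique / total_reads`),
#'   `lambda_hat`, and `status` (`"ok"` or `"no-duplicates"` when
#'   `R == u`, where the estimator is unbounded and `estimated_unique`
#'   falls back to the observed count with a warning).
#' @export
#' @examples
#' h <- structure(list(counts = c(`10` = 50L), total_reads = 500L,
#'                     observed_unique = 50L), class = "dup_histogram")
#' estimate_complexity(h)$lambda_hat
estimate_complexity <- function(hist) {
  if (inherits(hist, "fragment_library")) hist <- dup_histogram(hist)
  stopifnot(inherits(hist, "dup_histogram"))
  R <- hist$total_reads
  u <- hist$observed_unique
  if (u < 1) stop("cannot estimate complexity of an empty library")
  if (R < u) stop("total reads below observed unique count: invalid histogram")
  if (R == u) {
    warning("no duplicate reads observed; unique-molecule count is not ",
            "identifiable and is reported as the observed count")
    est <- list(total_reads = R, observed_unique = u, estimated_unique = u,
                proportion_unique = u / R, lambda_hat = NA_real_,
                status = "no-duplicates")
    return(structure(est, class = "complexity_estimate"))
  }
  lambda <- ztp_lambda(R / u)
  structure(list(total_reads = R, observed_unique = u,
                 estimated_unique = R / lambda,
                 proportion_unique = (R / lambda) / R,
                 lambda_hat = lambda,
                 status = "ok"),
            class = "complexity_estimate")
}

#' @export
print.complexity_estimate <- function(x, ...) {
  cat(sprintf(paste0(
    "complexity_estimate: R = %d reads, u = %d observed unique,\n",
    "  N_hat = %.1f estimated unique (lambda_hat = %s, %s)\n"),
    x$total_reads, x$observed_unique, x$estimated_unique,
    if (is.na(x$lambda_hat)) "NA" else sprintf("%.4f", x$lambda_hat),
    x$status))
  invisible(x)
}

#' Downsample a library to a target complexity
#'
#' Ratio-based thinning: every read (each copy of each molecule,
#' independently) is retained with probability
#' `p = target_unique / estimated_unique`, after which molecules losing
#' all copies disappear. This matches per-read random subsampling of a
#' non-deduplicated alignment at a fixed seed, the step used to equalize
#' complexity across libraries before deduplication.
#'
#' @param lib a non-deduplicated [fragment_library()].
#' @param target_unique desired number of unique molecules; may be
#'   fractional (estimates are), so the limiting library itself passes
#'   through unchanged at `target_unique = estimated_unique`.
#' @param estimate a `complexity_estimate` for `lib`; computed from the
#'   library when omitted.
#' @param seed integer seed.
#' @return a thinned, still non-deduplicated [fragment_library()].
#' @export
downsample_library <- function(lib, target_unique, estimate = NULL,
                               seed = 1L) {
  stopifnot(inherits(lib, "fragment_library"), is.numeric(target_unique),
            length(target_unique) == 1L, target_unique > 0)
  if (lib$deduplicated) {
    stop("downsampling applies to non-deduplicated libraries")
  }
  if (is.null(estimate)) estimate <- estimate_complexity(lib)
  stopifnot(inherits(estimate, "complexity_estimate"))
  p <- target_unique / estimate$estimated_unique
  if (p > 1) {
    stop("target_unique exceeds the estimated unique count (retention ",
         "probability ", signif(p, 4), " > 1); skip downsampling for the ",
         "limiting library instead")
  }
  if (p == 1) return(lib)
  f <- lib$fragments
  with_seed(stage_seed(seed, paste0("downsample:", lib$library_id)), {
    kept <- rbinom(nrow(f), f$copy_count, p)
    f$copy_count <- as.integer(kept)
    f <- f[f$copy_count > 0L, , drop = FALSE]
    fragment_library(f, library_id = lib$library_id,
                     targeted = lib$targeted, deduplicated = FALSE)
  })
}

#' Deduplicate a library
#'
#' Collapses reads with identical fragment endpoints (both mates, i.e.
#' exact (chrom, start, end) equality) to one molecule with
#' `copy_count = 1`. Idempotent.
#'
#' @param lib a [fragment_library()].
#' @return a deduplicated [fragment_library()].
#' @export
deduplicate_library <- function(lib) {
  stopifnot(inherits(lib, "fragment_library"))
  f <- lib$fragments
  key <- paste(f$chrom, f$start, f$end)
  f <- f[!duplicated(key), , drop = FALSE]
  f$copy_count <- rep.int(1L, nrow(f))
  fragment_library(f, library_id = lib$library_id, targeted = lib$targeted,
                   deduplicated = TRUE)
}

#' Filter libraries by minimum unique-read count
#'
#' Retains libraries whose observed unique-molecule count is at least
#' `min_unique` (the boundary is inclusive: a library with exactly
#' `min_unique` unique reads is kept). Order is preserved.
#'
#' @param libs list of [fragment_library()] objects.
#' @param min_unique minimum number of distinct molecules.
#' @return the retained sub-list.
#' @export
filter_min_unique <- function(libs, min_unique) {
  stopifnot(is.list(libs), is_count(min_unique))
  keep <- vapply(libs, function(l) observed_unique(l) >= min_unique,
                 logical(1))
  libs[keep]
}

#' Complexity report for a set of libraries
#'
#' @param libs list of non-deduplicated [fragment_library()] objects.
#' @return data.frame with one row per library: `library_id`,
#'   `total_reads`, `observed_unique`, `estimated_unique`,
#'   `proportion_unique`, `lambda_hat`.
#' @export
complexity_report <- function(libs) {
  stopifnot(is.list(libs), length(libs) >= 1)
  rows <- lapply(libs, function(l) {
    e <- estimate_complexity(l)
    data.frame(library_id = l$library_id, total_reads = e$total_reads,
               observed_unique = e$observed_unique,
               estimated_unique = e$estimated_unique,
               proportion_unique = e$proportion_unique,
               lambda_hat = e$lambda_hat, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
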