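#' Negative-binomial Wald test for differential enrichment at peaks
#'
#' Tests, per peak, whether normalized fragment counts increase in
#' targeted relative to untargeted libraries. Counts are divided by
#' size factors (from [background_size_factors()]; all 1 when absent,
#' with a warning). A per-peak negative-binomial dispersion is estimated
#' by method of moments from the pooled within-group variance of the
#' normalized counts and shrunk halfway to the median dispersion across
#' peaks (floored at 1e-8) to stabilize small-replicate estimates. The
#' Wald statistic is the log2 fold change of group means (pseudo-count
#' 0.5) divided by its delta-method standard error under the NB variance
#' `mu + phi mu^2`, referred to a standard normal two-sidedly;
#' Benjamini-Hochberg adjustment is applied across all peaks.
#'
#' Peaks with all-zero counts in both groups keep `log2FC = 0`,
#' `p = 1` so the row count of the result always matches the peak count.
#'
#' @param cm a [count_matrix()] whose columns are the libraries.
#' @param group character/factor of `"targeted"` / `"untargeted"` labels
#'   per library (targeted is the fold-change numerator). One library
#'   per group is allowed but warned against: there is no within-group
#'   dispersion information.
#' @param alpha FDR threshold used for the significance counts.
#' @return an object of class `diff_result`: list with `table`
#'   (data.frame: `chrom`, `start`, `end` 0-based half-open,
#'   `mean_norm_count`, `log2_fold_change`, `p_value`, `fdr`),
#'   `n_significant_up` (fdr < alpha and log2FC > 0),
#'   `n_significant_total` (fdr < alpha, either direction) and `alpha`.
#' @export
nb_differential <- function(cm, group, alpha = 0.05) {
  stopifnot(inherits(cm, "count_matrix"))
  group <- as.character(group)
  stopifnot(length(group) == ncol(cm$counts),
            all(group %in% c("targeted", "untargeted")))
  if (!all(c("targeted", "untargeted") %in% group)) {
    stop("need at least one library in each group")
  }
  if (min(table(group)) < 2) {
    warning("a group has a single library; dispersion is estimated ",
            "without within-group replication for it")
  }
  if (is.null(cm$size_factors)) {
    warning("count matrix has no size factors; using 1 for every library")
    sf <- rep(1, ncol(cm$counts))
  } else {
    sf <- cm$size_factors
  }
  counts <- cm$counts
  n_peak <- nrow(counts)
  coords <- if (length(cm$regions)) {
    data.frame(chrom = as.character(seqnames(cm$regions)),
               start = start(cm$regions) - 1L, end = end(cm$regions),
               stringsAsFactors = FALSE)
  } else {
    data.frame(chrom = character(), start = integer(), end = integer())
  }
  if (n_peak == 0L) {
    tab <- cbind(coords,
                 data.frame(mean_norm_count = numeric(),
                            log2_fold_change = numeric(),
                            p_value = numeric(), fdr = numeric()))
    return(structure(list(table = tab, n_significant_up = 0L,
                          n_significant_total = 0L, alpha = alpha),
                     class = "diff_result"))
  }
  x <- sweep(counts, 2, sf, "/")
  tgt <- group == "targeted"
  n_t <- sum(tgt)
  n_u <- sum(!tgt)
  mu_t <- rowMeans(x[, tgt, drop = FALSE])
  mu_u <- rowMeans(x[, !tgt, drop = FALSE])
  mu <- rowMeans(x)
  # pooled within-group variance (method of moments for the NB)
  ss <- rowSums((x[, tgt, drop = FALSE] - mu_t)^2) +
    rowSums((x[, !tgt, drop = FALSE] - mu_u)^2)
  df <- max(n_t + n_u - 2L, 1L)
  s2 <- ss / df
  phi_raw <- ifelse(mu > 0, pmax((s2 - mu) / mu^2, 0), 0)
  informative <- mu > 0
  # shrink halfway to the mean dispersion: the per-peak moment estimate
  # is right-skewed at few replicates, so the mean (not the median) is
  # the approximately unbiased pooled summary and keeps the Wald test
  # calibrated near its nominal level
  phi_pool <- if (any(informative)) mean(phi_raw[informative]) else 0
  phi <- pmax(0.5 * phi_raw + 0.5 * phi_pool, 1e-8)
  lfc <- log2((mu_t + 0.5) / (mu_u + 0.5))
  var_t <- (mu_t + phi * mu_t^2) / n_t
  var_u <- (mu_u + phi * mu_u^2) / n_u
  se <- sqrt(var_t / (mu_t + 0.5)^2 + var_u / (mu_u + 0.5)^2) / log(2)
  z <- ifelse(se > 0, lfc / se, 0)
  p <- 2 * pnorm(-abs(z))
  zero <- mu_t == 0 & mu_u == 0
  lfc[zero] <- 0
  p[zero] <- 1
  fdr <- p.adjust(p, method = "BH")
  tab <- cbind(coords,
               data.frame(mean_norm_count = mu, log2_fold_change = lfc,
                          p_value = p, fdr = fdr))
  structure(list(table = tab,
                 n_significant_up = sum(fdr < alpha & lfc > 0),
                 n_significant_total = sum(fdr < alpha),
                 alpha = alpha),
            class = "diff_result")
}

#' @export
print.diff_result <- function(x, ...) {
  cat(sprintf(paste0(
    "diff_result: %d peaks tested; %d significant (FDR < %g), ",
    "%d with positive fold change\n"),
    nrow(x$table), x$n_significant_total, x$alpha, x$n_significant_up))
  invisible(x)
}

#' MA table of a differential result
#'
#' One row per peak with the log2 mean normalized concentration
#' (pseudo-count 0.5), the log2 fold change, and the significance flag
#' (`fdr < alpha`) used to highlight points on an MA plot.
#'
#' @param result a `diff_result` from [nb_differential()].
#' @return data.frame with columns `log2_mean_conc`, `log2_fold_change`,
#'   `significant`.
#' @export
ma_table <- function(result) {
  stopifnot(inherits(result, "diff_result"))
  t <- result$table
  data.frame(log2_mean_conc = log2(t$mean_norm_count + 0.5),
             log2_fold_change = t$log2_fold_change,
             significant = t$fdr < result$alpha)
}

#' Differential significance with and without complexity normalization
#'
#' Runs the differential test twice on the same libraries and regions:
#' once after deduplication only, and once after first downsampling every
#' library to a common estimated unique-molecule count (the limiting
#' library's, unless given) and then deduplicating. When targeted
#' libraries are much deeper than their untargeted controls, the
#' dedup-only branch retains that depth advantage as extra power, while
#' the complexity-normalized branch removes it — the mechanism by which
#' complexity normalization collapses the number of significant peaks.
#'
#' @param libs list of non-deduplicated [fragment_library()] objects;
#'   each library's `targeted` flag assigns its group.
#' @param regions merged [GenomicRanges::GRanges] of peaks to test.
#' @param layout a [genome_layout()] for background size factors.
#' @param target_unique unique-molecule count to downsample to; default
#'   is the smallest estimated unique count among `libs`.
#' @param seed integer seed for the downsampling stage.
#' @param alpha FDR threshold.
#' @return list with `n_sig_dedup_only`, `n_sig_complexity_normalized`
#'   (significant-up counts) and the two full `diff_result`s
#'   (`dedup_only`, `complexity_normalized`).
#' @export
complexity_contrast <- function(libs, regions, layout, target_unique = NULL,
                                seed = 1L, alpha = 0.05) {
  stopifnot(is.list(libs), length(libs) >= 2,
            methods::is(regions, "GRanges"),
            inherits(layout, "genome_layout"))
  if (any(vapply(libs, function(l) l$deduplicated, logical(1)))) {
    stop("complexity_contrast needs non-deduplicated libraries")
  }
  group <- ifelse(vapply(libs, function(l) l$targeted, logical(1)),
                  "targeted", "untargeted")
  run_branch <- function(branch_libs) {
    dedup <- lapply(branch_libs, deduplicate_library)
    sf <- background_size_factors(dedup, layout)
    cm <- count_matrix(dedup, regions, size_factors = sf)
    nb_differential(cm, group, alpha = alpha)
  }
  if (length(regions) == 0L) {
    empty <- run_branch(libs)
    return(list(n_sig_dedup_only = 0L, n_sig_complexity_normalized = 0L,
                dedup_only = empty, complexity_normalized = empty))
  }
  estimates <- lapply(libs, estimate_complexity)
  if (is.null(target_unique)) {
    target_unique <- floor(min(vapply(estimates, `[[`, numeric(1),
                                      "estimated_unique")))
  }
  res_dedup <- run_branch(libs)
  down <- Map(function(l, e) {
    downsample_library(l, min(target_unique, floor(e$estimated_unique)),
                       estimate = e, seed = seed)
  }, libs, estimates)
  res_norm <- run_branch(down)
  list(n_sig_dedup_only = res_dedup$n_significant_up,
       n_sig_complexity_normalized = res_norm$n_significant_up,
       dedup_only = res_dedup, complexity_normalized = res_norm)
}
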