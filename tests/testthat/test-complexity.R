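ztp_pmf <- function(j, lambda) {
  exp(j * log(lambda) - lambda - lgamma(j + 1)) / (1 - exp(-lambda))
}

# independent bisection for lambda / (1 - exp(-lambda)) = r
bisect_lambda <- function(r, lo = 1e-9, hi = 100) {
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (mid / (1 - exp(-mid)) < r) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

test_that("duplication histograms tally copy counts exactly", {
  lib <- lib_from_table("chr1", c(0, 10, 20, 30), c(5, 15, 25, 35),
                        copy = c(1L, 1L, 2L, 3L))
  h <- dup_histogram(lib)
  expect_identical(h$counts, c(`1` = 2L, `2` = 1L, `3` = 1L))
  expect_equal(h$total_reads, 7)
  expect_equal(h$observed_unique, 4)
  expect_equal(sum(as.integer(names(h$counts)) * h$counts), h$total_reads)

  dd <- deduplicate_library(lib)
  expect_identical(dup_histogram(dd)$counts, c(`1` = 4L))

  h0 <- dup_histogram(lib_from_table(character(), integer(), integer()))
  expect_equal(h0$observed_unique, 0)
})

test_that("simulated copy counts follow the zero-truncated Poisson", {
  sim <- simulate_genome(sim_config(n_accessible = 50, seed = 21))
  cfg <- sim_config(n_accessible = 50, n_unique_molecules = 10000,
                    mean_depth_per_molecule = 2, seed = 21)
  lib <- simulate_library(sim$layout, sim$sites, cfg, "ztp")
  h <- dup_histogram(lib)
  j <- as.integer(names(h$counts))
  # pool the tail so expected cell counts stay comfortable
  jmax <- 7L
  obs <- c(h$counts[j < jmax], sum(h$counts[j >= jmax]))
  probs <- c(ztp_pmf(seq_len(jmax - 1), 2),
             1 - sum(ztp_pmf(seq_len(jmax - 1), 2)))
  gof <- suppressWarnings(chisq.test(obs, p = probs))
  expect_gt(gof$p.value, 0.01)
})

test_that("complexity estimation inverts the truncated-Poisson coupling", {
  sat <- structure(list(counts = c(`10` = 50L), total_reads = 500,
                        observed_unique = 50), class = "dup_histogram")
  e <- estimate_complexity(sat)
  expect_equal(e$lambda_hat, 10, tolerance = 1e-3)
  expect_equal(e$estimated_unique, 50, tolerance = 1e-3)

  h <- structure(list(counts = c(`1` = 0L), total_reads = 20000,
                      observed_unique = 8647), class = "dup_histogram")
  e2 <- estimate_complexity(h)
  lam_oracle <- bisect_lambda(20000 / 8647)
  expect_equal(e2$lambda_hat, lam_oracle, tolerance = 1e-9)
  expect_equal(e2$lambda_hat, 2, tolerance = 2e-3)
  expect_equal(e2$estimated_unique, 10000, tolerance = 0.005 * 10000)
  # the defining equation holds to high precision
  expect_equal(e2$lambda_hat / (1 - exp(-e2$lambda_hat)), 20000 / 8647,
               tolerance = 1e-10)
  expect_gte(e2$estimated_unique, e2$observed_unique)
})

test_that("degenerate histograms are handled explicitly", {
  nodup <- structure(list(counts = c(`1` = 100L), total_reads = 100,
                          observed_unique = 100), class = "dup_histogram")
  expect_warning(e <- estimate_complexity(nodup), "no duplicate")
  expect_equal(e$estimated_unique, 100)
  expect_equal(e$status, "no-duplicates")

  bad <- structure(list(counts = c(`1` = 5L), total_reads = 3,
                        observed_unique = 5), class = "dup_histogram")
  expect_error(estimate_complexity(bad), "invalid histogram")
})

test_that("estimated unique count is monotone in the duplication rate", {
  u <- 5000
  ests <- vapply(c(1.1, 1.5, 2, 3, 5), function(ratio) {
    h <- structure(list(counts = integer(), total_reads = round(u * ratio),
                        observed_unique = u), class = "dup_histogram")
    estimate_complexity(h)$estimated_unique
  }, numeric(1))
  expect_true(all(diff(ests) < 0))
})

test_that("downsampling follows the thinning model", {
  sim <- simulate_genome(sim_config(n_accessible = 50, seed = 31))
  cfg <- sim_config(n_accessible = 50, n_unique_molecules = 10000,
                    mean_depth_per_molecule = 2, seed = 31)
  lib <- simulate_library(sim$layout, sim$sites, cfg, "thin")
  est <- estimate_complexity(lib)

  # identity at p = 1
  same <- downsample_library(lib, est$estimated_unique, est)
  expect_identical(same$fragments, lib$fragments)

  # p > 1 is refused with advice
  expect_error(downsample_library(lib, 10 * floor(est$estimated_unique), est),
               "limiting library")

  # thinned-Poisson expectation: N (1 - exp(-p * lambda)) at p = 1/2
  half <- downsample_library(lib, round(est$estimated_unique / 2), est,
                             seed = 7)
  expected <- 10000 * (1 - exp(-0.5 * 2))
  expect_lt(abs(observed_unique(half) - expected) / expected, 0.02)
  expect_false(half$deduplicated)
})

test_that("deduplication keys on exact endpoints and is idempotent", {
  lib <- lib_from_table("chr1", c(0, 100, 200), c(50, 150, 250),
                        copy = c(3L, 2L, 1L))
  dd <- deduplicate_library(lib)
  expect_equal(nrow(dd$fragments), 3)
  expect_true(all(dd$fragments$copy_count == 1))
  expect_true(dd$deduplicated)
  expect_identical(deduplicate_library(dd)$fragments, dd$fragments)

  # same start, different end: distinct molecules
  ends <- lib_from_table("chr1", c(0, 0), c(50, 60))
  expect_equal(nrow(deduplicate_library(ends)$fragments), 2)
})

test_that("the minimum-unique filter is boundary-inclusive", {
  mk <- function(n, id) {
    lib_from_table("chr1", seq_len(n) * 10L, seq_len(n) * 10L + 5L, id = id)
  }
  libs <- list(mk(250, "a"), mk(300, "b"), mk(900, "c"))
  kept <- filter_min_unique(libs, 300)
  expect_equal(vapply(kept, function(l) l$library_id, ""), c("b", "c"))
  expect_length(filter_min_unique(libs, 0), 3)
  expect_length(filter_min_unique(list(), 100), 0)
})

test_that("downsampling equalizes libraries of unequal complexity", {
  # ratio-based read thinning equalizes the unique reads present in the
  # files in the low-duplication regime the procedure is designed for
  # (observed unique ~ lambda x target on both sides as lambda -> 0)
  sim <- simulate_genome(sim_config(n_accessible = 50, seed = 41))
  mk <- function(n, seed, id) {
    cfg <- sim_config(n_accessible = 50, n_unique_molecules = n,
                      mean_depth_per_molecule = 0.15, seed = seed)
    simulate_library(sim$layout, sim$sites, cfg, id)
  }
  big <- mk(50000, 41, "big")
  small <- mk(15000, 42, "small")
  e_big <- estimate_complexity(big)
  e_small <- estimate_complexity(small)
  target <- floor(min(e_big$estimated_unique, e_small$estimated_unique))
  u1 <- observed_unique(deduplicate_library(
    downsample_library(big, target, e_big, seed = 1)))
  u2 <- observed_unique(deduplicate_library(
    downsample_library(small, target, e_small, seed = 1)))
  expect_lt(abs(u1 - u2) / max(u1, u2), 0.10)
})

test_that("the complexity report covers every library", {
  sim <- simulate_genome(sim_config(n_accessible = 30, seed = 51))
  cfg <- sim_config(n_accessible = 30, n_unique_molecules = 1000, seed = 51)
  libs <- list(simulate_library(sim$layout, sim$sites, cfg, "a"),
               simulate_library(sim$layout, sim$sites, cfg, "b", seed = 52))
  rep <- complexity_report(libs)
  expect_equal(rep$library_id, c("a", "b"))
  expect_true(all(rep$estimated_unique >= rep$observed_unique))
})
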