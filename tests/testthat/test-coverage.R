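toy_layout <- genome_layout(data.frame(name = c("chr1", "chr2"),
                                       length = c(1000L, 600L)))

test_that("span and midpoint binning place fragments correctly", {
  lib <- lib_from_table("chr1", 100L, 260L)
  span <- fragments_to_coverage(lib, toy_layout, 50, "span")
  expect_equal(span$values$chr1, c(0, 0, 1, 1, 1, 1, rep(0, 14)))

  midp <- fragments_to_coverage(lib, toy_layout, 50, "midpoint")
  expect_equal(which(midp$values$chr1 > 0), 4L)  # midpoint 179 -> bin [150,200)

  # copy counts weight the signal
  dup <- lib_from_table("chr1", 100L, 260L, copy = 3L)
  expect_equal(max(fragments_to_coverage(dup, toy_layout, 50,
                                         "midpoint")$values$chr1), 3)
})

test_that("CPM normalization conserves one million total in midpoint mode", {
  lib <- lib_from_table("chr1", c(0, 100, 200, 300), c(60, 160, 260, 360))
  cpm <- fragments_to_coverage(lib, toy_layout, 50, "midpoint", "cpm")
  occupied <- cpm$values$chr1[cpm$values$chr1 > 0]
  expect_equal(unname(occupied), rep(250000, 4))
  expect_equal(sum(unlist(cpm$values)), 1e6, tolerance = 1e-6)

  # property: conservation holds for arbitrary libraries
  set.seed(33)
  for (i in 1:5) {
    start <- sample.int(900, 50, replace = TRUE)
    rnd <- lib_from_table(sample(c("chr1", "chr2"), 50, TRUE,
                                 prob = c(0.7, 0.3)),
                          pmin(start, 500), pmin(start, 500) + 40L,
                          copy = sample.int(3, 50, TRUE))
    tr <- fragments_to_coverage(rnd, toy_layout, 37, "midpoint", "cpm")
    expect_equal(sum(unlist(tr$values)), 1e6, tolerance = 1e-6)
  }
})

test_that("fragments outside the layout are reported by name", {
  lib <- lib_from_table("chr2", 550L, 700L)
  expect_error(fragments_to_coverage(lib, toy_layout, 50),
               "chr2:550-700")
})

test_that("FRiP matches a brute-force overlap scan", {
  peaks <- GRanges("chr1", IRanges(c(101, 501), width = 100))
  inside <- lib_from_table("chr1", c(110L, 520L), c(150L, 560L))
  expect_equal(frip(inside, peaks), 1)
  outside <- lib_from_table("chr1", c(300L, 700L), c(350L, 750L))
  expect_equal(frip(outside, peaks), 0)

  set.seed(7)
  start <- sample.int(900, 100, replace = TRUE)
  rnd <- lib_from_table("chr1", start, start + 30L)
  got <- frip(rnd, peaks)
  want <- mean(vapply(start, function(s) {
    any(overlaps1(s + 1, s + 30, start(peaks), end(peaks)))
  }, logical(1)))
  expect_equal(got, want)

  whole <- GRanges("chr1", IRanges(1, 1000))
  expect_equal(frip(rnd, whole), 1)
  # monotone under union
  expect_gte(frip(rnd, c(peaks, GRanges("chr1", IRanges(801, 900)))),
             frip(rnd, peaks))

  empty <- lib_from_table(character(), integer(), integer())
  expect_error(frip(empty, peaks), "empty")
})

test_that("count matrices agree with the brute-force double loop", {
  expect_equal(nrow(count_matrix(list(lib_from_table("chr1", 1L, 10L)),
                                 GRanges())$counts), 0L)

  whole <- GRanges(c("chr1", "chr2"), IRanges(1, c(1000, 600)))
  set.seed(11)
  libs <- lapply(1:3, function(i) {
    start <- sample.int(500, 60, replace = TRUE)
    lib_from_table(sample(c("chr1", "chr2"), 60, TRUE), start, start + 25L,
                   id = paste0("l", i))
  })
  cm <- count_matrix(libs, whole)
  for (i in 1:3) {
    expect_equal(unname(colSums(cm$counts))[i], 60)
    perchrom <- table(factor(libs[[i]]$fragments$chrom,
                             c("chr1", "chr2")))
    expect_equal(unname(cm$counts[, i]), as.vector(perchrom))
  }

  regions <- reduce(GRanges("chr1", IRanges(c(1, 201, 401), width = 100)))
  cm2 <- count_matrix(libs, regions)
  for (l in seq_along(libs)) {
    f <- libs[[l]]$fragments
    brute <- vapply(seq_along(regions), function(r) {
      sum(f$chrom == as.character(seqnames(regions))[r] &
            overlaps1(f$start + 1, f$end, start(regions)[r],
                      end(regions)[r]))
    }, numeric(1))
    expect_equal(unname(cm2$counts[, l]), as.integer(brute))
  }

  overlapping <- GRanges("chr1", IRanges(c(1, 50), width = 100))
  expect_error(count_matrix(libs, overlapping), "merge")
})

test_that("background size factors recover known depth ratios", {
  set.seed(13)
  start <- sample.int(900, 400, replace = TRUE)
  a <- lib_from_table("chr1", start, start + 30L, id = "a")
  same <- lib_from_table("chr1", start, start + 30L, id = "a2")
  sf <- background_size_factors(list(a, same), toy_layout,
                                background_bin = 100)
  expect_equal(unname(sf), c(1, 1), tolerance = 1e-12)

  doubled <- lib_from_table("chr1", start, start + 30L, copy = 2L, id = "b")
  sf2 <- background_size_factors(list(a, doubled), toy_layout,
                                 background_bin = 100)
  expect_equal(unname(sf2[2] / sf2[1]), 2, tolerance = 1e-12)

  # 1x / 2x / 4x subsamples of one molecule set give proportional factors
  sim <- simulate_genome(sim_config(n_accessible = 50, seed = 13))
  cfg <- sim_config(n_accessible = 50, n_unique_molecules = 40000,
                    mean_depth_per_molecule = 5, seed = 13)
  base <- simulate_library(sim$layout, sim$sites, cfg, "base")
  est <- estimate_complexity(base)
  quarter <- downsample_library(base, round(est$estimated_unique / 4),
                                est, seed = 2)
  half <- downsample_library(base, round(est$estimated_unique / 2),
                             est, seed = 3)
  sf3 <- background_size_factors(list(quarter, half, base), sim$layout)
  ratios <- unname(sf3 / sf3[1])
  expect_equal(ratios[2], 2, tolerance = 0.05 * 2)
  expect_equal(ratios[3], 4, tolerance = 0.05 * 4)

  empty1 <- lib_from_table("chr1", 1L, 10L)
  empty2 <- lib_from_table("chr2", 1L, 10L)
  expect_error(background_size_factors(list(empty1, empty2), toy_layout),
               "no background bin")
})

test_that("correlation matrices behave like Pearson correlation", {
  counts <- cbind(a = c(10L, 20L, 30L), b = c(20L, 40L, 60L),
                  c = c(5L, 50L, 20L))
  cm <- cm_from_counts(counts)
  cc <- correlation_matrix(cm)
  expect_equal(diag(cc), setNames(rep(1, 3), colnames(cc)))
  expect_equal(cc["lib1", "lib2"], 1)  # exact scaling
  # hand-computed Pearson for the third column against the first
  x <- counts[, 1]; y <- counts[, 3]
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(cc["lib1", "lib3"], hand, tolerance = 1e-12)
  expect_true(isSymmetric(unclass(cc)))

  flat <- cm_from_counts(cbind(c(5L, 5L, 5L), c(1L, 2L, 3L)))
  cf <- correlation_matrix(flat)
  expect_equal(attr(cf, "flagged"), "lib1")
  expect_true(is.na(cf["lib1", "lib2"]))
})

test_that("bedGraph round-trips collapse runs but preserve values", {
  lib <- lib_from_table("chr1", c(100L, 100L, 300L), c(200L, 200L, 420L))
  tr <- fragments_to_coverage(lib, toy_layout, 50, "span")
  path <- tempfile(fileext = ".bedGraph")
  write_bedgraph(tr, path)
  back <- rtracklayer::import(path, format = "bedGraph")
  expect_equal(sum(width(back) * back$score),
               sum(unlist(tr$values) * 50))
  expect_true(all(back$score > 0))
})
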