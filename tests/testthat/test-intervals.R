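layout10k <- genome_layout(data.frame(name = "chr1", length = 10000L))

test_that("the default consensus rule is the 50% membership rule", {
  expect_equal(consensus_min_count(8), 4L)
  expect_equal(consensus_min_count(5), 3L)
  expect_equal(consensus_min_count(8, fraction = 1), 8L)
})

test_that("consensus membership counting matches the per-bp oracle", {
  shared <- GRanges("chr1", IRanges(101, 200))
  others <- lapply(1:4, function(k) GRanges("chr1",
                                            IRanges(k * 1000 + 1, width = 50)))
  sets <- list(c(others[[1]], shared), c(others[[2]], shared),
               others[[3]], others[[4]])
  cons <- multi_consensus(sets, 2)
  expect_equal(length(findOverlaps(shared, cons)), 1L)

  # min_count = 1 is the merged union
  u <- multi_consensus(sets, 1)
  expect_identical(granges(u), granges(reduce(do.call(c, sets))))

  set.seed(37)
  for (i in 1:10) {
    sets5 <- lapply(1:5, function(k) reduce(random_intervals(8)))
    for (k in c(1, 2, 3, 5)) {
      cons <- multi_consensus(sets5, k)
      got <- integer(0)
      for (j in seq_along(cons)) {
        got <- c(got, start(cons)[j]:end(cons)[j])
      }
      expect_identical(got, brute_consensus_bp(sets5, k))
    }
    # nesting in min_count as base-pair sets
    c3 <- multi_consensus(sets5, 3)
    c2 <- multi_consensus(sets5, 2)
    expect_equal(sum(width(GenomicRanges::setdiff(c3, c2))), 0)
  }

  expect_error(multi_consensus(list(), 1), "non-empty")
})

test_that("precision and recall follow their peak-counting definitions", {
  reference <- GRanges("chr1", IRanges(seq(1, by = 1000, length.out = 10),
                                       width = 100))
  query <- c(shift(reference[1:9], 50),  # 9 of 10 queries overlap
             GRanges("chr1", IRanges(950, width = 20)))
  pr <- precision_recall_f1(query, reference)
  expect_equal(pr$precision, 0.9)
  expect_equal(pr$recall, 0.9)

  # 8 of 10 reference peaks overlapped
  query2 <- shift(reference[1:8], 50)
  pr2 <- precision_recall_f1(query2, reference)
  expect_equal(pr2$precision, 1)
  expect_equal(pr2$recall, 0.8)

  pr3 <- precision_recall_f1(reference, reference)
  expect_equal(c(pr3$precision, pr3$recall, pr3$f1), c(1, 1, 1))

  pr4 <- precision_recall_f1(GRanges(), reference)
  expect_true(is.na(pr4$precision))
  expect_equal(pr4$flagged, "precision")
  pr5 <- precision_recall_f1(reference, GRanges())
  expect_equal(pr5$flagged, "recall")

  disjoint <- shift(reference, 500)
  pr6 <- precision_recall_f1(disjoint, reference)
  expect_equal(pr6$f1, 0)
})

test_that("jaccard is exact base-pair arithmetic and symmetric", {
  a <- GRanges("chr1", IRanges(1, 100))
  b <- GRanges("chr1", IRanges(51, 150))
  expect_equal(jaccard_index(a, b), 50 / 150)
  expect_equal(jaccard_index(a, a), 1)
  expect_equal(jaccard_index(a, shift(a, 1000)), 0)

  set.seed(41)
  for (i in 1:10) {
    x <- random_intervals(20)
    y <- random_intervals(20)
    expect_identical(jaccard_index(x, y), jaccard_index(y, x))
  }
  expect_warning(j <- jaccard_index(GRanges(), GRanges()), "undefined")
  expect_true(is.na(j))
})

test_that("shuffling preserves widths and avoids exclusions", {
  set.seed(43)
  x <- reduce(random_intervals(30, genome_bp = 9000))
  exclude <- GRanges("chr1", IRanges(c(1, 5001), width = 500))
  sh <- shuffle_intervals(x, layout10k, exclude, seed = 5)
  expect_equal(sort(width(sh)), sort(width(x)))
  # brute-force pairwise scans: no overlap with exclusions, no self-overlap
  for (i in seq_along(sh)) {
    expect_false(any(overlaps1(start(sh)[i], end(sh)[i], start(exclude),
                               end(exclude))))
    others <- setdiff(seq_along(sh), i)
    expect_false(any(overlaps1(start(sh)[i], end(sh)[i],
                               start(sh)[others], end(sh)[others])))
  }
  expect_identical(shuffle_intervals(x, layout10k, exclude, seed = 5), sh)
  expect_false(identical(shuffle_intervals(x, layout10k, exclude, seed = 6),
                         sh))

  # an impossible placement is reported
  blockall <- GRanges("chr1", IRanges(1, 9999))
  expect_error(shuffle_intervals(x[1], layout10k, blockall, max_tries = 25),
               "failed to place")
})

# exhaustive hypergeometric enumeration of the two-sided Fisher p
brute_fisher_p <- function(tab) {
  m <- tab[1, 1] + tab[1, 2]
  n <- tab[2, 1] + tab[2, 2]
  k <- tab[1, 1] + tab[2, 1]
  support <- max(0, k - n):min(k, m)
  probs <- dhyper(support, m, n, k)
  p_obs <- dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

test_that("fisher association matches exact enumeration on its own table", {
  a <- GRanges("chr1", IRanges(c(101, 301, 501, 701, 901, 2001),
                               width = 50))
  b <- GRanges("chr1", IRanges(c(121, 321, 521, 721, 921, 4001),
                               width = 50))
  res <- fisher_overlap(a, b, layout10k)
  expect_equal(res$table[1, 1], 5)
  expect_equal(res$table[1, 2], 1)
  expect_equal(res$table[2, 1], 1)
  expect_equal(res$p, brute_fisher_p(res$table), tolerance = 1e-10)

  same <- fisher_overlap(a, a, layout10k)
  expect_equal(same$table[1, 2], 0)
  expect_equal(same$table[2, 1], 0)
  expect_lt(same$p, res$p)

  expect_error(fisher_overlap(GRanges(), b, layout10k), "non-empty")
})

test_that("fisher association separates real overlap from shuffled nulls", {
  # the genome-segmentation n22 slot count is a heuristic, so the null
  # p-value distribution is only approximate; what the statistic must do
  # is discriminate: a genuinely associated pair scores below every
  # width-matched shuffled pair, and null pairs never look overwhelming
  set.seed(47)
  big <- genome_layout(data.frame(name = "chr1", length = 200000L))
  base <- GRanges("chr1", IRanges(seq(1, by = 150, length.out = 25),
                                  width = 100))
  ps <- vapply(1:200, function(s) {
    a <- shuffle_intervals(base, big, GRanges(), seed = 2 * s)
    b <- shuffle_intervals(base, big, GRanges(), seed = 2 * s + 1)
    fisher_overlap(a, b, big)$p
  }, numeric(1))
  expect_equal(mean(ps < 1e-6), 0)

  a <- shuffle_intervals(base, big, GRanges(), seed = 991)
  p_assoc <- fisher_overlap(a, shift(a, 40), big)$p
  expect_lt(p_assoc, min(ps))
})
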