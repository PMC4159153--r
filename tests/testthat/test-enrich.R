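# Enhancer-overlap binomial enrichment, greedy 25-kb binning, chromatin
# interaction counting and empirical ranking.

test_that("overlap flags follow half-open BED semantics", {
  track <- data.frame(chrom = "1", start = 99L, end = 101L, name = "iv1")
  snps <- data.frame(chrom = "1", pos = c(99L, 100L, 101L, 102L))
  got <- overlapFlags(snps, track)
  # [99,101) covers 1-based positions 100 and 101
  expect_identical(got, c(FALSE, TRUE, TRUE, FALSE))

  # random fixture against the brute-force double loop
  set.seed(127)
  snps2 <- data.frame(chrom = sample(c("1", "2"), 300, TRUE),
                      pos = sample.int(1e5, 300))
  track2 <- data.frame(chrom = sample(c("1", "2"), 40, TRUE),
                       start = sample.int(9e4, 40))
  track2$end <- track2$start + sample.int(3000, 40)
  track2$name <- paste0("e", 1:40)
  track2 <- track2[order(track2$chrom, track2$start), ]
  expect_identical(overlapFlags(snps2, track2), naiveOverlap(snps2, track2))
  # unsorted track warns and still agrees
  shuffled <- track2[sample(nrow(track2)), ]
  expect_warning(got2 <- overlapFlags(snps2, shuffled), "sort")
  expect_identical(got2, naiveOverlap(snps2, track2))
})

test_that("binomial enrichment reproduces reported folds and the exact
           tail", {
  # observed 11 of 42 tagged vs expected 2.1: fold 5.2
  e <- enrichmentTest(42, 11, 2.1 / 42, cellType = "K562")
  expect_equal(e$fold, 5.2)
  expect_equal(e$expected, 2.1, tolerance = 1e-12)
  # other printed-fold arithmetic: 7/2.2 -> 3.2, 5/0.6 -> 8.3, 7/2.7 -> 2.6
  expect_equal(enrichmentTest(42, 7, 2.2 / 42)$fold, 3.2)
  expect_equal(enrichmentTest(42, 5, 0.6 / 42)$fold, 8.3)
  expect_equal(enrichmentTest(42, 7, 2.7 / 42)$fold, 2.6)

  # exact binomial tail vs an independent lchoose summation oracle
  f <- 2.1 / 42
  for (obs in c(0, 1, 3, 11, 20, 42)) {
    tail <- sum(exp(lchoose(42, obs:42) + (obs:42) * log(f) +
                      (42 - obs:42) * log(1 - f)))
    expect_equal(enrichmentTest(42, obs, f)$p, tail, tolerance = 1e-12)
  }
  # monotone decreasing P in observed
  ps <- vapply(0:42, function(o) enrichmentTest(42, o, f)$p, numeric(1))
  expect_true(all(diff(ps) < 0))
  # null-consistent observation
  e0 <- enrichmentTest(100, 10, 0.1)
  expect_equal(e0$fold, 1.0)
  expect_gt(e0$p, 0.3)
  expect_error(enrichmentTest(10, 2, 0), "frequency")
})

test_that("end-to-end enhancer enrichment detects planted overlap excess", {
  map <- simulateMap(400, spanBp = 2e6, seed = 131)
  ann <- simulateAnnotations(map, enhancerDensity = 0.05, chiapetRate = 0,
                             seed = 131)
  bg <- map[, c("chrom", "pos")]
  inEnh <- overlapFlags(bg, ann$enhancers)
  # tagged set biased toward enhancers
  tagIdx <- c(which(inEnh)[1:10], which(!inEnh)[1:20])
  res <- enhancerEnrichment(bg[tagIdx, ], bg,
                            tracks = list(cellA = ann$enhancers))
  expect_gt(res$fold, 2)
  expect_lt(res$p, 0.01)
})

test_that("greedy binning follows the left-to-right 25-kb rule", {
  one <- binSnps(data.frame(chrom = "1", pos = 500L))
  expect_equal(nrow(one), 1)
  expect_equal(one$n_snps, 1)

  two <- binSnps(data.frame(chrom = "1", pos = c(0L, 30000L)))
  expect_equal(nrow(two), 2)

  onebin <- binSnps(data.frame(chrom = "1", pos = c(0L, 10000L, 24999L)))
  expect_equal(nrow(onebin), 1)
  expect_equal(onebin$n_snps, 3)
  # boundary: a SNP at exactly first + 25000 starts a new region
  edge <- binSnps(data.frame(chrom = "1", pos = c(0L, 25000L)))
  expect_equal(nrow(edge), 2)

  # partition property: every SNP in exactly one region
  set.seed(137)
  pos <- sort(sample.int(5e5, 300))
  bins <- binSnps(data.frame(chrom = "1", pos = pos))
  expect_equal(sum(bins$n_snps), 300)
  expect_true(all(bins$start[-1] >= head(bins$start + 25000, -1)))
})

test_that("chromatin interaction counts match the brute-force loop", {
  map <- simulateMap(200, spanBp = 2e6, seed = 139)
  ann <- simulateAnnotations(map, enhancerDensity = 0.02, chiapetRate = 30,
                             seed = 139)
  bins <- binSnps(map[, c("chrom", "pos")])
  got <- countChiaPet(bins, ann$interactions)
  expect_identical(got$chiapet_count,
                   naiveChiaPetCounts(bins, ann$interactions))

  # direct constructions
  b1 <- data.frame(chrom = "1", start = 0, end = 25000, midpoint = 12500,
                   n_snps = 1)
  near <- data.frame(chrom1 = "1", start1 = 12000, end1 = 13000,
                     chrom2 = "1", start2 = 500000, end2 = 501000)
  far <- data.frame(chrom1 = "1", start1 = 300000, end1 = 301000,
                    chrom2 = "1", start2 = 500000, end2 = 501000)
  five <- do.call(rbind, replicate(5, near, simplify = FALSE))
  expect_equal(countChiaPet(b1, near)$chiapet_count, 1L)
  expect_equal(countChiaPet(b1, far)$chiapet_count, 0L)
  expect_equal(countChiaPet(b1, five)$chiapet_count, 5L)
  # malformed rows are skipped with a warning
  bad <- rbind(near, data.frame(chrom1 = "1", start1 = 10, end1 = 5,
                                chrom2 = "1", start2 = 1, end2 = 2))
  expect_warning(cnt <- countChiaPet(b1, bad), "malformed")
  expect_equal(cnt$chiapet_count, 1L)
})

test_that("empirical rank uses strict inequality", {
  bins <- data.frame(chrom = "1", start = (0:9) * 25000,
                     end = (1:10) * 25000, midpoint = (0:9) * 25000 + 12500,
                     n_snps = 1, chiapet_count = c(5L, 9L, 2L, 9L, 1L,
                                                   0L, 3L, 9L, 4L, 6L))
  # focal has the maximum: fraction 0
  rk <- empiricalRank(bins, which.max(bins$chiapet_count))
  expect_equal(rk$fraction, 0)
  # all equal: strict > gives 0
  bins2 <- bins; bins2$chiapet_count <- 3L
  expect_equal(empiricalRank(bins2, 1)$fraction, 0)
  # order-statistics behaviour on Poisson counts
  set.seed(141)
  bins3 <- bins[rep(1, 2000), ]
  bins3$chiapet_count <- rpois(2000, 5)
  q99 <- quantile(bins3$chiapet_count, 0.99, type = 1)
  focal <- which(bins3$chiapet_count == q99)[1]
  fr <- empiricalRank(bins3, focal)$fraction
  expect_lt(fr, 0.03)
  expect_equal(fr, mean(bins3$chiapet_count > bins3$chiapet_count[focal]))
})
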