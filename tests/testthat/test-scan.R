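# Threshold derivation, bit-plane encoding, the screening F test vs the
# exact full-model test, LD, the marginal score scan and classification.

test_that("Bonferroni thresholds match direct arithmetic", {
  th <- deriveThresholds(514662, 166)
  expect_equal(signif(th@tFull, 2), 3.8e-13)
  expect_equal(signif(th@tMarginal, 2), 5.9e-10)
  expect_equal(th@tFull, 0.05 / (514662 * 514661 / 2))
  expect_equal(th@tMarginal, 0.05 / (514661 * 166))

  th2 <- deriveThresholds(2, 1)
  expect_equal(th2@tFull, 0.05)
  expect_equal(th2@tMarginal, 0.05)

  th3 <- deriveThresholds(1000, 10)
  expect_equal(th3@tFull, 0.05 / (1000 * 999 / 2))
  expect_equal(th3@tFull, 1.001e-07, tolerance = 1e-4)
  expect_equal(th3@tMarginal, 5.005e-06, tolerance = 1e-4)

  # k = 0: marginal threshold undefined, flagged absent
  expect_true(is.na(deriveThresholds(1000, 0)@tMarginal))
  # monotonicity at GWAS-like scale
  th4 <- deriveThresholds(2000, 5)
  expect_true(th4@tFull < th4@tMarginal && th4@tMarginal < th4@tLocal)
})

test_that("bitwise encoding is lossless and popcounts match counts", {
  set.seed(61)
  co <- nullCohort(n = 137, m = 25, seed = 61, missingRate = 0.05)
  gd <- co$gd
  bitg <- encodeBitwise(gd)
  expect_identical(unname(decodeBitwise(bitg)), unname(genotypes(gd)))
  pc <- bitPlaneCounts(bitg)
  g <- genotypes(gd)
  expect_equal(unname(pc["g0", ]), unname(colSums(g == 0L, na.rm = TRUE)))
  expect_equal(unname(pc["g1", ]), unname(colSums(g == 1L, na.rm = TRUE)))
  expect_equal(unname(pc["g2", ]), unname(colSums(g == 2L, na.rm = TRUE)))
  expect_equal(unname(pc["called", ]), unname(colSums(!is.na(g))))
  # planes disjoint and unioning to the called mask
  expect_equal(colSums(pc[1:3, ]), pc["called", ], ignore_attr = TRUE)
})

test_that("plane ANDs reproduce the 9-cell contingency of a pair", {
  co <- nullCohort(n = 211, m = 12, seed = 67, missingRate = 0.08)
  y <- rnorm(211)
  bitg <- encodeBitwise(co$gd)
  g <- genotypes(co$gd)
  for (pair in list(c(1, 2), c(3, 11), c(5, 6))) {
    got <- pairCellCounts(bitg, pair[1], pair[2], y)
    oracle <- naiveCellCounts(g[, pair[1]], g[, pair[2]], y)
    expect_equal(unname(got$counts), unname(oracle$counts))
    expect_equal(unname(got$sums), unname(oracle$sums), tolerance = 1e-10)
    expect_equal(unname(got$sumsq), unname(oracle$sumsq), tolerance = 1e-10)
    expect_equal(got$n, oracle$n)
  }
})

test_that("screening equals the exact full-model test on complete data", {
  co <- nullCohort(n = 400, m = 30, seed = 71)
  y <- rnorm(400)
  bitg <- encodeBitwise(co$gd)
  idx <- pairIndices(markerMap(co$gd), "all")
  scr <- pairScreen(bitg, y, idx)
  g <- genotypes(co$gd)
  sel <- sample(nrow(scr), 60)
  for (k in sel) {
    full <- pairFullTest(g[, scr$idx1[k]], g[, scr$idx2[k]], y)
    expect_equal(scr$p_screen[k], full$p, tolerance = 1e-10)
    expect_equal(scr$df1[k], full$df1)
  }
  # constant trait: F = 0, p = 1 everywhere
  scr0 <- pairScreen(bitg, rep(2.5, 400), idx)
  expect_true(all(scr0$F == 0))
  expect_true(all(scr0$p_screen == 1))
})

test_that("screening tracks the exact test closely under missingness", {
  co <- nullCohort(n = 500, m = 25, seed = 73, missingRate = 0.05)
  y <- rnorm(500)
  bitg <- encodeBitwise(co$gd)
  idx <- pairIndices(markerMap(co$gd), "all")
  scr <- pairScreen(bitg, y, idx)
  g <- genotypes(co$gd)
  for (k in sample(nrow(scr), 40)) {
    full <- pairFullTest(g[, scr$idx1[k]], g[, scr$idx2[k]], y)$p
    expect_lt(abs(log10(scr$p_screen[k]) - log10(full)), 0.3)
  }
})

test_that("full-model interaction test matches hand-computed balanced ANOVA", {
  # balanced fabricated 3x3 layout, 4 observations per cell
  cells <- expand.grid(g1 = 0:2, g2 = 0:2)
  mu <- c(1, 2, 3, 2, 3, 4, 3, 4, 6)  # interaction in the (2,2) corner
  g1 <- rep(cells$g1, each = 4); g2 <- rep(cells$g2, each = 4)
  set.seed(79)
  eps <- rep(c(-0.3, -0.1, 0.1, 0.3), times = 9)  # zero-mean within cells
  y <- rep(mu, each = 4) + eps
  res <- pairFullTest(g1, g2, y)
  # textbook sums of squares
  av <- anova(lm(y ~ factor(g1) * factor(g2)))
  expect_equal(res$F, av["factor(g1):factor(g2)", "F value"],
               tolerance = 1e-10)
  expect_equal(res$p, av["factor(g1):factor(g2)", "Pr(>F)"],
               tolerance = 1e-12)
  expect_equal(res$df1, 4)

  # orthogonal background covariate barely changes P at large n
  set.seed(80)
  n <- 3000
  G1 <- sample(0:2, n, TRUE); G2 <- sample(0:2, n, TRUE)
  yy <- rnorm(n) + 0.2 * (G1 == 1 & G2 == 1)
  bgc <- rnorm(n)
  p0 <- pairFullTest(G1, G2, yy)$p
  p1 <- pairFullTest(G1, G2, yy, background = cbind(bgc))$p
  expect_equal(log10(p0), log10(p1), tolerance = 0.05)
})

test_that("marginal score scan equals OLS under identity covariance and is
           calibrated under the null", {
  co <- nullCohort(n = 600, m = 120, seed = 83)
  y <- rnorm(600)
  fit <- fitPolygenic(y, NULL, K = NULL)
  res <- marginalScan(fit, co$gd)
  g <- genotypes(co$gd)
  r <- pgResiduals(fit)
  # OLS score-test oracle per SNP
  for (j in sample(ncol(g), 20)) {
    gc <- g[, j] - mean(g[, j])
    stat <- sum(gc * r)^2 / (sum(gc^2) * sum(varianceComponents(fit)))
    expect_equal(res$stat[j], stat, tolerance = 1e-8)
  }
  # null P-values are uniform
  ks <- suppressWarnings(stats::ks.test(res$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("a strongly associated SNP is flagged marginal", {
  co <- simulateCohort(nSamples = 2000, nSnps = 60, seed = 87)
  map <- markerMap(co$gdComplete)
  g <- genotypes(co$gdComplete)
  p <- mean(g[, 30]) / 2
  a <- plantedAdditiveEffect(p, 0.045)
  co2 <- simulateCohort(nSamples = 2000, nSnps = 60,
                        spec = effectSpec(
                          marginal = data.frame(snp_id = map$snp_id[30],
                                                a = a)),
                        seed = 87)
  fit <- fitPolygenic(co2$pheno$trait, NULL, K = NULL)
  res <- marginalScan(fit, co2$gdComplete)
  expect_true(res$marginal[30])
})

test_that("composite LD matches fixtures of known r2", {
  set.seed(91)
  x <- sample(0:2, 500, TRUE)
  expect_equal(ldR2(x, x), 1)
  # haplotype-frequency fixture built to r2 = 0.23
  target <- 0.23
  pA <- 0.4; pB <- 0.5
  D <- sqrt(target * pA * (1 - pA) * pB * (1 - pB))
  hf <- c((1 - pA) * (1 - pB) + D, (1 - pA) * pB - D,
          pA * (1 - pB) - D, pA * pB + D)
  expect_equal(hapFreqR2(hf), 0.23, tolerance = 1e-12)
  fx <- genotypesFromHaplotypeFreqs(9000, hf, seed = 92)
  expect_lt(abs(ldR2(fx$g1, fx$g2) - 0.23), 0.02)
  # independent SNPs: E[r2] ~ 1/n
  r2null <- replicate(200, {
    a <- rbinom(300, 2, 0.3); b <- rbinom(300, 2, 0.3)
    suppressWarnings(ldR2(a, b))
  })
  expect_lt(abs(mean(r2null, na.rm = TRUE) - 1 / 300), 2e-3)
  expect_warning(ldR2(rep(0L, 10), sample(0:2, 10, TRUE)), "monomorphic")
})

test_that("pair classification applies distance and threshold rules", {
  map <- data.frame(
    snp_id = c("rs731069", "rs10939766", "rsX", "rsY"),
    chrom = c("4", "4", "4", "7"),
    pos = c(10152431L, 10204970L, 11204971L, 500L),
    allele_ref = "A", allele_alt = "C")
  th <- deriveThresholds(514662, 166)
  pairs <- data.frame(
    snp1 = c("rs731069", "rs731069", "rs731069", "rs731069"),
    snp2 = c("rs10939766", "rsX", "rsY", "rs10939766"),
    p_full = c(1.5e-02, 1e-06, 1e-06, 1e-14))
  res <- classifyPairs(pairs, th, marginalSnps = "rs731069", map)
  hasSnp <- function(d, s) d$snp1 == s | d$snp2 == s
  # distance from the printed positions: 52.5 kb
  r1 <- res[hasSnp(res, "rs10939766") & res$p_full == 1.5e-02, ]
  expect_equal(r1$dist_kb, 52.5)
  # 1 052 540 bp apart with p = 1e-6: beyond the inclusive 1 Mb bound
  r2 <- res[hasSnp(res, "rsX"), ]
  expect_equal(r2$category, "")
  # cross-chromosome: no distance
  expect_true(is.na(res$dist_kb[hasSnp(res, "rsY")]))
  # genome-wide pair is also local (52.5 kb, P < 1e-5) and marginal
  r4 <- res[res$p_full == 1e-14, ]
  expect_setequal(strsplit(r4$category, ",")[[1]],
                  c("genomewide", "marginal_pair", "local"))

  # exact boundary: 1 000 001 bp apart is NOT local; 1 000 000 is
  mapB <- data.frame(snp_id = c("a", "b", "c"), chrom = "1",
                     pos = c(1L, 1000001L, 1000002L),
                     allele_ref = "A", allele_alt = "C")
  pb <- data.frame(snp1 = c("a", "a"), snp2 = c("b", "c"),
                   p_full = c(1e-06, 1e-06))
  resB <- classifyPairs(pb, th, character(), mapB)
  expect_equal(resB$category[resB$snp2 == "b"], "local")
  expect_equal(resB$category[resB$snp2 == "c"], "")
  # same position convention: dist 0.0 (not constructible under a strictly
  # increasing map; adjacent 1 bp rounds to 0.0)
  expect_equal(resB$dist_kb[2], 1000.0)
})

test_that("scan output is independent of pair input order", {
  co <- nullCohort(n = 300, m = 20, seed = 97)
  y <- rnorm(300)
  th <- deriveThresholds(20, 0)
  s1 <- scanPairs(co$gd, y, th, mode = "local", pMax = 1)
  s2 <- scanPairs(co$gd, y, th, mode = "local", pMax = 1)
  expect_identical(s1$snp1, s2$snp1)
  expect_true(all(s1$snp1 < s1$snp2))
  expect_true(all(diff(order(s1$chr1, s1$pos1, s1$pos2)) > 0))
})
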