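# Synthetic cohort generator: frequency conservation, LD decay, relatedness,
# variance bookkeeping and determinism.

test_that("allele frequencies are conserved and LD decays with distance", {
  map <- simulateMap(200, spanBp = 2e6, seed = 3)
  panel <- simulateHaplotypes(2000, map, ldDecayBp = 5e4, seed = 3)
  # frequency conservation: realized freq within binomial error of drawn freq
  realized <- colMeans(panel$h)
  se <- sqrt(panel$freq * (1 - panel$freq) / 2000)
  expect_true(mean(abs(realized - panel$freq) < 4 * se) > 0.95)

  # empirical r2 per distance bin, against an independent per-bin oracle
  m <- nrow(map)
  i <- rep(1:(m - 1), times = 3)
  j <- pmin(i + rep(1:3, each = m - 1), m)
  keep <- j > i
  i <- i[keep]; j <- j[keep]
  d <- map$pos[j] - map$pos[i]
  r2 <- vapply(seq_along(i), function(k) {
    suppressWarnings(cor(panel$h[, i[k]], panel$h[, j[k]])^2)
  }, numeric(1))
  ok <- !is.na(r2)
  bins <- cut(d[ok], c(0, 2e4, 6e4, Inf))
  mr2 <- tapply(r2[ok], bins, mean)
  expect_true(all(diff(mr2) < 0))

  # independence limit: ldDecayBp -> 0 gives only the 1/n null bias
  panel0 <- simulateHaplotypes(2000, map, ldDecayBp = 0, seed = 4)
  r2adj <- vapply(1:(m - 1), function(k) {
    suppressWarnings(cor(panel0$h[, k], panel0$h[, k + 1])^2)
  }, numeric(1))
  expect_lt(mean(r2adj, na.rm = TRUE), 3 / 2000)

  # near-zero distance with a slow kernel: near-perfect copying
  map2 <- data.frame(snp_id = c("a", "b"), chrom = "1", pos = c(100L, 101L),
                     allele_ref = "A", allele_alt = "C")
  p2 <- simulateHaplotypes(500, map2, ldDecayBp = 1e12,
                           mafRange = c(0.3, 0.300001), seed = 5)
  expect_gt(cor(p2$h[, 1], p2$h[, 2])^2, 0.99)
})

test_that("haplotype simulation rejects non-increasing positions", {
  badMap <- data.frame(snp_id = c("a", "b"), chrom = "1", pos = c(5L, 5L),
                       allele_ref = "A", allele_alt = "C")
  expect_error(simulateHaplotypes(10, badMap), "strictly increasing")
})

test_that("genotypes follow HWE and sib pairs show expected relatedness", {
  map <- simulateMap(120, seed = 9)
  panel <- simulateHaplotypes(3000, map, ldDecayBp = 0,
                              mafRange = c(0.29, 0.31), seed = 9)
  gd <- simulateGenotypes(panel, 600, nFamilies = 5, seed = 9)
  g <- genotypes(gd)
  # HWE at MAF ~0.3: genotype frequencies near 0.49/0.42/0.09
  gf <- c(mean(g == 0L), mean(g == 1L), mean(g == 2L))
  expect_equal(gf, c(0.49, 0.42, 0.09), tolerance = 0.05)
  # dosage/2 matches panel frequency
  expect_equal(unname(colMeans(g) / 2), panel$freq, tolerance = 0.06)

  K <- genomicKinship(gd)
  sib <- attr(gd, "sibPairs")
  sibK <- K[sib]
  unrelK <- K[upper.tri(K)][sample.int(sum(upper.tri(K)), 2000)]
  # identity-by-descent bookkeeping oracle: a pair sharing s parental
  # haplotypes has realized GRM-scale relatedness s/2 (expectation 0.5,
  # i.e. kinship coefficient 0.25)
  ibd <- attr(gd, "sibIbd")
  expect_true(all(abs(sibK - ibd / 2) < 4 / sqrt(120)))
  expect_equal(mean(ibd) / 2, 0.5, tolerance = 0.5)  # 5 families, coarse
  expect_lt(abs(mean(unrelK)), 0.03)

  gd0 <- simulateGenotypes(panel, 400, nFamilies = 0, seed = 10)
  K0 <- genomicKinship(gd0)
  expect_lt(abs(mean(K0[upper.tri(K0)])), 0.02)
})

test_that("phenotype variance bookkeeping matches the effect specification", {
  co <- simulateCohort(nSamples = 4000, nSnps = 150,
                       spec = effectSpec(h2Poly = 0.3, sigmaE = 1),
                       seed = 21)
  comp <- attr(co$pheno, "components")
  # polygenic variance: sigmaG2 = 0.3/0.7 * 1
  expect_equal(var(comp$polygenic), 0.3 / 0.7, tolerance = 0.1)
  expect_equal(var(comp$noise), 1, tolerance = 0.1)

  # planted additive fraction recovered by closed-form R2
  map <- markerMap(co$gdComplete)
  snp <- map$snp_id[75]
  p <- mean(genotypes(co$gdComplete)[, 75]) / 2
  a <- plantedAdditiveEffect(p, 0.045, baseVar = 1)
  # same cohort seed: identical genotypes, so the closed-form effect size
  # refers to the realized allele frequency
  co2 <- simulateCohort(nSamples = 4000, nSnps = 150,
                        spec = effectSpec(
                          marginal = data.frame(snp_id = snp, a = a),
                          sigmaE = 1),
                        seed = 21)
  y <- co2$pheno$trait
  x <- genotypes(co2$gdComplete)[, snp]
  expect_lt(abs(summary(lm(y ~ x))$r.squared - 0.045), 0.015)
})

test_that("pure interaction effects carry no marginal association", {
  map <- simulateMap(10, seed = 30)
  panel <- simulateHaplotypes(4000, map, ldDecayBp = 0,
                              mafRange = c(0.45, 0.5), seed = 30)
  gd <- simulateGenotypes(panel, 3000, seed = 30)
  s <- markerMap(gd)$snp_id[c(2, 7)]
  p1 <- mean(genotypes(gd)[, 2]) / 2; p2 <- mean(genotypes(gd)[, 7]) / 2
  ce <- centeredEpistasisMatrix(xorEffectMatrix(0.5), p1, p2)
  co <- simulatePhenotype(gd, effectSpec(
    epistatic = list(list(snps = s, M = ce$M)), sigmaE = 1), seed = 31)
  y <- co$trait
  g <- genotypes(gd)
  # marginal fits are null; 9-cell ANOVA interaction is extreme
  pm1 <- summary(lm(y ~ g[, 2]))$coefficients[2, 4]
  pm2 <- summary(lm(y ~ g[, 7]))$coefficients[2, 4]
  expect_gt(pm1, 1e-3)
  expect_gt(pm2, 1e-3)
  pint <- pairFullTest(g[, 2], g[, 7], y)$p
  expect_lt(pint, 1e-10)
  # closed-form planted interaction variance
  expect_equal(ce$varInt, var(attr(co, "components")$epistatic),
               tolerance = 0.03)
})

test_that("annotation tracks respect density and degenerate inputs", {
  map <- simulateMap(100, spanBp = 1e6, seed = 40)
  ann <- simulateAnnotations(map, enhancerDensity = 0.1, chiapetRate = 20,
                             seed = 40)
  covered <- sum(ann$enhancers$end - ann$enhancers$start)
  span <- max(map$pos) - min(map$pos) + 1
  expect_equal(covered / span, 0.1, tolerance = 0.02)
  expect_true(all(diff(ann$enhancers$start) > 0))

  empty <- simulateAnnotations(map, enhancerDensity = 0, chiapetRate = 5,
                               seed = 41)
  expect_equal(nrow(empty$enhancers), 0)
  expect_false(any(overlapFlags(map[, c("chrom", "pos")], empty$enhancers)))
  expect_error(simulateAnnotations(map[0, ], 0.1, 5), "empty")
})

test_that("identical seeds give bit-identical cohorts", {
  a <- simulateCohort(nSamples = 50, nSnps = 20, seed = 99,
                      missingRate = 0.02)
  b <- simulateCohort(nSamples = 50, nSnps = 20, seed = 99,
                      missingRate = 0.02)
  expect_identical(genotypes(a$gd), genotypes(b$gd))
  expect_identical(a$pheno$trait, b$pheno$trait)
  c <- simulateCohort(nSamples = 50, nSnps = 20, seed = 100,
                      missingRate = 0.02)
  expect_false(identical(a$pheno$trait, c$pheno$trait))
})
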