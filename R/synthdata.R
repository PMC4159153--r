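# Synthetic cohorts: LD-structured haplotypes, optional sib pairs, planted
# marginal/epistatic effects, a polygenic background of stated heritability,
# covariates, and synthetic regulatory annotation tracks. Every downstream
# stage of the pipeline is exercised against cohorts built here.

#' Simulate a marker map
#'
#' Positions are drawn uniformly over `spanBp` base pairs, sorted, and made
#' strictly increasing (1-based).
#'
#' @param nSnps number of SNPs.
#' @param chrom chromosome label.
#' @param spanBp span of the map in bp.
#' @param startBp position of the first base of the span.
#' @param seed integer seed.
#' @return `data.frame` with columns `snp_id`, `chrom`, `pos`, `allele_ref`,
#'   `allele_alt`.
#' @export
simulateMap <- function(nSnps, chrom = "1", spanBp = 5e6, startBp = 1e6,
                        seed = 1) {
  withSeed(seed, {
    pos <- sort(sample.int(spanBp, nSnps)) + as.integer(startBp)
    alleles <- c("A", "C", "G", "T")
    ref <- sample(alleles, nSnps, replace = TRUE)
    alt <- vapply(ref, function(a) sample(setdiff(alleles, a), 1), "")
    data.frame(
      snp_id = sprintf("snp%05d", seq_len(nSnps)),
      chrom = chrom, pos = as.integer(pos),
      allele_ref = ref, allele_alt = unname(alt),
      stringsAsFactors = FALSE)
  })
}

#' Simulate an LD-structured haplotype panel
#'
#' Left-neighbour copying on a latent-uniform scale: each haplotype carries a
#' latent uniform value that is refreshed at site `j` with probability
#' `1 - exp(-delta_bp / ldDecayBp)` (and always at a chromosome change),
#' otherwise copied from the previous site. The allele at site `j` is
#' `latent < p_j`, so each site's allele frequency is exactly its drawn
#' frequency while pairwise LD decays monotonically with distance through a
#' single kernel parameter.
#'
#' @param nHap number of haplotypes (>= 2).
#' @param map marker map as from [simulateMap()]; positions must be strictly
#'   increasing within chromosome.
#' @param ldDecayBp kernel scale in bp; `0` gives independent sites.
#' @param mafRange allele-frequency range, a sub-interval of (0, 0.5].
#' @param seed integer seed.
#' @return list with `h` (nHap x nSnps 0/1 matrix), `freq` (per-site
#'   alternate-allele frequency) and `map`.
#' @export
simulateHaplotypes <- function(nHap, map, ldDecayBp = 5e4,
                               mafRange = c(0.05, 0.5), seed = 1) {
  stopifnot(nHap >= 2, mafRange[1] > 0, mafRange[2] <= 0.5)
  byc <- split(map$pos, map$chrom)
  if (any(vapply(byc, function(p) any(diff(p) <= 0), logical(1))))
    stop("map positions must be strictly increasing within chromosome")
  m <- nrow(map)
  withSeed(seed, {
    p <- runif(m, mafRange[1], mafRange[2])
    h <- matrix(0L, nHap, m)
    u <- runif(nHap)
    h[, 1] <- as.integer(u < p[1])
    if (m > 1) for (j in 2:m) {
      newChrom <- map$chrom[j] != map$chrom[j - 1]
      pr <- if (newChrom || ldDecayBp <= 0) 1 else
        1 - exp(-(map$pos[j] - map$pos[j - 1]) / ldDecayBp)
      sw <- runif(nHap) < pr
      if (any(sw)) u[sw] <- runif(sum(sw))
      h[, j] <- as.integer(u < p[j])
    }
    list(h = h, freq = p, map = map)
  })
}

#' Simulate genotypes from a haplotype panel
#'
#' Each individual is the sum of two haplotypes resampled from the panel.
#' With `nFamilies > 0`, the first `2 * nFamilies` samples form sib pairs:
#' each pair draws four parental haplotypes and each sib inherits one
#' haplotype from each parent, giving an expected kinship coefficient of
#' 0.25 (0.5 on the genomic-relationship scale used by [genomicKinship()]).
#'
#' @param panel haplotype panel from [simulateHaplotypes()].
#' @param nSamples number of individuals.
#' @param nFamilies number of sib-pair families (2 samples each).
#' @param seed integer seed.
#' @return [GenotypeData-class] with attributes `sibPairs` (two-column
#'   matrix of sample indices forming sib pairs) and `sibIbd` (realized
#'   number of shared parental haplotypes per pair, 0/1/2; the pair's
#'   realized relationship on the GRM scale is `sibIbd / 2`).
#' @export
simulateGenotypes <- function(panel, nSamples, nFamilies = 0, seed = 1) {
  stopifnot(nSamples >= 1, 2 * nFamilies <= nSamples)
  h <- panel$h
  nh <- nrow(h)
  withSeed(seed, {
    g <- matrix(0L, nSamples, ncol(h))
    sib <- matrix(integer(0), 0, 2)
    s <- 1L
    ibd <- integer(nFamilies)
    if (nFamilies > 0) {
      sib <- matrix(0L, nFamilies, 2)
      for (f in seq_len(nFamilies)) {
        par <- sample.int(nh, 4, replace = TRUE)  # p1: 1,2; p2: 3,4
        pick <- matrix(c(sample(1:2, 2, replace = TRUE),
                         sample(1:2, 2, replace = TRUE)), 2, 2)
        for (k in 1:2) {
          g[s, ] <- h[par[pick[k, 1]], ] + h[par[2 + pick[k, 2]], ]
          sib[f, k] <- s
          s <- s + 1L
        }
        # realized number of shared parental haplotypes (0, 1 or 2)
        ibd[f] <- sum(pick[1, ] == pick[2, ])
      }
    }
    while (s <= nSamples) {
      idx <- sample.int(nh, 2, replace = TRUE)
      g[s, ] <- h[idx[1], ] + h[idx[2], ]
      s <- s + 1L
    }
    gd <- GenotypeData(g, panel$map)
    attr(gd, "sibPairs") <- sib
    attr(gd, "sibIbd") <- ibd
    gd
  })
}

#' Expected genomic relationship matrix of a simulated cohort
#'
#' Pedigree expectation on the GRM scale: 1 on the diagonal, 0.5 for sib
#' pairs, 0 elsewhere. Build only at small n (dense n x n).
#'
#' @param gd a [GenotypeData-class] from [simulateGenotypes()].
#' @return numeric matrix n x n.
#' @export
pedigreeKinship <- function(gd) {
  n <- nSamples(gd)
  K <- diag(n)
  sib <- attr(gd, "sibPairs")
  if (!is.null(sib) && nrow(sib)) {
    K[sib] <- 0.5
    K[sib[, 2:1, drop = FALSE]] <- 0.5
  }
  rownames(K) <- colnames(K) <- sampleIds(gd)
  K
}

#' Specify planted genetic and covariate effects
#'
#' @param marginal `data.frame` with columns `snp_id`, `a` (additive effect,
#'   trait units per alternate allele) and optionally `d` (dominance
#'   deviation); may be `NULL`.
#' @param epistatic list of entries `list(snps = c(id1, id2), M = 3x3)`
#'   giving trait-unit effects per genotype combination (row = genotype of
#'   snp 1); may be `NULL`. Use [centeredEpistasisMatrix()] to plant
#'   interaction-only effects of computable variance.
#' @param h2Poly polygenic heritability: fraction of the non-fixed-effect
#'   variance attributable to the polygenic background, in [0, 1).
#' @param covariateEffects named numeric vector of coefficients over
#'   phenotype-table covariate columns.
#' @param sigmaE environmental SD, trait units.
#' @return list of class `EffectSpec`.
#' @export
effectSpec <- function(marginal = NULL, epistatic = NULL, h2Poly = 0,
                       covariateEffects = NULL, sigmaE = 1) {
  stopifnot(h2Poly >= 0, h2Poly < 1, sigmaE > 0)
  structure(list(marginal = marginal, epistatic = epistatic,
                 h2Poly = h2Poly, covariateEffects = covariateEffects,
                 sigmaE = sigmaE), class = "EffectSpec")
}

#' Additive effect size planting a target variance fraction
#'
#' Closed form: a SNP of allele frequency `p` with additive effect `a`
#' contributes variance `a^2 * 2 p (1-p)`; to make that a fraction `frac` of
#' the final trait variance when the rest has variance `baseVar`, use
#' `a = sqrt(frac/(1-frac) * baseVar / (2 p (1-p)))`.
#'
#' @param p allele frequency.
#' @param frac target fraction of total variance in (0, 1).
#' @param baseVar variance of everything else in the trait.
#' @return additive effect in trait units.
#' @export
plantedAdditiveEffect <- function(p, frac, baseVar = 1) {
  stopifnot(frac > 0, frac < 1, p > 0, p < 1)
  sqrt(frac / (1 - frac) * baseVar / (2 * p * (1 - p)))
}

#' XOR-like 3x3 epistatic effect matrix
#'
#' Corners and centre +1, edges -1 (times `scale`). At allele frequency 0.5
#' under Hardy-Weinberg this matrix has zero marginal (additive and
#' dominance) content and interaction variance `scale^2`.
#'
#' @param scale trait-unit multiplier.
#' @return 3x3 numeric matrix (row = genotype 0/1/2 at locus 1).
#' @export
xorEffectMatrix <- function(scale = 1) {
  matrix(c(1, -1, 1, -1, 1, -1, 1, -1, 1), 3, 3) * scale
}

#' Centre an epistatic effect matrix to pure interaction
#'
#' Removes the weighted grand mean and both weighted marginal means under
#' Hardy-Weinberg genotype frequencies at the two allele frequencies, so the
#' remaining effects carry no marginal association and the planted
#' interaction variance is `sum(f1 f2 M_c^2)` in closed form.
#'
#' @param M 3x3 effect matrix.
#' @param p1,p2 alternate-allele frequencies of the two SNPs.
#' @return list `M` (centred matrix) and `varInt` (its interaction variance
#'   under HWE).
#' @export
centeredEpistasisMatrix <- function(M, p1, p2) {
  f1 <- c((1 - p1)^2, 2 * p1 * (1 - p1), p1^2)
  f2 <- c((1 - p2)^2, 2 * p2 * (1 - p2), p2^2)
  grand <- sum(outer(f1, f2) * M)
  r <- as.vector(M %*% f2) - grand        # weighted row effects
  cc <- as.vector(t(M) %*% f1) - grand    # weighted col effects
  Mc <- M - outer(r, rep(1, 3)) - outer(rep(1, 3), cc) - grand
  list(M = Mc, varInt = sum(outer(f1, f2) * Mc^2) -
         sum(outer(f1, f2) * Mc)^2)
}

#' Simulate cohort covariates
#'
#' Sex, age, BMI, serum creatinine, hypertension-treatment flag and sample
#' centre, with marginal distributions typical of a middle-aged
#' population-based cohort.
#'
#' @param n number of samples.
#' @param nCentres number of sample centres.
#' @param seed integer seed.
#' @return `data.frame` with columns `sample_id`, `sex`, `age`, `bmi`,
#'   `creatinine`, `treatment`, `centre`.
#' @export
simulateCovariates <- function(n, nCentres = 4, seed = 1) {
  withSeed(seed, {
    data.frame(
      sample_id = paste0("S", seq_len(n)),
      sex = rbinom(n, 1, 0.5),
      age = pmax(18, round(rnorm(n, 54, 8))),
      bmi = round(pmax(15, rnorm(n, 27, 4)), 1),
      creatinine = round(pmax(0.3, rnorm(n, 1.0, 0.2)), 2),
      treatment = rbinom(n, 1, 0.3),
      centre = sample.int(nCentres, n, replace = TRUE),
      stringsAsFactors = FALSE)
  })
}

#' Simulate a quantitative trait with planted effects
#'
#' `trait = sum(additive + dominance) + sum(3x3 epistatic lookups) +
#' covariate terms + polygenic background + N(0, sigmaE^2)`. The polygenic
#' background is realised as a sum of small random additive effects over all
#' genotyped markers with total variance `sigmaG2 = h2Poly/(1-h2Poly) *
#' sigmaE^2`, so the genomic kinship of the cohort carries the signal and
#' `h2Poly` equals `sigmaG2/(sigmaG2+sigmaE2)` by construction.
#'
#' @param gd [GenotypeData-class] (no missing calls; inject missingness with
#'   [injectMissing()] afterwards).
#' @param spec an [effectSpec()].
#' @param covariates optional covariate table from [simulateCovariates()];
#'   required when `spec$covariateEffects` is non-empty.
#' @param seed integer seed.
#' @return phenotype `data.frame` (`sample_id`, `trait`, covariates) with
#'   attribute `components`: the per-source trait vectors, for variance
#'   bookkeeping.
#' @export
simulatePhenotype <- function(gd, spec, covariates = NULL, seed = 1) {
  g <- genotypes(gd)
  if (anyNA(g))
    stop("simulate the phenotype before injecting missingness")
  map <- markerMap(gd)
  n <- nrow(g)
  withSeed(seed, {
    comp <- list()
    y <- numeric(n)
    if (!is.null(spec$marginal) && nrow(spec$marginal)) {
      gm <- numeric(n)
      for (i in seq_len(nrow(spec$marginal))) {
        j <- match(spec$marginal$snp_id[i], map$snp_id)
        if (is.na(j)) stop("marginal effect references unknown SNP: ",
                           spec$marginal$snp_id[i])
        a <- spec$marginal$a[i]
        d <- if ("d" %in% names(spec$marginal)) spec$marginal$d[i] else 0
        p <- mean(g[, j]) / 2
        gm <- gm + a * (g[, j] - 2 * p) + d * (g[, j] == 1L)
      }
      comp$marginal <- gm; y <- y + gm
    }
    if (!is.null(spec$epistatic) && length(spec$epistatic)) {
      ge <- numeric(n)
      for (e in spec$epistatic) {
        j1 <- match(e$snps[1], map$snp_id); j2 <- match(e$snps[2], map$snp_id)
        if (is.na(j1) || is.na(j2))
          stop("epistatic effect references unknown SNP")
        if (length(unique(g[, j1])) < 2 || length(unique(g[, j2])) < 2)
          warning("epistatic pair involves a monomorphic SNP; ",
                  "effect will be inestimable downstream")
        ge <- ge + e$M[cbind(g[, j1] + 1L, g[, j2] + 1L)]
      }
      comp$epistatic <- ge; y <- y + ge
    }
    if (!is.null(spec$covariateEffects) && length(spec$covariateEffects)) {
      if (is.null(covariates))
        stop("covariate effects specified but no covariate table given")
      cv <- numeric(n)
      for (nm in names(spec$covariateEffects))
        cv <- cv + spec$covariateEffects[[nm]] * as.numeric(covariates[[nm]])
      comp$covariates <- cv; y <- y + cv
    }
    sigmaE2 <- spec$sigmaE^2
    if (spec$h2Poly > 0) {
      sigmaG2 <- spec$h2Poly / (1 - spec$h2Poly) * sigmaE2
      p <- colMeans(g) / 2
      poly <- which(p > 0 & p < 1)
      b <- rnorm(length(poly), 0,
                 sqrt(sigmaG2 / length(poly) / (2 * p[poly] * (1 - p[poly]))))
      gp <- as.vector(sweep(g[, poly, drop = FALSE], 2, 2 * p[poly]) %*% b)
      comp$polygenic <- gp; y <- y + gp
    }
    noise <- rnorm(n, 0, spec$sigmaE)
    comp$noise <- noise; y <- y + noise
    out <- data.frame(sample_id = sampleIds(gd), trait = y,
                      stringsAsFactors = FALSE)
    if (!is.null(covariates))
      out <- cbind(out, covariates[setdiff(names(covariates), "sample_id")])
    attr(out, "components") <- comp
    out
  })
}

#' Inject missing genotype calls
#'
#' Uniform missingness at rate `rate`, applied after phenotype simulation so
#' quality control has work to do.
#'
#' @param gd [GenotypeData-class].
#' @param rate missingness probability per call.
#' @param seed integer seed.
#' @return [GenotypeData-class] with `NA` calls.
#' @export
injectMissing <- function(gd, rate, seed = 1) {
  stopifnot(rate >= 0, rate < 1)
  if (rate == 0) return(gd)
  g <- genotypes(gd)
  withSeed(seed, {
    g[runif(length(g)) < rate] <- NA_integer_
  })
  out <- GenotypeData(g, markerMap(gd), sampleIds(gd))
  attr(out, "sibPairs") <- attr(gd, "sibPairs")
  out
}

#' Simulate regulatory annotation tracks
#'
#' Enhancer intervals (BED-style, 0-based half-open) covering approximately
#' `enhancerDensity` of the mapped span, placed one per jittered grid slot so
#' they never overlap, and chromatin interactions (BEDPE-style) with anchor
#' pairs drawn along the map.
#'
#' @param map marker map.
#' @param enhancerDensity target fraction of the span covered, in [0, 1).
#' @param chiapetRate expected chromatin interactions per Mb of span.
#' @param enhancerLength length of each enhancer interval in bp.
#' @param seed integer seed.
#' @return list `enhancers` (`data.frame` chrom/start/end/name) and
#'   `interactions` (`data.frame` chrom1/start1/end1/chrom2/start2/end2/
#'   name/score), both sorted.
#' @export
simulateAnnotations <- function(map, enhancerDensity, chiapetRate,
                                enhancerLength = 1000, seed = 1) {
  if (nrow(map) == 0) stop("empty marker map")
  stopifnot(enhancerDensity >= 0, enhancerDensity < 1, chiapetRate >= 0)
  lo <- min(map$pos); hi <- max(map$pos)
  span <- hi - lo + 1
  withSeed(seed, {
    nInt <- round(enhancerDensity * span / enhancerLength)
    if (nInt > 0) {
      slot <- span / nInt
      start0 <- (lo - 1) + (seq_len(nInt) - 1) * slot +
        runif(nInt) * pmax(0, slot - enhancerLength)
      enh <- data.frame(chrom = map$chrom[1],
                        start = as.integer(floor(start0)),
                        end = as.integer(floor(start0) + enhancerLength),
                        name = sprintf("enh%04d", seq_len(nInt)),
                        stringsAsFactors = FALSE)
    } else {
      enh <- data.frame(chrom = character(), start = integer(),
                        end = integer(), name = character(),
                        stringsAsFactors = FALSE)
    }
    nLoop <- rpois(1, chiapetRate * span / 1e6)
    if (nLoop > 0) {
      a1 <- floor(runif(nLoop, lo, hi - 2000))
      gap <- pmin(rexp(nLoop, 1 / 5e4) + 5000, hi - a1 - 1000)
      loops <- data.frame(chrom1 = map$chrom[1], start1 = as.integer(a1),
                          end1 = as.integer(a1 + 1000),
                          chrom2 = map$chrom[1],
                          start2 = as.integer(a1 + gap),
                          end2 = as.integer(a1 + gap + 1000),
                          name = sprintf("loop%04d", seq_len(nLoop)),
                          score = as.integer(rpois(nLoop, 10) + 1),
                          stringsAsFactors = FALSE)
      loops <- loops[order(loops$start1), ]
      rownames(loops) <- NULL
    } else {
      loops <- data.frame(chrom1 = character(), start1 = integer(),
                          end1 = integer(), chrom2 = character(),
                          start2 = integer(), end2 = integer(),
                          name = character(), score = integer(),
                          stringsAsFactors = FALSE)
    }
    list(enhancers = enh, interactions = loops)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: map, haplotype panel, genotypes (with optional sib
#' pairs), covariates and phenotype in one call, all driven by one seed.
#'
#' @param nSamples,nSnps cohort dimensions.
#' @param spec an [effectSpec()]; its SNP ids must exist in the generated
#'   map (`snp00001` style) or be `NULL`.
#' @param nFamilies sib-pair families.
#' @param spanBp,ldDecayBp,mafRange map and LD parameters, see
#'   [simulateHaplotypes()].
#' @param nHap haplotype panel size.
#' @param missingRate genotype missingness injected after the phenotype.
#' @param covariateEffects passed into the phenotype when `spec` is NULL.
#' @param seed master integer seed; sub-stages derive their own streams.
#' @return list with `gd` (genotypes after missingness), `gdComplete`
#'   (before missingness), `pheno`, `covariates`, `panel`, `spec`, `seed`.
#' @export
simulateCohort <- function(nSamples, nSnps, spec = effectSpec(),
                           nFamilies = 0, spanBp = 5e6,
                           ldDecayBp = 5e4, mafRange = c(0.05, 0.5),
                           nHap = 2000, missingRate = 0, seed = 1) {
  map <- simulateMap(nSnps, spanBp = spanBp, seed = deriveSeed(seed, 1))
  panel <- simulateHaplotypes(nHap, map, ldDecayBp, mafRange,
                              seed = deriveSeed(seed, 2))
  gd <- simulateGenotypes(panel, nSamples, nFamilies,
                          seed = deriveSeed(seed, 3))
  cov <- simulateCovariates(nSamples, seed = deriveSeed(seed, 4))
  pheno <- simulatePhenotype(gd, spec, covariates = cov,
                             seed = deriveSeed(seed, 5))
  gdMiss <- injectMissing(gd, missingRate, seed = deriveSeed(seed, 6))
  list(gd = gdMiss, gdComplete = gd, pheno = pheno, covariates = cov,
       panel = panel, spec = spec, seed = seed)
}
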