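# Genotype and sample quality control: call rates, MAF, Hardy-Weinberg,
# heterozygosity FDR, covariate-range rules and kinship-PC outliers.

#' Per-SNP quality filters
#'
#' A SNP fails if its minor allele frequency (computed on called genotypes
#' only), its call rate, or its Hardy-Weinberg equilibrium P-value falls
#' below threshold. The HWE test is a 1-df chi-square of observed vs
#' HWE-expected genotype counts (no continuity correction); an exact test
#' is available via `hweExact = TRUE`.
#'
#' @param gd [GenotypeData-class].
#' @param mafMin minimum minor allele frequency.
#' @param callrateMin minimum per-SNP call rate.
#' @param hwePMin minimum HWE P-value.
#' @param hweExact use the exact conditional HWE test instead of chi-square.
#' @return `data.frame` with per-SNP `snp_id`, `maf`, `callrate`, `hwe_p`,
#'   `pass` and `reasons` (comma-separated failed rules, "" if passing).
#' @export
snpFilters <- function(gd, mafMin = 0.02, callrateMin = 0.95,
                       hwePMin = 1e-10, hweExact = FALSE) {
  g <- genotypes(gd)
  if (ncol(g) == 0 || nrow(g) == 0) stop("empty genotype matrix")
  called <- !is.na(g)
  nCalled <- colSums(called)
  callrate <- nCalled / nrow(g)
  n0 <- colSums(g == 0L, na.rm = TRUE)
  n1 <- colSums(g == 1L, na.rm = TRUE)
  n2 <- colSums(g == 2L, na.rm = TRUE)
  p <- ifelse(nCalled > 0, (2 * n2 + n1) / (2 * nCalled), NA_real_)
  maf <- pmin(p, 1 - p)
  hwe <- if (hweExact) {
    mapply(hweExactP, n0, n1, n2)
  } else {
    mapply(hweChisqP, n0, n1, n2)
  }
  reasons <- character(ncol(g))
  add <- function(idx, r) ifelse(idx, paste0(reasons, r, ","), reasons)
  reasons <- add(is.na(maf) | maf < mafMin, "maf")
  reasons <- add(callrate < callrateMin, "callrate")
  reasons <- add(!is.na(hwe) & hwe < hwePMin, "hwe")
  reasons <- sub(",$", "", reasons)
  data.frame(snp_id = markerMap(gd)$snp_id, maf = maf, callrate = callrate,
             hwe_p = hwe, pass = reasons == "", reasons = reasons,
             stringsAsFactors = FALSE)
}

# 1-df chi-square HWE test on called genotype counts.
hweChisqP <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(NA_real_)
  p <- (2 * n2 + n1) / (2 * n)
  if (p == 0 || p == 1) return(1)  # monomorphic: no HWE deviation testable
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  stat <- sum((c(n0, n1, n2) - e)^2 / e)
  pchisq(stat, df = 1, lower.tail = FALSE)
}

# Exact conditional HWE test (two-sided, sum of probabilities <= observed).
hweExactP <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  if (n == 0) return(NA_real_)
  nA <- 2 * n2 + n1  # minor or major, symmetric below
  nMinor <- min(nA, 2 * n - nA)
  hets <- seq(nMinor %% 2, nMinor, by = 2)
  logp <- vapply(hets, function(h) {
    hom1 <- (nMinor - h) / 2
    hom2 <- n - h - hom1
    lgamma(n + 1) - lgamma(hom1 + 1) - lgamma(h + 1) - lgamma(hom2 + 1) +
      h * log(2) + lgamma(nMinor + 1) + lgamma(2 * n - nMinor + 1) -
      lgamma(2 * n + 1)
  }, numeric(1))
  pr <- exp(logp - max(logp)); pr <- pr / sum(pr)
  obs <- pr[match(n1, hets)]
  if (is.na(obs)) return(NA_real_)
  sum(pr[pr <= obs + 1e-12])
}

#' Per-sample quality filters
#'
#' A sample fails on low call rate, unacceptably high heterozygosity
#' (one-sided z P-values of the per-sample heterozygosity proportion,
#' Benjamini-Hochberg controlled at `hetFdr`), age below `ageMin`, BMI above
#' `bmiMax`, or creatinine beyond `creatSd` SD of the cohort mean. Samples
#' with missing covariates are flagged `unevaluable` and excluded.
#'
#' @param gd [GenotypeData-class].
#' @param pheno phenotype table with covariates `age`, `bmi`, `creatinine`.
#' @param callrateMin minimum individual call rate.
#' @param hetFdr FDR level for the high-heterozygosity rule.
#' @param ageMin,bmiMax,creatSd covariate exclusion rules.
#' @return `data.frame` with `sample_id`, `callrate`, `het`, `pass`,
#'   `reasons`.
#' @export
sampleFilters <- function(gd, pheno, callrateMin = 0.97, hetFdr = 0.01,
                          ageMin = 18, bmiMax = 50, creatSd = 3) {
  g <- genotypes(gd)
  called <- !is.na(g)
  callrate <- rowSums(called) / ncol(g)
  het <- rowSums(g == 1L, na.rm = TRUE) / pmax(rowSums(called), 1)
  z <- (het - mean(het)) / sd(het)
  pUp <- pnorm(z, lower.tail = FALSE)
  hetFail <- p.adjust(pUp, method = "BH") < hetFdr
  ph <- pheno[match(sampleIds(gd), pheno$sample_id), , drop = FALSE]
  reasons <- character(nrow(g))
  add <- function(idx, r) {
    idx[is.na(idx)] <- FALSE
    ifelse(idx, paste0(reasons, r, ","), reasons)
  }
  reasons <- add(callrate < callrateMin, "callrate")
  reasons <- add(hetFail, "het")
  unev <- is.na(ph$age) | is.na(ph$bmi) | is.na(ph$creatinine)
  reasons <- add(unev, "unevaluable")
  reasons <- add(!unev & ph$age < ageMin, "age")
  reasons <- add(!unev & ph$bmi > bmiMax, "bmi")
  cm <- mean(ph$creatinine, na.rm = TRUE)
  cs <- sd(ph$creatinine, na.rm = TRUE)
  reasons <- add(!unev & abs(ph$creatinine - cm) > creatSd * cs, "creatinine")
  reasons <- sub(",$", "", reasons)
  data.frame(sample_id = sampleIds(gd), callrate = callrate, het = het,
             pass = reasons == "", reasons = reasons, stringsAsFactors = FALSE)
}

#' Kinship principal-component outlier removal
#'
#' Samples are scored on the first `nPc` principal components of the kinship
#' matrix; any sample with |score| beyond `sdMult` SDs of that component's
#' scores fails. After removing outliers the PCs are recomputed once on the
#' remaining samples and the rule is re-applied (one iteration).
#'
#' @param K symmetric kinship matrix with sample ids as dimnames.
#' @param nPc number of leading components to screen.
#' @param sdMult outlier cut in SD units.
#' @return logical vector, `TRUE` = keep, named by sample.
#' @export
pcaOutliers <- function(K, nPc = 3, sdMult = 6) {
  n <- nrow(K)
  if (n < nPc + 1) stop("need more samples than principal components")
  keep <- rep(TRUE, n)
  for (pass in 1:2) {
    Ks <- K[keep, keep, drop = FALSE]
    ev <- eigen(Ks, symmetric = TRUE)
    npc <- min(nPc, ncol(ev$vectors))
    sc <- ev$vectors[, seq_len(npc), drop = FALSE] %*%
      diag(sqrt(pmax(ev$values[seq_len(npc)], 0)), npc)
    bad <- rep(FALSE, sum(keep))
    for (k in seq_len(npc)) {
      s <- sc[, k]
      bad <- bad | abs(s - mean(s)) > sdMult * sd(s)
    }
    keep[keep] <- !bad
    if (!any(bad)) break
  }
  names(keep) <- rownames(K)
  keep
}

#' Run the full quality-control protocol
#'
#' One pass: SNP filters (MAF, call rate, HWE), sample filters (call rate,
#' heterozygosity FDR, covariate rules), then kinship-PC outlier removal on
#' the filtered set.
#'
#' @param gd [GenotypeData-class].
#' @param pheno phenotype table.
#' @param mafMin,callrateSnpMin,hwePMin SNP thresholds.
#' @param callrateIndMin,hetFdr,ageMin,bmiMax,creatSd sample thresholds.
#' @param nPc,sdMult PC-outlier parameters; `nPc = 0` skips the PC stage.
#' @return [QcReport-class].
#' @export
runQc <- function(gd, pheno, mafMin = 0.02, callrateSnpMin = 0.95,
                  hwePMin = 1e-10, callrateIndMin = 0.97, hetFdr = 0.01,
                  ageMin = 18, bmiMax = 50, creatSd = 3, nPc = 3,
                  sdMult = 6) {
  snp <- snpFilters(gd, mafMin, callrateSnpMin, hwePMin)
  smp <- sampleFilters(gd, pheno, callrateIndMin, hetFdr, ageMin, bmiMax,
                       creatSd)
  sampleMask <- smp$pass
  snpMaskV <- snp$pass
  if (nPc > 0 && sum(sampleMask) > nPc + 1 && sum(snpMaskV) >= 2) {
    sub <- gd[sampleMask, snpMaskV]
    K <- genomicKinship(sub)
    keep <- pcaOutliers(K, nPc, sdMult)
    if (any(!keep)) {
      idx <- which(sampleMask)[!keep]
      smp$reasons[idx] <- ifelse(smp$reasons[idx] == "", "pca",
                                 paste0(smp$reasons[idx], ",pca"))
      smp$pass[idx] <- FALSE
      sampleMask[idx] <- FALSE
    }
  }
  snpReasons <- strsplit(snp$reasons[!snp$pass], ",")
  names(snpReasons) <- snp$snp_id[!snp$pass]
  smpReasons <- strsplit(smp$reasons[!smp$pass], ",")
  names(smpReasons) <- smp$sample_id[!smp$pass]
  allReasons <- c(unlist(snpReasons), unlist(smpReasons))
  counts <- if (length(allReasons)) {
    tab <- table(allReasons)
    setNames(as.integer(tab), names(tab))
  } else integer(0)
  new("QcReport", snpMask = snp$pass, sampleMask = smp$pass,
      snpReasons = snpReasons, sampleReasons = smpReasons, counts = counts)
}

#' Apply a QC report to a genotype set and phenotype table
#'
#' @param gd [GenotypeData-class].
#' @param pheno phenotype table.
#' @param report [QcReport-class] from [runQc()].
#' @return list `gd`, `pheno` filtered to passing SNPs and samples.
#' @export
applyQc <- function(gd, pheno, report) {
  gd2 <- gd[sampleMask(report), snpMask(report)]
  ph2 <- pheno[match(sampleIds(gd2), pheno$sample_id), , drop = FALSE]
  rownames(ph2) <- NULL
  list(gd = gd2, pheno = ph2)
}

#' Write a QC report as a tab-separated table
#'
#' One row per removed entity: entity id, type, failed rule.
#'
#' @param report [QcReport-class].
#' @param path output file.
#' @export
writeQcReport <- function(report, path) {
  rows <- rbind(
    if (length(report@snpReasons))
      data.frame(entity = rep(names(report@snpReasons),
                              lengths(report@snpReasons)),
                 type = "snp", rule = unlist(report@snpReasons)),
    if (length(report@sampleReasons))
      data.frame(entity = rep(names(report@sampleReasons),
                              lengths(report@sampleReasons)),
                 type = "sample", rule = unlist(report@sampleReasons)))
  if (is.null(rows))
    rows <- data.frame(entity = character(), type = character(),
                       rule = character())
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
}
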