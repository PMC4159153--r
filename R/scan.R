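# Marginal association scan and the exhaustive pairwise interaction scan:
# Bonferroni threshold derivation, bit-plane encoding, the screening F test
# computed from 9-cell popcount summaries, exact full-model verification,
# composite LD, and category classification of emitted pairs.

#' Derive Bonferroni significance thresholds for the scan
#'
#' `tFull = 0.05 / (m (m - 1) / 2)` for the full pairwise scan over `m`
#' SNPs and `tMarginal = 0.05 / ((m - 1) k)` for pairs involving at least
#' one of `k` marginal SNPs. Raw values are stored; [formatThreshold()]
#' reports them to two significant figures. The local-interaction threshold
#' (1e-5) and GWAS consensus threshold (5e-8) are fixed conventions.
#'
#' @param mSnps number of SNPs scanned (>= 2).
#' @param nMarginal number of marginal SNPs (k >= 0; `tMarginal` is NA when
#'   k = 0).
#' @return [Thresholds-class].
#' @examples
#' th <- deriveThresholds(514662, 166)
#' formatThreshold(th@tFull)      # "3.8e-13"
#' formatThreshold(th@tMarginal)  # "5.9e-10"
#' @export
deriveThresholds <- function(mSnps, nMarginal = 0) {
  stopifnot(mSnps >= 2, nMarginal >= 0)
  tFull <- 0.05 / (mSnps * (mSnps - 1) / 2)
  tMarginal <- if (nMarginal > 0) 0.05 / ((mSnps - 1) * nMarginal)
               else NA_real_
  new("Thresholds", tFull = tFull, tMarginal = tMarginal, tLocal = 1e-5,
      tGwas = 5e-8, mSnps = as.integer(mSnps),
      nMarginal = as.integer(nMarginal))
}

#' Encode genotypes into bit planes
#'
#' Lossless: each SNP becomes four bit planes over samples (genotype classes
#' 0/1/2 plus a called mask), packed into 64-bit words. The planes are
#' mutually disjoint and union to the called mask.
#'
#' @param gd [GenotypeData-class].
#' @return [BitGenotypes-class].
#' @export
encodeBitwise <- function(gd) {
  g <- genotypes(gd)
  new("BitGenotypes", bits = .cpp_bit_encode(g),
      nSamples = nrow(g), nSnps = ncol(g),
      snpIds = markerMap(gd)$snp_id)
}

#' Decode bit planes back to a genotype matrix
#'
#' @param bitg [BitGenotypes-class].
#' @return integer matrix samples x SNPs with NA for uncalled.
#' @export
decodeBitwise <- function(bitg) {
  g <- .cpp_bit_decode(bitg@bits, bitg@nSamples, bitg@nSnps)
  colnames(g) <- bitg@snpIds
  g
}

#' Popcounts of the bit planes
#'
#' @param bitg [BitGenotypes-class].
#' @return 4 x nSnps integer matrix (rows: genotype classes 0, 1, 2 and the
#'   called mask).
#' @export
bitPlaneCounts <- function(bitg) {
  out <- .cpp_plane_counts(bitg@bits, bitg@nSamples, bitg@nSnps)
  dimnames(out) <- list(c("g0", "g1", "g2", "called"), bitg@snpIds)
  out
}

#' 9-cell contingency summaries for one SNP pair
#'
#' Cell counts via plane-AND popcounts; trait sums and sums of squares by
#' iterating set bits; computed over pairwise-complete samples.
#'
#' @param bitg [BitGenotypes-class].
#' @param i,j SNP indices (1-based) or SNP ids.
#' @param y trait vector over samples.
#' @return list `counts`, `sums`, `sumsq` (3x3, rows = genotype of SNP i)
#'   and `n` (pairwise-complete sample count).
#' @export
pairCellCounts <- function(bitg, i, j, y) {
  if (is.character(i)) i <- match(i, bitg@snpIds)
  if (is.character(j)) j <- match(j, bitg@snpIds)
  .cpp_pair_cells(bitg@bits, bitg@nSamples, bitg@nSnps, i, j,
                  as.numeric(y))
}

#' Mixed-model score test single-SNP scan
#'
#' Per SNP, the 1-df score statistic
#' `[(g - gbar)' V^-1 r]^2 / [(g - gbar)' V^-1 (g - gbar)]` against
#' chi-square(1), where `r` is the environmental residual trait and `V` the
#' fitted trait covariance from the polygenic model. With `V` proportional
#' to the identity this is exactly the OLS score test. Missing genotypes are
#' mean-imputed (zero after centring); monomorphic SNPs get NA.
#'
#' @param fit [PolygenicFit-class] from [fitPolygenic()].
#' @param gd [GenotypeData-class] aligned to the fit's samples.
#' @param tGwas genome-wide significance threshold for flagging.
#' @return `data.frame` `snp_id`, `chrom`, `pos`, `maf`, `stat`, `p`,
#'   `marginal` (logical flag at `tGwas`).
#' @export
marginalScan <- function(fit, gd, tGwas = 5e-8) {
  g <- genotypes(gd)
  r <- pgResiduals(fit)
  stopifnot(nrow(g) == length(r))
  lam <- fit@eigenK$values
  U <- fit@eigenK$vectors
  h2 <- heritability(fit)
  sigma2 <- sum(varianceComponents(fit))
  w <- h2 * lam + (1 - h2)
  p <- colMeans(g, na.rm = TRUE) / 2
  Gc <- sweep(g, 2, 2 * p)
  Gc[is.na(Gc)] <- 0
  Gt <- crossprod(U, Gc)
  rt <- crossprod(U, r)
  num <- as.numeric(crossprod(Gt, rt / w))^2 / sigma2
  den <- colSums(Gt^2 / w)
  stat <- ifelse(den > 0, num / den, NA_real_)
  mono <- p <= 0 | p >= 1
  stat[mono] <- NA_real_
  pv <- pchisq(stat, df = 1, lower.tail = FALSE)
  map <- markerMap(gd)
  data.frame(snp_id = map$snp_id, chrom = map$chrom, pos = map$pos,
             maf = pmin(p, 1 - p), stat = stat, p = pv,
             marginal = !is.na(pv) & pv < tGwas, stringsAsFactors = FALSE)
}

#' Candidate pair indices for a scan window
#'
#' @param map marker map.
#' @param window `"all"` for all pairs or `"local"` for same-chromosome
#'   pairs within `maxDistBp`.
#' @param maxDistBp inclusive distance bound for the local window.
#' @return two-column integer matrix of SNP index pairs (i < j).
#' @export
pairIndices <- function(map, window = c("all", "local"), maxDistBp = 1e6) {
  window <- match.arg(window)
  m <- nrow(map)
  if (window == "all") {
    idx <- which(upper.tri(matrix(0, m, m)), arr.ind = TRUE)
    return(cbind(idx[, 1], idx[, 2]))
  }
  out <- vector("list", m)
  for (i in seq_len(m - 1)) {
    j <- (i + 1):m
    ok <- map$chrom[j] == map$chrom[i] &
      (map$pos[j] - map$pos[i]) <= maxDistBp
    if (any(ok)) out[[i]] <- cbind(i, j[ok])
  }
  do.call(rbind, out[!vapply(out, is.null, TRUE)])
}

#' Screen SNP pairs for interaction with the bit-plane F test
#'
#' For each pair, over pairwise-complete samples, the 9-cell counts/sums/
#' sums-of-squares are built by plane ANDs; the screening statistic is
#' `F = [(SS_cells - SS_main)/df_int] / [SS_within/(n - cells)]` where
#' `SS_main` is the explained sum of squares of the best additive+dominance
#' two-locus main-effect fit (5 parameters, weighted by cell counts) and
#' `df_int = nonempty cells - rank of the main design`. On complete data
#' with no empty cells this is exactly the full-model interaction F test.
#'
#' @param bitg [BitGenotypes-class].
#' @param y trait vector (environmental residuals).
#' @param pairs two-column matrix of SNP index pairs, e.g. from
#'   [pairIndices()].
#' @param pMax emit only pairs with `p_screen <= pMax` (default all).
#' @return `data.frame` `idx1`, `idx2`, `n`, `df1`, `df2`, `F`, `p_screen`;
#'   pairs whose interaction df collapsed to zero are dropped and counted in
#'   attribute `nSkipped`.
#' @export
pairScreen <- function(bitg, y, pairs, pMax = 1) {
  stopifnot(length(y) == bitg@nSamples)
  res <- .cpp_pair_screen(bitg@bits, bitg@nSamples, bitg@nSnps,
                          as.integer(pairs[, 1]), as.integer(pairs[, 2]),
                          as.numeric(y))
  res$p_screen <- pf(res$F, res$df1, res$df2, lower.tail = FALSE)
  skipped <- sum(is.na(res$F))
  res <- res[!is.na(res$F) & res$p_screen <= pMax, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "nSkipped") <- skipped
  res
}

#' Exact full-model interaction test for one SNP pair
#'
#' Factor-coded least squares on complete cases: the full 9-cell two-locus
#' genotype model against the two-locus main-effects model, compared by
#' partial F test. Optional background columns (e.g. conditioning terms)
#' enter both models. Rank deficiency (empty or collinear cells) reduces the
#' interaction degrees of freedom, noted in the result.
#'
#' @param g1,g2 genotype vectors (0/1/2/NA).
#' @param y trait vector.
#' @param background optional numeric matrix of fixed-effect columns.
#' @return list `p`, `F`, `df1`, `df2`, `n`, `anova` (the model comparison
#'   table), `note`.
#' @export
pairFullTest <- function(g1, g2, y, background = NULL) {
  keep <- !is.na(g1) & !is.na(g2) & !is.na(y)
  if (!is.null(background)) {
    background <- as.matrix(background)
    keep <- keep & complete.cases(background)
    bg <- background[keep, , drop = FALSE]
  } else bg <- NULL
  g1 <- factor(g1[keep], levels = 0:2)
  g2 <- factor(g2[keep], levels = 0:2)
  g1 <- droplevels(g1); g2 <- droplevels(g2)
  yy <- y[keep]
  n <- sum(keep)
  note <- ""
  if (nlevels(g1) < 2 || nlevels(g2) < 2)
    return(list(p = NA_real_, F = NA_real_, df1 = 0L, df2 = n, n = n,
                anova = NULL, note = "monomorphic on complete samples"))
  dat <- data.frame(y = yy, g1 = g1, g2 = g2)
  fmMain <- if (is.null(bg)) y ~ g1 + g2 else y ~ bg + g1 + g2
  fmFull <- if (is.null(bg)) y ~ g1 * g2 else y ~ bg + g1 * g2
  fitMain <- lm(fmMain, data = dat)
  fitFull <- lm(fmFull, data = dat)
  av <- anova(fitMain, fitFull)
  df1 <- av$Df[2]
  if (is.na(df1) || df1 <= 0)
    return(list(p = NA_real_, F = NA_real_, df1 = 0L, df2 = fitFull$df.residual,
                n = n, anova = av, note = "no interaction df"))
  if (df1 < 4) note <- "reduced interaction df"
  list(p = av$`Pr(>F)`[2], F = av$F[2], df1 = df1,
       df2 = fitFull$df.residual, n = n, anova = av, note = note)
}

#' Composite LD r-squared between two SNPs
#'
#' Squared Pearson correlation of 0/1/2 allele dosages over pairwise-
#' complete samples (phase-free composite LD).
#'
#' @param g1,g2 genotype vectors (0/1/2/NA).
#' @return r^2 in [0, 1]; NA (with a warning) if either SNP is monomorphic
#'   on the complete samples.
#' @export
ldR2 <- function(g1, g2) {
  keep <- !is.na(g1) & !is.na(g2)
  a <- g1[keep]; b <- g2[keep]
  if (var(a) == 0 || var(b) == 0) {
    warning("monomorphic SNP: LD undefined")
    return(NA_real_)
  }
  cor(a, b)^2
}

#' Classify scanned pairs into significance categories
#'
#' `genomewide` if `p_full < tFull`; `marginal_pair` if `p_full < tMarginal`
#' and at least one SNP is a flagged marginal SNP; `local` if both SNPs are
#' on the same chromosome at most 1 Mb apart (inclusive) with
#' `p_full < 1e-5`. Same-chromosome distances are reported in kb rounded
#' half-up to one decimal; cross-chromosome distance is NA.
#'
#' @param pairs `data.frame` with columns `snp1`, `snp2`, `p_full` (and
#'   optionally `p_screen`, `r2`).
#' @param thresholds [Thresholds-class].
#' @param marginalSnps character vector of marginal SNP ids.
#' @param map marker map.
#' @return the input with `chr1`, `pos1`, `chr2`, `pos2`, `dist_kb`,
#'   `category` (comma-joined set, "" if none) added, pairs ordered with
#'   lexicographically smaller snp id first and rows sorted by position.
#' @export
classifyPairs <- function(pairs, thresholds, marginalSnps = character(),
                          map) {
  if (nrow(pairs) == 0) {
    pairs$chr1 <- character(); pairs$pos1 <- integer()
    pairs$chr2 <- character(); pairs$pos2 <- integer()
    pairs$dist_kb <- numeric(); pairs$category <- character()
    return(pairs)
  }
  swap <- pairs$snp1 > pairs$snp2
  tmp <- pairs$snp1[swap]; pairs$snp1[swap] <- pairs$snp2[swap]
  pairs$snp2[swap] <- tmp
  i1 <- match(pairs$snp1, map$snp_id); i2 <- match(pairs$snp2, map$snp_id)
  if (anyNA(i1) || anyNA(i2)) stop("pair references SNP absent from map")
  pairs$chr1 <- map$chrom[i1]; pairs$pos1 <- map$pos[i1]
  pairs$chr2 <- map$chrom[i2]; pairs$pos2 <- map$pos[i2]
  same <- pairs$chr1 == pairs$chr2
  distBp <- ifelse(same, abs(pairs$pos2 - pairs$pos1), NA_real_)
  pairs$dist_kb <- roundHalfUp(distBp / 1000, 1)
  p <- pairs$p_full
  cats <- mapply(function(pv, sameChrom, d, s1, s2) {
    if (is.na(pv)) return("")
    out <- character()
    if (!is.na(thresholds@tFull) && pv < thresholds@tFull)
      out <- c(out, "genomewide")
    if (!is.na(thresholds@tMarginal) && pv < thresholds@tMarginal &&
        (s1 %in% marginalSnps || s2 %in% marginalSnps))
      out <- c(out, "marginal_pair")
    if (sameChrom && !is.na(d) && d <= 1e6 && pv < thresholds@tLocal)
      out <- c(out, "local")
    paste(out, collapse = ",")
  }, p, same, distBp, pairs$snp1, pairs$snp2)
  pairs$category <- unname(cats)
  ord <- order(pairs$chr1, pairs$pos1, pairs$chr2, pairs$pos2)
  pairs <- pairs[ord, , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

#' Run the pairwise interaction scan
#'
#' Encodes the genotypes, screens candidate pairs with the bit-plane F test,
#' verifies every emitted pair with the exact full-model test (reported as
#' `p_full`, the interaction P), computes composite LD, and classifies
#' pairs against the thresholds. `p_screen` is retained for audit.
#'
#' @param gd [GenotypeData-class] (QC-passed).
#' @param y environmental residual trait aligned to `gd`.
#' @param thresholds [Thresholds-class]; defaults to thresholds derived from
#'   the scanned SNP count and `marginalSnps`.
#' @param mode `"full"` (all pairs, emit at the marginal-pair or full
#'   threshold, whichever is looser), `"marginal"` (all pairs involving a
#'   marginal SNP) or `"local"` (same-chromosome pairs within 1 Mb, emit at
#'   1e-5).
#' @param marginalSnps character vector of marginal SNP ids (from
#'   [marginalScan()]).
#' @param maxDistBp local-window bound, inclusive.
#' @param pMax override the emission threshold on `p_screen`.
#' @return classified pair `data.frame` (see [classifyPairs()]) with
#'   `p_screen`, `p_full`, `r2`; attribute `nSkipped` counts pairs whose
#'   interaction df collapsed.
#' @export
scanPairs <- function(gd, y, thresholds = NULL, mode = c("full", "marginal",
                                                         "local"),
                      marginalSnps = character(), maxDistBp = 1e6,
                      pMax = NULL) {
  mode <- match.arg(mode)
  map <- markerMap(gd)
  if (is.null(thresholds))
    thresholds <- deriveThresholds(nSnps(gd), length(marginalSnps))
  idx <- pairIndices(map, if (mode == "local") "local" else "all", maxDistBp)
  if (mode == "marginal") {
    mi <- match(marginalSnps, map$snp_id)
    keep <- (idx[, 1] %in% mi) | (idx[, 2] %in% mi)
    idx <- idx[keep, , drop = FALSE]
  }
  if (is.null(pMax)) {
    pMax <- switch(mode,
      full = max(thresholds@tFull, thresholds@tMarginal, na.rm = TRUE),
      marginal = thresholds@tMarginal,
      local = thresholds@tLocal)
    if (is.na(pMax)) pMax <- thresholds@tFull
  }
  bitg <- encodeBitwise(gd)
  scr <- pairScreen(bitg, y, idx, pMax = pMax)
  g <- genotypes(gd)
  n <- nrow(scr)
  out <- data.frame(snp1 = map$snp_id[scr$idx1], snp2 = map$snp_id[scr$idx2],
                    p_screen = scr$p_screen,
                    p_full = rep(NA_real_, n), r2 = rep(NA_real_, n),
                    stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    g1 <- g[, scr$idx1[k]]; g2 <- g[, scr$idx2[k]]
    out$p_full[k] <- pairFullTest(g1, g2, y)$p
    out$r2[k] <- suppressWarnings(ldR2(g1, g2))
  }
  out <- classifyPairs(out, thresholds, marginalSnps, map)
  attr(out, "nSkipped") <- attr(scr, "nSkipped")
  attr(out, "thresholds") <- thresholds
  out
}
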