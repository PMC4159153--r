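# Shared fixture builders. All fixtures are generated in code at test time.

# Small cohort with no planted effects.
nullCohort <- function(n = 300, m = 40, seed = 11, ...) {
  simulateCohort(nSamples = n, nSnps = m, seed = seed, ...)
}

# Two-SNP genotype fixture drawn from explicit haplotype frequencies
# (hapFreq over haplotypes 00, 01, 10, 11), for LD tests with a known
# target r2.
genotypesFromHaplotypeFreqs <- function(n, hapFreq, seed = 1) {
  stopifnot(length(hapFreq) == 4, abs(sum(hapFreq) - 1) < 1e-9)
  set.seed(seed)
  haps <- matrix(c(0, 0, 0, 1, 1, 0, 1, 1), 4, 2, byrow = TRUE)
  draw <- function() {
    i <- sample.int(4, n, replace = TRUE, prob = hapFreq)
    haps[i, , drop = FALSE]
  }
  h1 <- draw(); h2 <- draw()
  list(g1 = h1[, 1] + h2[, 1], g2 = h1[, 2] + h2[, 2])
}

# Theoretical composite r2 for a two-locus haplotype frequency vector.
hapFreqR2 <- function(hapFreq) {
  pA <- hapFreq[3] + hapFreq[4]  # allele 1 at locus 1
  pB <- hapFreq[2] + hapFreq[4]
  D <- hapFreq[4] - pA * pB
  D^2 / (pA * (1 - pA) * pB * (1 - pB))
}

# Brute-force 9-cell contingency of two genotype vectors.
naiveCellCounts <- function(g1, g2, y) {
  counts <- matrix(0L, 3, 3); sums <- matrix(0, 3, 3); sumsq <- matrix(0, 3, 3)
  for (i in seq_along(g1)) {
    if (is.na(g1[i]) || is.na(g2[i])) next
    r <- g1[i] + 1; c <- g2[i] + 1
    counts[r, c] <- counts[r, c] + 1L
    sums[r, c] <- sums[r, c] + y[i]
    sumsq[r, c] <- sumsq[r, c] + y[i]^2
  }
  list(counts = counts, sums = sums, sumsq = sumsq, n = sum(counts))
}

# Brute-force overlap of 1-based SNP positions vs 0-based half-open track.
naiveOverlap <- function(snps, track) {
  vapply(seq_len(nrow(snps)), function(i) {
    any(track$chrom == snps$chrom[i] &
          track$start < snps$pos[i] & snps$pos[i] <= track$end)
  }, logical(1))
}

# Brute-force chromatin-interaction counting around bin midpoints.
naiveChiaPetCounts <- function(bins, loops, flank = 1e5) {
  vapply(seq_len(nrow(bins)), function(b) {
    lo <- bins$midpoint[b] - flank; hi <- bins$midpoint[b] + flank
    hit <- 0L
    for (k in seq_len(nrow(loops))) {
      a1 <- loops$chrom1[k] == bins$chrom[b] &&
        loops$start1[k] + 1 <= hi && loops$end1[k] >= lo
      a2 <- loops$chrom2[k] == bins$chrom[b] &&
        loops$start2[k] + 1 <= hi && loops$end2[k] >= lo
      if (a1 || a2) hit <- hit + 1L
    }
    hit
  }, integer(1))
}
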