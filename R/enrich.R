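# Regulatory enrichment: enhancer-overlap binomial tests against the
# genotyped-SNP background, greedy 25-kb binning of trait-associated SNPs,
# chromatin-interaction counting in a +/- 100 kb window around bin
# midpoints, and empirical ranking of a focal region.

#' Flag SNPs overlapping a BED-style track
#'
#' A SNP (1-based position) overlaps a 0-based half-open interval
#' `[start, end)` iff `start < pos <= end`, i.e. its 0-based coordinate
#' `pos - 1` lies in the interval. Interval arithmetic is delegated to
#' IRanges. An unsorted track is sorted internally with a warning.
#'
#' @param snps `data.frame` with `chrom` and `pos` (1-based).
#' @param track `data.frame` with `chrom`, `start`, `end` (0-based
#'   half-open), e.g. from [readBedTrack()] or [simulateAnnotations()].
#' @return logical vector, one flag per SNP.
#' @export
overlapFlags <- function(snps, track) {
  if (nrow(track) == 0) return(rep(FALSE, nrow(snps)))
  ord <- order(track$chrom, track$start)
  if (!identical(ord, seq_len(nrow(track)))) {
    warning("track not sorted; sorting internally")
    track <- track[ord, , drop = FALSE]
  }
  q <- GenomicRanges::GRanges(snps$chrom,
                              IRanges::IRanges(snps$pos, width = 1))
  # half-open [start, end) in 0-based = closed [start+1, end] in 1-based
  s <- GenomicRanges::GRanges(track$chrom,
                              IRanges::IRanges(track$start + 1, track$end))
  IRanges::overlapsAny(q, s)
}

#' Binomial enhancer-overlap enrichment test
#'
#' Expected overlap count is `nTagged * backgroundFreq` where the background
#' frequency is the overlap rate among all genotyped (QC-passed) SNPs; fold
#' is observed/expected (reported rounded half-up to one decimal); the
#' P-value is the exact upper-tail binomial probability
#' `P(X >= observed | nTagged, backgroundFreq)`.
#'
#' @param nTagged number of tagged (trait-associated) SNPs.
#' @param observed number of tagged SNPs overlapping the annotation.
#' @param backgroundFreq background overlap fraction, in (0, 1).
#' @param cellType label carried into the result.
#' @return one-row `data.frame`: `cell_type`, `n_tagged`, `observed`,
#'   `expected`, `fold` (one decimal), `p`.
#' @examples
#' enrichmentTest(42, 11, 2.1 / 42)$fold  # 5.2
#' @export
enrichmentTest <- function(nTagged, observed, backgroundFreq,
                           cellType = NA_character_) {
  stopifnot(observed <= nTagged, nTagged > 0)
  if (is.na(backgroundFreq) || backgroundFreq <= 0 || backgroundFreq >= 1)
    stop("background overlap frequency must be in (0, 1)")
  expected <- nTagged * backgroundFreq
  fold <- roundHalfUp(observed / expected, 1)
  p <- pbinom(observed - 1, nTagged, backgroundFreq, lower.tail = FALSE)
  data.frame(cell_type = cellType, n_tagged = nTagged, observed = observed,
             expected = expected, fold = fold, p = p,
             stringsAsFactors = FALSE)
}

#' Enhancer enrichment of a tagged SNP set over cell-type tracks
#'
#' @param tagged `data.frame` of tagged SNPs (`chrom`, `pos`).
#' @param background `data.frame` of all genotyped SNPs (`chrom`, `pos`),
#'   defining the genomic background.
#' @param tracks named list of BED-style tracks, one per cell type.
#' @return `data.frame`, one row per cell type (see [enrichmentTest()]).
#' @export
enhancerEnrichment <- function(tagged, background, tracks) {
  stopifnot(length(tracks) > 0, nrow(background) > 0)
  rows <- lapply(names(tracks), function(ct) {
    freq <- mean(overlapFlags(background, tracks[[ct]]))
    obs <- sum(overlapFlags(tagged, tracks[[ct]]))
    enrichmentTest(nrow(tagged), obs, freq, cellType = ct)
  })
  do.call(rbind, rows)
}

#' Greedy 25-kb binning of sorted SNP positions
#'
#' Left-to-right clustering per chromosome: open a region at the first
#' unassigned SNP, absorb every subsequent SNP within `binSpan` bp of that
#' first SNP, close, repeat. Each region spans
#' `[first_snp, first_snp + binSpan)`.
#'
#' @param snps `data.frame` with `chrom` and `pos` (1-based), sorted by
#'   position within chromosome.
#' @param binSpan region span in bp.
#' @return `data.frame` of regions: `chrom`, `start`, `end`, `midpoint`,
#'   `n_snps`.
#' @export
binSnps <- function(snps, binSpan = 25000) {
  out <- list()
  for (ch in unique(snps$chrom)) {
    pos <- sort(snps$pos[snps$chrom == ch])
    i <- 1
    while (i <= length(pos)) {
      first <- pos[i]
      inBin <- pos >= first & pos < first + binSpan
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = first, end = first + binSpan,
        midpoint = first + binSpan / 2, n_snps = sum(inBin))
      i <- max(which(inBin)) + 1
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Count chromatin interactions near region midpoints
#'
#' An interaction is counted for a region iff either of its two anchor
#' intervals overlaps the window `[midpoint - flank, midpoint + flank]`;
#' each interaction counts at most once per region.
#'
#' @param bins region `data.frame` from [binSnps()].
#' @param interactions BEDPE-style `data.frame` (`chrom1`, `start1`, `end1`,
#'   `chrom2`, `start2`, `end2`, 0-based half-open anchors).
#' @param flank window half-width in bp.
#' @return `bins` with a `chiapet_count` column.
#' @export
countChiaPet <- function(bins, interactions, flank = 1e5) {
  bad <- with(interactions, start1 > end1 | start2 > end2 |
                is.na(start1) | is.na(start2))
  if (any(bad)) {
    warning(sum(bad), " malformed BEDPE rows skipped")
    interactions <- interactions[!bad, , drop = FALSE]
  }
  counts <- integer(nrow(bins))
  if (nrow(interactions)) {
    win <- GenomicRanges::GRanges(bins$chrom,
      IRanges::IRanges(pmax(1, bins$midpoint - flank), bins$midpoint + flank))
    a1 <- GenomicRanges::GRanges(interactions$chrom1,
      IRanges::IRanges(interactions$start1 + 1, pmax(interactions$end1,
                                                     interactions$start1 + 1)))
    a2 <- GenomicRanges::GRanges(interactions$chrom2,
      IRanges::IRanges(interactions$start2 + 1, pmax(interactions$end2,
                                                     interactions$start2 + 1)))
    h1 <- GenomicRanges::findOverlaps(win, a1)
    h2 <- GenomicRanges::findOverlaps(win, a2)
    hitList <- split(c(S4Vectors::subjectHits(h1), S4Vectors::subjectHits(h2)),
                     c(S4Vectors::queryHits(h1), S4Vectors::queryHits(h2)))
    idx <- as.integer(names(hitList))
    counts[idx] <- vapply(hitList, function(x) length(unique(x)), integer(1))
  }
  bins$chiapet_count <- counts
  bins
}

#' Empirical rank of a focal region's interaction count
#'
#' Fraction of regions with strictly more interactions than the focal
#' region ("had more ... than": strict inequality).
#'
#' @param bins region `data.frame` with `chiapet_count`.
#' @param focal index of the focal region in `bins`, or a one-row
#'   `data.frame` matched by `chrom`/`start`.
#' @return list `fraction`, `numerator`, `denominator`.
#' @export
empiricalRank <- function(bins, focal) {
  stopifnot(nrow(bins) >= 2)
  if (is.data.frame(focal)) {
    focal <- which(bins$chrom == focal$chrom[1] &
                     bins$start == focal$start[1])[1]
    if (is.na(focal)) stop("focal region not found among bins")
  }
  num <- sum(bins$chiapet_count > bins$chiapet_count[focal])
  list(fraction = num / nrow(bins), numerator = num,
       denominator = nrow(bins))
}
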