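# File formats: PLINK bed/bim/fam (SNP-major binary), phenotype TSV,
# BED4 and BEDPE annotation tracks. Coordinate conventions: SNP positions
# are 1-based (BIM/VCF); BED/BEDPE intervals are 0-based half-open.

#' Read a PLINK bed/bim/fam fileset
#'
#' SNP-major .bed decoding with the standard 2-bit dialect: `00` =
#' homozygous A1, `01` = missing, `10` = heterozygous, `11` = homozygous
#' A2. By default A1 is treated as the alternate (counted) allele, so
#' genotype = 2 - (number of A2 alleles); set `a1Alt = FALSE` to count A2.
#'
#' @param prefix path prefix (without extension).
#' @param a1Alt logical; count A1 as the alternate allele.
#' @return [GenotypeData-class].
#' @export
readPlink <- function(prefix, a1Alt = TRUE) {
  bedPath <- paste0(prefix, ".bed")
  bim <- read.table(paste0(prefix, ".bim"), header = FALSE,
                    col.names = c("chrom", "snp_id", "cm", "pos", "a1", "a2"),
                    colClasses = c("character", "character", "numeric",
                                   "integer", "character", "character"))
  fam <- read.table(paste0(prefix, ".fam"), header = FALSE,
                    col.names = c("fid", "iid", "pat", "mat", "sex", "pheno"),
                    colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  bytesPerSnp <- ceiling(n / 4)
  expect <- 3 + bytesPerSnp * m
  sz <- file.size(bedPath)
  raw <- readBin(bedPath, "raw", n = expect + 1)
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b))
    stop("not a PLINK .bed file (bad magic bytes)")
  if (raw[3] != as.raw(0x01))
    stop("only SNP-major .bed (mode byte 0x01) is supported")
  if (sz != expect)
    stop("truncated or oversized .bed: expected ", expect, " bytes, found ",
         sz)
  body <- as.integer(raw[-(1:3)])
  # expand each byte into 4 two-bit codes, sample-fastest
  codes <- matrix(0L, bytesPerSnp * 4, m)
  b <- matrix(body, bytesPerSnp, m)
  for (k in 0:3)
    codes[seq(k + 1, by = 4, length.out = bytesPerSnp), ] <-
      (b %/% 4^k) %% 4L
  codes <- codes[seq_len(n), , drop = FALSE]
  # 00->2 A1, 10->1, 11->0, 01->missing (A1 counted)
  g <- matrix(NA_integer_, n, m)
  g[codes == 0L] <- 2L
  g[codes == 2L] <- 1L
  g[codes == 3L] <- 0L
  if (!a1Alt) g <- 2L - g
  map <- data.frame(snp_id = bim$snp_id, chrom = bim$chrom, pos = bim$pos,
                    allele_ref = if (a1Alt) bim$a2 else bim$a1,
                    allele_alt = if (a1Alt) bim$a1 else bim$a2,
                    stringsAsFactors = FALSE)
  GenotypeData(g, map, samples = fam$iid)
}

#' Write a PLINK bed/bim/fam fileset
#'
#' SNP-major .bed with magic bytes 0x6C 0x1B 0x01; the alternate allele is
#' written as A1 so [readPlink()] round-trips bit-identically.
#'
#' @param gd [GenotypeData-class].
#' @param prefix output path prefix.
#' @return invisibly, the prefix.
#' @export
writePlink <- function(gd, prefix) {
  g <- genotypes(gd)
  map <- markerMap(gd)
  n <- nrow(g); m <- ncol(g)
  bim <- data.frame(map$chrom, map$snp_id, 0, map$pos, map$allele_alt,
                    map$allele_ref)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(sampleIds(gd), sampleIds(gd), 0, 0, 0, -9)
  write.table(fam, paste0(prefix, ".fam"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  codeOf <- c(`0` = 3L, `1` = 2L, `2` = 0L)  # A1 = alt
  bytesPerSnp <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- bytesPerSnp * 4 - n
  for (j in seq_len(m)) {
    v <- g[, j]
    code <- ifelse(is.na(v), 1L, codeOf[as.character(v)])
    code <- c(code, rep(0L, pad))
    cm <- matrix(code, 4, bytesPerSnp)
    bytes <- cm[1, ] + 4L * cm[2, ] + 16L * cm[3, ] + 64L * cm[4, ]
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Read a phenotype + covariate TSV
#'
#' Expects a header with at least `sample_id` and `trait`.
#'
#' @param path file path.
#' @return `data.frame`.
#' @export
readPhenotypeTable <- function(path) {
  ph <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("sample_id", "trait")
  if (!all(need %in% names(ph)))
    stop("phenotype table must have columns: ", paste(need, collapse = ", "))
  ph$sample_id <- as.character(ph$sample_id)
  ph
}

#' Write a phenotype table / generic TSV
#' @param x `data.frame`. @param path output file.
#' @export
writeTsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a BED track (0-based half-open)
#'
#' Parsed with rtracklayer and returned as a plain `data.frame` in BED
#' coordinates.
#'
#' @param path BED file.
#' @return `data.frame` `chrom`, `start`, `end`, `name`.
#' @export
readBedTrack <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             name = if (!is.null(gr$name)) gr$name else
               sprintf("iv%04d", seq_along(gr)),
             stringsAsFactors = FALSE)
}

#' Write a BED4 track
#' @param track `data.frame` `chrom`, `start`, `end`, `name`.
#' @param path output file.
#' @export
writeBedTrack <- function(track, path) {
  write.table(track[, c("chrom", "start", "end", "name")], path,
              sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE interaction file (0-based half-open anchors)
#'
#' @param path BEDPE file (chrom1 start1 end1 chrom2 start2 end2 [name
#'   score]).
#' @return `data.frame` with those columns.
#' @export
readBedpe <- function(path) {
  x <- read.table(path, header = FALSE, sep = "\t",
                  stringsAsFactors = FALSE)
  cols <- c("chrom1", "start1", "end1", "chrom2", "start2", "end2",
            "name", "score")
  names(x) <- cols[seq_len(ncol(x))]
  x
}

#' Write a BEDPE interaction file
#' @param loops `data.frame` as from [simulateAnnotations()].
#' @param path output file.
#' @export
writeBedpe <- function(loops, path) {
  write.table(loops, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
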