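#' @useDynLib EpistasisScan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importFrom stats anova aov coef complete.cases cor dbinom ecdf lm
#'   lm.fit model.matrix na.omit optimize p.adjust pbinom pchisq pf pnorm
#'   qnorm rbinom rexp rnorm rpois runif sd setNames var
#' @importFrom utils read.table write.table head
NULL

#' GenotypeData: samples-by-SNPs genotype matrix with a marker map
#'
#' The central genotype container. Genotypes are stored as an integer matrix
#' (rows = samples, columns = SNPs) coding the count of the alternate allele
#' (0/1/2), with `NA` for missing calls. The marker map carries one row per
#' SNP with 1-based physical positions, strictly increasing within each
#' chromosome.
#'
#' @slot genotypes integer matrix, samples x SNPs, values 0/1/2/NA.
#' @slot map `data.frame` with columns `snp_id`, `chrom`, `pos`,
#'   `allele_ref`, `allele_alt`; `snp_id` unique, `pos` strictly increasing
#'   within chromosome.
#' @slot samples character vector of sample identifiers.
#'
#' @seealso [GenotypeData()] for the constructor, [genotypes()],
#'   [markerMap()], [sampleIds()] for accessors.
#' @export
setClass("GenotypeData",
  representation(
    genotypes = "matrix",
    map       = "data.frame",
    samples   = "character"
  )
)

setValidity("GenotypeData", function(object) {
  g <- object@genotypes
  map <- object@map
  msg <- character()
  need <- c("snp_id", "chrom", "pos", "allele_ref", "allele_alt")
  if (!all(need %in% names(map)))
    msg <- c(msg, paste("map must have columns:", paste(need, collapse = ", ")))
  else {
    if (ncol(g) != nrow(map))
      msg <- c(msg, "ncol(genotypes) must equal nrow(map)")
    if (anyDuplicated(map$snp_id))
      msg <- c(msg, "snp_ids must be unique")
    byc <- split(map$pos, map$chrom)
    if (any(vapply(byc, function(p) any(diff(p) <= 0), logical(1))))
      msg <- c(msg, "positions must be strictly increasing within chromosome")
  }
  if (length(object@samples) != nrow(g))
    msg <- c(msg, "length(samples) must equal nrow(genotypes)")
  bad <- g[!is.na(g)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    msg <- c(msg, "genotypes must be 0, 1, 2 or NA")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeData object
#'
#' @param genotypes samples x SNPs matrix of 0/1/2/NA allele counts.
#' @param map marker map `data.frame` (`snp_id`, `chrom`, `pos`,
#'   `allele_ref`, `allele_alt`).
#' @param samples sample identifiers; defaults to rownames or `S1..Sn`.
#' @return A [GenotypeData-class] object.
#' @examples
#' map <- data.frame(snp_id = c("a", "b"), chrom = "1", pos = c(100L, 200L),
#'                   allele_ref = "A", allele_alt = "B")
#' gd <- GenotypeData(matrix(c(0L, 1L, 2L, 1L), 2, 2), map)
#' nSnps(gd)
#' @export
GenotypeData <- function(genotypes, map, samples = NULL) {
  storage.mode(genotypes) <- "integer"
  if (is.null(samples)) {
    samples <- rownames(genotypes)
    if (is.null(samples)) samples <- paste0("S", seq_len(nrow(genotypes)))
  }
  map$snp_id <- as.character(map$snp_id)
  map$chrom <- as.character(map$chrom)
  map$pos <- as.integer(map$pos)
  rownames(map) <- NULL
  colnames(genotypes) <- map$snp_id
  rownames(genotypes) <- samples
  new("GenotypeData", genotypes = genotypes, map = map,
      samples = as.character(samples))
}

#' BitGenotypes: bit-plane encoded genotypes
#'
#' A lossless bit-packed encoding used by the pairwise interaction scan.
#' Each SNP is stored as four 64-bit-word planes over samples: one plane per
#' genotype class (0, 1, 2) plus a called-mask plane. The class planes are
#' mutually disjoint and their union is the called mask, so 9-cell two-locus
#' contingency tables are obtained by ANDing planes and counting set bits.
#'
#' @slot bits raw vector holding the packed planes.
#' @slot nSamples number of samples.
#' @slot nSnps number of SNPs.
#' @slot snpIds SNP identifiers, in encoding order.
#' @seealso [encodeBitwise()], [decodeBitwise()], [bitPlaneCounts()]
#' @export
setClass("BitGenotypes",
  representation(bits = "raw", nSamples = "integer", nSnps = "integer",
                 snpIds = "character"))

#' PolygenicFit: mixed-model fit producing the analysis trait
#'
#' Result of [fitPolygenic()]: REML variance components for a single
#' polygenic component against a kinship matrix, GLS fixed-effect estimates,
#' and the environmental residuals (`pgresidualY`) that all downstream
#' association and interaction tests use as the trait.
#'
#' @slot h2 narrow-sense polygenic heritability, `sigmaG2/(sigmaG2+sigmaE2)`.
#' @slot sigmaG2,sigmaE2 genetic and environmental variance components.
#' @slot beta named fixed-effect estimates (GLS at the REML optimum).
#' @slot pgresidualY per-sample environmental residuals (trait minus fixed
#'   effects minus polygenic BLUP).
#' @slot loglik restricted log-likelihood at the optimum.
#' @slot eigenK eigendecomposition of the kinship matrix (list `values`,
#'   `vectors`), retained so score tests can rebuild the trait covariance.
#' @slot samples sample ids the fit is aligned to.
#' @export
setClass("PolygenicFit",
  representation(h2 = "numeric", sigmaG2 = "numeric", sigmaE2 = "numeric",
                 beta = "numeric", pgresidualY = "numeric", loglik = "numeric",
                 eigenK = "list", samples = "character"))

setValidity("PolygenicFit", function(object) {
  msg <- character()
  if (object@h2 < 0 || object@h2 >= 1) msg <- c(msg, "h2 must be in [0, 1)")
  tot <- object@sigmaG2 + object@sigmaE2
  if (tot > 0 && abs(object@h2 - object@sigmaG2 / tot) > 1e-6)
    msg <- c(msg, "h2 must equal sigmaG2/(sigmaG2+sigmaE2)")
  if (length(msg)) msg else TRUE
})

#' QcReport: quality-control masks and reasons
#'
#' @slot snpMask logical per SNP; `TRUE` = keep.
#' @slot sampleMask logical per sample; `TRUE` = keep.
#' @slot snpReasons,sampleReasons named list mapping a failed entity to the
#'   character vector of rules it failed.
#' @slot counts named integer vector: entities removed per rule.
#' @export
setClass("QcReport",
  representation(snpMask = "logical", sampleMask = "logical",
                 snpReasons = "list", sampleReasons = "list",
                 counts = "integer"))

setValidity("QcReport", function(object) {
  failSnp <- names(object@snpReasons)
  failSmp <- names(object@sampleReasons)
  ok <- all(lengths(object@snpReasons) >= 1L) &&
        all(lengths(object@sampleReasons) >= 1L)
  if (!ok) return("every failed entity must carry at least one reason")
  TRUE
})

#' Thresholds: Bonferroni-derived significance thresholds for the scan
#'
#' Holds the genome-wide threshold for the full pairwise scan
#' (`0.05 / (m(m-1)/2)` for `m` SNPs), the threshold for pairs involving at
#' least one marginal SNP (`0.05 / ((m-1) k)` for `k` marginal SNPs), the
#' fixed local-interaction threshold (1e-5) and the consensus single-SNP
#' GWAS threshold (5e-8). Raw values are kept for comparisons; reporting
#' rounds to two significant figures.
#'
#' @slot tFull,tMarginal raw Bonferroni thresholds (NA when undefined).
#' @slot tLocal,tGwas fixed conventional thresholds.
#' @slot mSnps,nMarginal the counts the thresholds were derived from.
#' @seealso [deriveThresholds()]
#' @export
setClass("Thresholds",
  representation(tFull = "numeric", tMarginal = "numeric", tLocal = "numeric",
                 tGwas = "numeric", mSnps = "integer", nMarginal = "integer"))

#' SelectionPath: forward-selection result
#'
#' Ordered model terms (marginal SNPs and epistatic pairs) with the
#' conditional P at entry and cumulative variance explained, mirroring the
#' statistical-construction table of a locus.
#'
#' @slot terms list of terms as accepted (each a list with `kind`, `snps`,
#'   `p_conditional`).
#' @slot table `data.frame` with one row per accepted term: `kind`, `snp1`,
#'   `pos1`, `snp2`, `pos2`, `dist_kb`, `r2`, `p`, `variance_explained_cum`.
#' @export
setClass("SelectionPath",
  representation(terms = "list", table = "data.frame"))

setValidity("SelectionPath", function(object) {
  v <- object@table$variance_explained_cum
  if (length(v) > 1 && any(diff(v) < -1e-8))
    return("cumulative variance explained must be non-decreasing")
  TRUE
})

## ---- generics ----

#' @rdname GenotypeData-class
#' @param object,x a `GenotypeData` object.
#' @export
setGeneric("genotypes", function(x) standardGeneric("genotypes"))
#' @rdname GenotypeData-class
#' @export
setGeneric("markerMap", function(x) standardGeneric("markerMap"))
#' @rdname GenotypeData-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname GenotypeData-class
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname GenotypeData-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname PolygenicFit-class
#' @param x a `PolygenicFit`.
#' @export
setGeneric("heritability", function(x) standardGeneric("heritability"))
#' @rdname PolygenicFit-class
#' @export
setGeneric("varianceComponents", function(x) standardGeneric("varianceComponents"))
#' @rdname PolygenicFit-class
#' @export
setGeneric("pgResiduals", function(x) standardGeneric("pgResiduals"))
#' @rdname PolygenicFit-class
#' @export
setGeneric("fixedEffects", function(x) standardGeneric("fixedEffects"))

#' @rdname QcReport-class
#' @param x a `QcReport`.
#' @export
setGeneric("snpMask", function(x) standardGeneric("snpMask"))
#' @rdname QcReport-class
#' @export
setGeneric("sampleMask", function(x) standardGeneric("sampleMask"))
#' @rdname QcReport-class
#' @export
setGeneric("qcCounts", function(x) standardGeneric("qcCounts"))

#' @rdname SelectionPath-class
#' @param x a `SelectionPath`.
#' @export
setGeneric("pathTable", function(x) standardGeneric("pathTable"))

## ---- methods ----

#' @rdname GenotypeData-class
#' @export
setMethod("genotypes", "GenotypeData", function(x) x@genotypes)
#' @rdname GenotypeData-class
#' @export
setMethod("markerMap", "GenotypeData", function(x) x@map)
#' @rdname GenotypeData-class
#' @export
setMethod("sampleIds", "GenotypeData", function(x) x@samples)
#' @rdname GenotypeData-class
#' @export
setMethod("nSnps", "GenotypeData", function(x) ncol(x@genotypes))
#' @rdname GenotypeData-class
#' @export
setMethod("nSamples", "GenotypeData", function(x) nrow(x@genotypes))

setMethod("show", "GenotypeData", function(object) {
  cat("GenotypeData:", nrow(object@genotypes), "samples x",
      ncol(object@genotypes), "SNPs\n")
  cat("  chromosomes:", paste(unique(object@map$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(object@genotypes))
  cat(sprintf("  missing call rate: %.4f\n", miss))
})

#' Subset a GenotypeData object
#'
#' `[` subsets samples (i) and SNPs (j), keeping map and ids in register.
#'
#' @param x a `GenotypeData`.
#' @param i sample index. @param j SNP index.
#' @param drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "GenotypeData", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@genotypes))
  if (missing(j)) j <- seq_len(ncol(x@genotypes))
  if (is.character(j)) j <- match(j, x@map$snp_id)
  GenotypeData(x@genotypes[i, j, drop = FALSE], x@map[j, , drop = FALSE],
               x@samples[i])
})

#' @rdname PolygenicFit-class
#' @export
setMethod("heritability", "PolygenicFit", function(x) x@h2)
#' @rdname PolygenicFit-class
#' @export
setMethod("varianceComponents", "PolygenicFit",
          function(x) c(sigmaG2 = x@sigmaG2, sigmaE2 = x@sigmaE2))
#' @rdname PolygenicFit-class
#' @export
setMethod("pgResiduals", "PolygenicFit", function(x) x@pgresidualY)
#' @rdname PolygenicFit-class
#' @export
setMethod("fixedEffects", "PolygenicFit", function(x) x@beta)

setMethod("show", "PolygenicFit", function(object) {
  cat("PolygenicFit\n")
  cat(sprintf("  h2 = %.4f (sigmaG2 = %.4f, sigmaE2 = %.4f)\n",
              object@h2, object@sigmaG2, object@sigmaE2))
  cat(sprintf("  REML loglik = %.3f; n = %d samples\n", object@loglik,
              length(object@pgresidualY)))
})

#' @rdname QcReport-class
#' @export
setMethod("snpMask", "QcReport", function(x) x@snpMask)
#' @rdname QcReport-class
#' @export
setMethod("sampleMask", "QcReport", function(x) x@sampleMask)
#' @rdname QcReport-class
#' @export
setMethod("qcCounts", "QcReport", function(x) x@counts)

setMethod("show", "QcReport", function(object) {
  cat("QcReport:", sum(!object@snpMask), "SNPs and",
      sum(!object@sampleMask), "samples removed\n")
  if (length(object@counts)) {
    for (r in names(object@counts))
      cat(sprintf("  %-12s %d\n", r, object@counts[[r]]))
  }
})

setMethod("show", "Thresholds", function(object) {
  cat("Scan significance thresholds (Bonferroni)\n")
  cat(sprintf("  full pairwise  : %s  (m = %d SNPs)\n",
              formatThreshold(object@tFull), object@mSnps))
  cat(sprintf("  marginal pairs : %s  (k = %d marginal SNPs)\n",
              formatThreshold(object@tMarginal), object@nMarginal))
  cat(sprintf("  local          : %s\n", formatThreshold(object@tLocal)))
  cat(sprintf("  GWAS consensus : %s\n", formatThreshold(object@tGwas)))
})

#' @rdname SelectionPath-class
#' @export
setMethod("pathTable", "SelectionPath", function(x) x@table)

setMethod("show", "SelectionPath", function(object) {
  cat("SelectionPath with", length(object@terms), "terms\n")
  if (nrow(object@table)) print(object@table, row.names = FALSE)
})
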