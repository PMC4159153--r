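# Pipeline driver: QC -> polygenic residualization -> marginal scan ->
# pairwise interaction scan -> forward selection -> enrichment, writing one
# TSV artifact per stage. Every output is reproducible from the
# configuration plus seed.

#' Build a pipeline configuration
#'
#' @param outDir artifact directory (created if absent).
#' @param mafMin,snpCallrateMin,hwePMin,indCallrateMin,hetFdr QC thresholds.
#' @param nPc kinship PCs used as fixed effects.
#' @param scanMode `"full"`, `"marginal"` or `"local"`.
#' @param alpha forward-selection significance level.
#' @param sexStratified also run the pair scan per sex stratum.
#' @param seed master seed recorded in the log.
#' @return named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(outDir, mafMin = 0.02, snpCallrateMin = 0.95,
                           hwePMin = 1e-10, indCallrateMin = 0.97,
                           hetFdr = 0.01, nPc = 10,
                           scanMode = "local", alpha = 0.05,
                           sexStratified = FALSE, seed = 1) {
  stopifnot(mafMin > 0, snpCallrateMin > 0, hwePMin > 0, alpha > 0)
  structure(list(outDir = outDir, mafMin = mafMin,
                 snpCallrateMin = snpCallrateMin, hwePMin = hwePMin,
                 indCallrateMin = indCallrateMin, hetFdr = hetFdr,
                 nPc = nPc, scanMode = scanMode, alpha = alpha,
                 sexStratified = sexStratified, seed = seed),
            class = "PipelineConfig")
}

#' Run the full analysis pipeline on a cohort
#'
#' Stages in order: quality control, kinship + polygenic residualization,
#' marginal (GWAS) scan, pairwise interaction scan, classification, forward
#' selection over significant terms, and (when tracks are given) enhancer
#' enrichment. Artifacts are written as TSVs under `config$outDir`; the log
#' records the thresholds actually used.
#'
#' @param gd [GenotypeData-class].
#' @param pheno phenotype table (`sample_id`, `trait`, covariates).
#' @param config from [pipelineConfig()].
#' @param tracks optional named list of BED-style enhancer tracks.
#' @param interactions optional BEDPE `data.frame` of chromatin loops.
#' @return invisible list with the per-stage results (`qc`, `residual`,
#'   `gwas`, `pairs`, `path`, `enrichment`, `thresholds`).
#' @export
runPipeline <- function(gd, pheno, config, tracks = NULL,
                        interactions = NULL) {
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  logPath <- file.path(config$outDir, "pipeline.log")
  logLine <- function(...) cat(..., "\n", sep = "", file = logPath,
                               append = TRUE)
  cat("", file = logPath)
  logLine("seed=", config$seed)
  stage <- "qc"
  res <- tryCatch({
    qc <- runQc(gd, pheno, mafMin = config$mafMin,
                callrateSnpMin = config$snpCallrateMin,
                hwePMin = config$hwePMin,
                callrateIndMin = config$indCallrateMin,
                hetFdr = config$hetFdr)
    writeQcReport(qc, file.path(config$outDir, "qc_report.tsv"))
    flt <- applyQc(gd, pheno, qc)
    logLine("qc: kept ", nSamples(flt$gd), " samples, ", nSnps(flt$gd),
            " SNPs")

    stage <- "grammar"
    resid <- residualizeTrait(flt$gd, flt$pheno, nPc = config$nPc)
    writeTsv(data.frame(sample_id = names(resid$pgresidualY),
                        pgresidualY = as.numeric(resid$pgresidualY)),
             file.path(config$outDir, "residuals.tsv"))
    logLine("grammar: h2=", signif(heritability(resid$fit), 4),
            " sigmaG2=", signif(resid$fit@sigmaG2, 4),
            " sigmaE2=", signif(resid$fit@sigmaE2, 4))

    stage <- "scan"
    gwas <- marginalScan(resid$fit, flt$gd)
    writeTsv(gwas, file.path(config$outDir, "gwas.tsv"))
    marg <- gwas$snp_id[gwas$marginal]
    th <- deriveThresholds(nSnps(flt$gd), length(marg))
    logLine("thresholds: t_full=", formatThreshold(th@tFull),
            " t_marginal=", formatThreshold(th@tMarginal),
            " t_local=", formatThreshold(th@tLocal))
    y <- resid$pgresidualY
    pairs <- scanPairs(flt$gd, y, th, mode = config$scanMode,
                       marginalSnps = marg)
    writeTsv(pairs[, c("chr1", "snp1", "pos1", "chr2", "snp2", "pos2",
                       "dist_kb", "r2", "p_screen", "p_full", "category")],
             file.path(config$outDir, "pairs.tsv"))
    logLine("scan: ", nrow(pairs), " pairs emitted (mode=", config$scanMode,
            ")")
    strat <- NULL
    if (isTRUE(config$sexStratified) && "sex" %in% names(flt$pheno)) {
      strat <- list()
      for (sx in sort(unique(flt$pheno$sex))) {
        idx <- which(flt$pheno$sex == sx)
        ps <- scanPairs(flt$gd[idx, ], y[idx], th, mode = config$scanMode,
                        marginalSnps = marg)
        fn <- file.path(config$outDir, paste0("pairs_sex", sx, ".tsv"))
        writeTsv(ps[, c("chr1", "snp1", "pos1", "chr2", "snp2", "pos2",
                        "dist_kb", "r2", "p_screen", "p_full", "category")],
                 fn)
        strat[[as.character(sx)]] <- ps
        logLine("scan[sex=", sx, "]: ", nrow(ps), " pairs")
      }
    }

    stage <- "modelbuild"
    cand <- c(lapply(marg, function(s) modelTerm("marginal", s)),
              lapply(seq_len(nrow(pairs)), function(k)
                modelTerm("pair", c(pairs$snp1[k], pairs$snp2[k]))))
    path <- NULL
    if (length(cand)) {
      path <- forwardSelect(cand, y, flt$gd, alpha = config$alpha)
      writeTsv(pathTable(path), file.path(config$outDir,
                                          "selection_path.tsv"))
      logLine("modelbuild: ", length(path@terms), " terms selected")
    }

    stage <- "enrich"
    enr <- NULL
    if (!is.null(tracks) && nrow(pairs)) {
      epiSnps <- unique(c(pairs$snp1, pairs$snp2))
      map <- markerMap(flt$gd)
      tagged <- map[map$snp_id %in% epiSnps, c("chrom", "pos")]
      bgSnps <- map[, c("chrom", "pos")]
      enr <- enhancerEnrichment(tagged, bgSnps, tracks)
      writeTsv(enr, file.path(config$outDir, "enrichment.tsv"))
      logLine("enrich: ", nrow(enr), " cell types tested")
    }
    list(qc = qc, residual = resid, gwas = gwas, pairs = pairs,
         stratified = strat, path = path, enrichment = enr,
         thresholds = th)
  }, error = function(e) {
    logLine("FAILED at stage ", stage, ": ", conditionMessage(e))
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}
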