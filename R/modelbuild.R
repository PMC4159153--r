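# Conditional testing, forward selection over marginal SNPs and epistatic
# pairs, cumulative variance-explained accounting, and cross-cohort
# replication bookkeeping.

#' Construct a model term
#'
#' @param kind `"marginal"` or `"pair"`.
#' @param snps one SNP id (marginal) or two (pair).
#' @return term list used by [conditionalTest()] and [forwardSelect()].
#' @export
modelTerm <- function(kind = c("marginal", "pair"), snps) {
  kind <- match.arg(kind)
  stopifnot(length(snps) == if (kind == "marginal") 1 else 2)
  list(kind = kind, snps = as.character(snps))
}

# Background design columns for a list of terms: marginal SNPs enter
# additive-only; pairs enter with full 9-cell factor coding.
termDesign <- function(terms, gd) {
  if (!length(terms)) return(NULL)
  g <- genotypes(gd)
  map <- markerMap(gd)
  cols <- lapply(terms, function(tm) {
    idx <- match(tm$snps, map$snp_id)
    if (anyNA(idx)) stop("term references SNP absent from map: ",
                         paste(tm$snps, collapse = ","))
    if (tm$kind == "marginal") {
      matrix(g[, idx], ncol = 1,
             dimnames = list(NULL, tm$snps))
    } else {
      f1 <- factor(g[, idx[1]], levels = 0:2)
      f2 <- factor(g[, idx[2]], levels = 0:2)
      mm <- model.matrix(~ f1 * f2)[, -1, drop = FALSE]
      colnames(mm) <- paste0(paste(tm$snps, collapse = "x"), ".",
                             colnames(mm))
      # model.matrix drops rows with NA factors; rebuild with NA rows
      full <- matrix(NA_real_, nrow(g), ncol(mm),
                     dimnames = list(NULL, colnames(mm)))
      ok <- !is.na(g[, idx[1]]) & !is.na(g[, idx[2]])
      full[ok, ] <- model.matrix(~ f1 * f2,
        data = data.frame(f1 = f1[ok], f2 = f2[ok]))[, -1, drop = FALSE]
      full
    }
  })
  do.call(cbind, cols)
}

#' Conditional association / interaction test of a term
#'
#' Tests a marginal SNP (1-df additive partial F) or an epistatic pair
#' (interaction partial F over the two-locus main effects) with the
#' background terms held in the model as fixed effects. A term is declared
#' statistically independent of the background when the conditional P is
#' below 0.05. A term collinear with the background (e.g. conditioning a
#' SNP on itself) yields an absent P with reason `"collinear"`.
#'
#' @param term a [modelTerm()].
#' @param background list of [modelTerm()]s (may be empty).
#' @param y environmental residual trait.
#' @param gd [GenotypeData-class].
#' @return list `p`, `df1`, `df2`, `n`, `reason` ("" when testable).
#' @export
conditionalTest <- function(term, background, y, gd) {
  map <- markerMap(gd)
  g <- genotypes(gd)
  bg <- termDesign(background, gd)
  idx <- match(term$snps, map$snp_id)
  if (anyNA(idx)) stop("term references SNP absent from map")
  if (term$kind == "pair") {
    res <- pairFullTest(g[, idx[1]], g[, idx[2]], y, background = bg)
    if (is.na(res$p) && res$note == "no interaction df")
      return(list(p = NA_real_, df1 = 0L, df2 = res$df2, n = res$n,
                  reason = "collinear"))
    return(list(p = res$p, df1 = res$df1, df2 = res$df2, n = res$n,
                reason = if (is.na(res$p)) res$note else ""))
  }
  x <- g[, idx]
  keep <- !is.na(x) & !is.na(y)
  if (!is.null(bg)) keep <- keep & complete.cases(bg)
  X0 <- if (is.null(bg)) matrix(1, sum(keep), 1) else
    cbind(1, bg[keep, , drop = FALSE])
  X1 <- cbind(X0, x[keep])
  q0 <- qr(X0); q1 <- qr(X1)
  if (q1$rank <= q0$rank)
    return(list(p = NA_real_, df1 = 0L, df2 = sum(keep) - q0$rank,
                n = sum(keep), reason = "collinear"))
  r0 <- qr.resid(q0, y[keep]); r1 <- qr.resid(q1, y[keep])
  rss0 <- sum(r0^2); rss1 <- sum(r1^2)
  df2 <- sum(keep) - q1$rank
  Fv <- (rss0 - rss1) / (rss1 / df2)
  list(p = pf(Fv, 1, df2, lower.tail = FALSE), df1 = 1L, df2 = df2,
       n = sum(keep), reason = "")
}

#' Cumulative variance explained along a term path
#'
#' Refits the polygenic model with the terms' design columns as fixed
#' effects (marginal SNPs additive-only, pairs full 9-cell coding) and
#' reports `Var(fitted genetic contribution) / Var(trait) * 100`,
#' accumulated along the path. With no kinship (or an identity kinship) the
#' fit is ordinary least squares. Singular columns are dropped with a
#' warning.
#'
#' @param terms list of [modelTerm()]s, in path order.
#' @param y trait on the residual scale.
#' @param gd [GenotypeData-class].
#' @param K optional kinship matrix for the GLS refit.
#' @return numeric vector: cumulative percent variance explained at each
#'   step.
#' @export
varianceExplained <- function(terms, y, gd, K = NULL) {
  if (!length(terms)) return(numeric(0))
  out <- numeric(length(terms))
  vy <- var(y, na.rm = TRUE)
  for (s in seq_along(terms)) {
    X <- termDesign(terms[seq_len(s)], gd)
    keep <- complete.cases(X) & !is.na(y)
    Xk <- X[keep, , drop = FALSE]
    # all-zero columns are structural (empty genotype cells); drop silently
    Xk <- Xk[, colSums(Xk != 0) > 0, drop = FALSE]
    qx <- qr(cbind(1, Xk))
    if (qx$rank < ncol(Xk) + 1) {
      warning("singular term design at step ", s, "; dropping aliased columns")
    }
    if (is.null(K)) {
      fit <- lm.fit(cbind(`(Intercept)` = 1, Xk), y[keep])
      beta <- fit$coefficients[-1]
      beta[is.na(beta)] <- 0
      fitted <- Xk %*% beta
    } else {
      pfit <- fitPolygenic(y[keep], Xk, K[keep, keep])
      beta <- fixedEffects(pfit)
      beta <- beta[setdiff(names(beta), "(Intercept)")]
      beta[is.na(beta)] <- 0
      fitted <- Xk %*% beta
    }
    out[s] <- var(as.numeric(fitted)) / vy * 100
  }
  out
}

#' Forward selection over candidate terms
#'
#' Greedy loop: at each step every remaining candidate is conditionally
#' tested against the accepted background; the candidate with the lowest
#' conditional P enters if it is below `alpha`; the loop stops when no
#' remaining candidate is significant. Ties in the minimum P are broken by
#' genomic order (chromosome, position of the first SNP). Collinear
#' candidates are excluded with their reason recorded.
#'
#' @param candidates list of [modelTerm()]s.
#' @param y environmental residual trait.
#' @param gd [GenotypeData-class].
#' @param alpha conditional significance level.
#' @param K optional kinship for the variance-explained refit.
#' @return [SelectionPath-class].
#' @export
forwardSelect <- function(candidates, y, gd, alpha = 0.05, K = NULL) {
  stopifnot(length(candidates) >= 1)
  map <- markerMap(gd)
  g <- genotypes(gd)
  remaining <- candidates
  accepted <- list()
  rows <- list()
  repeat {
    if (!length(remaining)) break
    ps <- vapply(remaining, function(tm) {
      r <- conditionalTest(tm, accepted, y, gd)
      if (is.na(r$p)) Inf else r$p
    }, numeric(1))
    best <- min(ps)
    if (!is.finite(best) || best >= alpha) break
    cand <- which(ps <= best + 0)  # exact ties
    if (length(cand) > 1) {
      ord <- order(map$chrom[match(vapply(remaining[cand],
                                          function(tm) tm$snps[1], ""),
                                   map$snp_id)],
                   map$pos[match(vapply(remaining[cand],
                                        function(tm) tm$snps[1], ""),
                                 map$snp_id)])
      pick <- cand[ord[1]]
    } else pick <- cand
    tm <- remaining[[pick]]
    tm$p_conditional <- ps[pick]
    accepted[[length(accepted) + 1]] <- tm
    remaining <- remaining[-pick]
    i1 <- match(tm$snps[1], map$snp_id)
    i2 <- if (tm$kind == "pair") match(tm$snps[2], map$snp_id) else NA
    same <- tm$kind == "pair" && map$chrom[i1] == map$chrom[i2]
    r2 <- if (tm$kind == "pair")
      suppressWarnings(ldR2(g[, i1], g[, i2])) else NA_real_
    rows[[length(rows) + 1]] <- data.frame(
      kind = tm$kind, snp1 = tm$snps[1], pos1 = map$pos[i1],
      snp2 = if (tm$kind == "pair") tm$snps[2] else NA_character_,
      pos2 = if (tm$kind == "pair") map$pos[i2] else NA_integer_,
      dist_kb = if (same) roundHalfUp(abs(map$pos[i2] - map$pos[i1]) / 1000,
                                      1) else NA_real_,
      r2 = r2, p = tm$p_conditional, stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), snp1 = character(), pos1 = integer(),
               snp2 = character(), pos2 = integer(), dist_kb = numeric(),
               r2 = numeric(), p = numeric(), stringsAsFactors = FALSE)
  tab$variance_explained_cum <- if (length(accepted))
    varianceExplained(accepted, y, gd, K) else numeric(0)
  # accumulated fits can dip by numerical noise; clamp to monotone
  if (nrow(tab) > 1)
    tab$variance_explained_cum <- cummax(tab$variance_explained_cum)
  new("SelectionPath", terms = accepted, table = tab)
}

#' Cross-cohort replication of epistatic pairs
#'
#' A discovery pair is replicated only if both SNPs are genotyped in the
#' replication cohort and its interaction P there is strictly below
#' `alpha`; otherwise the record is NA (not directly replicable).
#'
#' @param pairs `data.frame` with `snp1`, `snp2` (discovery pairs).
#' @param gd2 replication-cohort [GenotypeData-class].
#' @param y2 replication-cohort residual trait.
#' @param alpha replication significance level.
#' @return `data.frame` `snp1`, `snp2`, `both_typed`, `p_int_replication`,
#'   `replicated` (logical, NA when not both typed).
#' @export
replicationCheck <- function(pairs, gd2, y2, alpha = 0.05) {
  map2 <- markerMap(gd2)
  g2 <- genotypes(gd2)
  n <- nrow(pairs)
  out <- data.frame(snp1 = pairs$snp1, snp2 = pairs$snp2,
                    both_typed = FALSE, p_int_replication = NA_real_,
                    replicated = NA, stringsAsFactors = FALSE)
  for (k in seq_len(n)) {
    i1 <- match(pairs$snp1[k], map2$snp_id)
    i2 <- match(pairs$snp2[k], map2$snp_id)
    if (is.na(i1) || is.na(i2)) next
    out$both_typed[k] <- TRUE
    p <- pairFullTest(g2[, i1], g2[, i2], y2)$p
    out$p_int_replication[k] <- p
    out$replicated[k] <- !is.na(p) && p < alpha
  }
  out
}
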