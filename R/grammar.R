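# GRAMMAR stage: genomic kinship, rank-inverse-normal transform, and the
# single-component REML polygenic fit whose environmental residuals
# (pgresidualY) are the trait used by every downstream association test.

#' Genomic kinship (GRM) from genotype dosages
#'
#' Allele-frequency-weighted relationship matrix: dosages are centred at
#' `2p` and scaled by `sqrt(2p(1-p))` per SNP (Astle-Balding style), missing
#' calls are replaced by the mean dosage (zero after centring), and the
#' matrix is the mean cross-product over polymorphic SNPs. Diagonal is ~1
#' for non-inbred samples; full sibs are ~0.5.
#'
#' @param gd [GenotypeData-class] with >= 2 samples and >= 2 polymorphic
#'   SNPs.
#' @return symmetric numeric matrix with sample ids as dimnames.
#' @export
genomicKinship <- function(gd) {
  g <- genotypes(gd)
  if (nrow(g) < 2) stop("need at least 2 samples")
  if (any(rowSums(!is.na(g)) == 0)) stop("sample with all genotypes missing")
  p <- colMeans(g, na.rm = TRUE) / 2
  poly <- which(p > 0 & p < 1)
  if (length(poly) < 2) stop("need at least 2 polymorphic SNPs")
  Z <- sweep(g[, poly, drop = FALSE], 2, 2 * p[poly])
  Z <- sweep(Z, 2, sqrt(2 * p[poly] * (1 - p[poly])), "/")
  Z[is.na(Z)] <- 0
  K <- tcrossprod(Z) / length(poly)
  dimnames(K) <- list(sampleIds(gd), sampleIds(gd))
  K
}

#' Principal components of a kinship matrix
#'
#' Eigenvectors of the kinship matrix itself, scaled by the square root of
#' their eigenvalues; used both for QC outlier screening and as fixed
#' covariates in the polygenic model.
#'
#' @param K symmetric kinship matrix.
#' @param nPc number of components.
#' @return n x nPc matrix of component scores.
#' @export
kinshipPCs <- function(K, nPc = 10) {
  ev <- eigen(K, symmetric = TRUE)
  nPc <- min(nPc, ncol(ev$vectors))
  sc <- ev$vectors[, seq_len(nPc), drop = FALSE] %*%
    diag(sqrt(pmax(ev$values[seq_len(nPc)], 0)), nPc)
  colnames(sc) <- paste0("PC", seq_len(nPc))
  rownames(sc) <- rownames(K)
  sc
}

#' Rank-based inverse normal transformation
#'
#' `qnorm((rank - 0.5) / n)` on the ranks of the input; ties share averaged
#' ranks. The output is monotone in the input with mean ~0 and SD ~1.
#'
#' @param y numeric vector with at least 2 distinct values; NAs propagate.
#' @return transformed vector of the same length.
#' @export
rankInverseNormal <- function(y) {
  ok <- !is.na(y)
  if (length(unique(y[ok])) < 2) stop("need at least 2 distinct values")
  out <- rep(NA_real_, length(y))
  r <- rank(y[ok], ties.method = "average")
  out[ok] <- qnorm((r - 0.5) / sum(ok))
  out
}

#' Fit the single-component polygenic mixed model by REML
#'
#' Model: `y = X beta + g + e`, `g ~ N(0, sigmaG2 K)`, `e ~ N(0, sigmaE2 I)`.
#' After one eigendecomposition of `K` the restricted likelihood is profiled
#' over the total variance and maximised over `h2 = sigmaG2/(sigmaG2+sigmaE2)`
#' by Brent search on [0, 1-1e-6] (tolerance 1e-8). Fixed effects are GLS at
#' the optimum; the polygenic BLUP is `sigmaG2 K V^-1 (y - X beta)` and the
#' environmental residuals are
#' `pgresidualY = y - X beta - BLUP = sigmaE2 V^-1 (y - X beta)`.
#'
#' When `K` is the identity (or `NULL`) the model has no identifiable
#' genetic component: the fit reduces to ordinary least squares with
#' `h2 = 0` and `pgresidualY` equal to the OLS residuals.
#'
#' @param y trait vector (typically rank-inverse-normal transformed,
#'   covariate-adjusted upstream or via `X`).
#' @param X fixed-effect design matrix (covariates and leading kinship PCs);
#'   an intercept column is added if absent. `NULL` for intercept-only.
#' @param K kinship matrix, or `NULL` for the identity.
#' @param eigenK optional precomputed `eigen(K, symmetric = TRUE)`.
#' @return [PolygenicFit-class].
#' @export
fitPolygenic <- function(y, X = NULL, K = NULL, eigenK = NULL) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (!any(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0)))
    X <- cbind("(Intercept)" = 1, X)
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  samples <- if (!is.null(K) && !is.null(rownames(K))) rownames(K)
             else paste0("S", seq_len(n))

  identityK <- is.null(K) ||
    (is.null(eigenK) && nrow(K) == n &&
       max(abs(K - diag(n))) < 1e-12)
  if (identityK) {
    fit <- lm.fit(X, y)
    res <- fit$residuals
    sigmaE2 <- sum(res^2) / (n - fit$rank)
    ll <- -0.5 * ((n - fit$rank) * (log(2 * pi * sigmaE2) + 1))
    return(new("PolygenicFit", h2 = 0, sigmaG2 = 0, sigmaE2 = sigmaE2,
               beta = setNames(fit$coefficients, colnames(X)),
               pgresidualY = as.numeric(res), loglik = ll,
               eigenK = list(values = rep(1, n), vectors = diag(n)),
               samples = samples))
  }

  if (is.null(eigenK)) eigenK <- eigen(K, symmetric = TRUE)
  lam <- pmax(eigenK$values, 0)
  U <- eigenK$vectors
  yt <- crossprod(U, y)
  Xt <- crossprod(U, X)
  p <- ncol(X)

  remlParts <- function(h2) {
    w <- h2 * lam + (1 - h2)
    Wi <- 1 / w
    XtWX <- crossprod(Xt, Xt * Wi)
    XtWy <- crossprod(Xt, yt * Wi)
    ch <- tryCatch(chol(XtWX), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    beta <- backsolve(ch, forwardsolve(t(ch), XtWy))
    r <- yt - Xt %*% beta
    rss <- sum(r^2 * Wi)
    sigma2 <- rss / (n - p)
    ll <- -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) + sum(log(w)) +
                    2 * sum(log(diag(ch))))
    list(ll = ll, beta = beta, sigma2 = sigma2, w = w, r = r)
  }
  negll <- function(h2) {
    parts <- remlParts(h2)
    if (is.null(parts) || !is.finite(parts$ll)) return(1e10)
    -parts$ll
  }
  opt <- optimize(negll, c(0, 1 - 1e-6), tol = 1e-8)
  # Brent can miss a boundary optimum; check the edges explicitly.
  h2 <- opt$minimum
  for (edge in c(0, 1 - 1e-6))
    if (negll(edge) < negll(h2)) h2 <- edge
  parts <- remlParts(h2)
  if (is.null(parts) || !is.finite(parts$ll))
    stop("non-finite restricted likelihood at the optimum (h2 = ", h2, ")")
  sigma2 <- parts$sigma2
  sigmaG2 <- h2 * sigma2
  sigmaE2 <- (1 - h2) * sigma2
  # pgresidualY = sigmaE2 V^-1 (y - X beta), V = sigma2 * diag(w) in U-space
  resid <- as.numeric(U %*% ((1 - h2) / parts$w * parts$r))
  new("PolygenicFit", h2 = h2, sigmaG2 = sigmaG2, sigmaE2 = sigmaE2,
      beta = setNames(as.numeric(parts$beta), colnames(X)),
      pgresidualY = resid, loglik = parts$ll,
      eigenK = list(values = lam, vectors = U), samples = samples)
}

#' Restricted log-likelihood of the polygenic model at a given h2
#'
#' Utility for profiling/diagnostics: evaluates the same profiled REML
#' criterion [fitPolygenic()] maximises.
#'
#' @param fitOrY a [PolygenicFit-class] (uses its stored eigendecomposition)
#'   together with `y` and `X`, the original data.
#' @param y,X trait and design used in the fit.
#' @param h2 heritability value(s) to evaluate.
#' @return numeric vector of restricted log-likelihoods.
#' @export
polygenicLoglik <- function(fitOrY, y, X = NULL, h2) {
  fit <- fitOrY
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (!any(apply(X, 2, function(col) all(col == col[1]) && col[1] != 0)))
    X <- cbind(1, X)
  lam <- fit@eigenK$values
  U <- fit@eigenK$vectors
  yt <- crossprod(U, y); Xt <- crossprod(U, X)
  p <- ncol(X)
  vapply(h2, function(hh) {
    w <- hh * lam + (1 - hh)
    Wi <- 1 / w
    XtWX <- crossprod(Xt, Xt * Wi)
    beta <- solve(XtWX, crossprod(Xt, yt * Wi))
    r <- yt - Xt %*% beta
    sigma2 <- sum(r^2 * Wi) / (n - p)
    -0.5 * ((n - p) * (log(2 * pi * sigma2) + 1) + sum(log(w)) +
              determinant(XtWX, logarithm = TRUE)$modulus[1])
  }, numeric(1))
}

#' Build the analysis trait for a cohort
#'
#' Convenience wrapper for the full residualization stage: rank-inverse
#' normal transform of the raw trait, kinship and its leading PCs, covariate
#' design, REML polygenic fit, and the environmental residuals.
#'
#' @param gd QC-passed [GenotypeData-class].
#' @param pheno phenotype table with a `trait` column and covariates.
#' @param covariateCols covariate column names to adjust for.
#' @param nPc number of kinship PCs included as fixed effects.
#' @param K optional precomputed kinship.
#' @return list `fit` ([PolygenicFit-class]), `K`, `pcs`,
#'   `pgresidualY` (named by sample).
#' @export
residualizeTrait <- function(gd, pheno,
                             covariateCols = c("sex", "age", "bmi",
                                               "creatinine", "treatment",
                                               "centre"),
                             nPc = 10, K = NULL) {
  ph <- pheno[match(sampleIds(gd), pheno$sample_id), , drop = FALSE]
  if (is.null(K)) K <- genomicKinship(gd)
  eigenK <- eigen(K, symmetric = TRUE)
  nPc <- min(nPc, nSamples(gd) - length(covariateCols) - 2)
  pcs <- eigenK$vectors[, seq_len(nPc), drop = FALSE] %*%
    diag(sqrt(pmax(eigenK$values[seq_len(nPc)], 0)), nPc)
  colnames(pcs) <- paste0("PC", seq_len(nPc))
  covs <- covariateCols[covariateCols %in% names(ph)]
  Xcov <- if (length(covs)) {
    mm <- lapply(covs, function(cc) {
      v <- ph[[cc]]
      if (is.character(v) || is.factor(v) || cc == "centre") {
        f <- factor(v)
        if (nlevels(f) < 2) return(NULL)
        mmx <- model.matrix(~f)[, -1, drop = FALSE]
        colnames(mmx) <- paste0(cc, levels(f)[-1])
        mmx
      } else matrix(v, ncol = 1, dimnames = list(NULL, cc))
    })
    do.call(cbind, mm[!vapply(mm, is.null, TRUE)])
  } else NULL
  X <- cbind(Xcov, pcs)
  yRin <- rankInverseNormal(ph$trait)
  fit <- fitPolygenic(yRin, X, K, eigenK = eigenK)
  res <- setNames(pgResiduals(fit), sampleIds(gd))
  list(fit = fit, K = K, pcs = pcs, pgresidualY = res)
}
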