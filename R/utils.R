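# Small shared helpers.

#' Round half away from zero to a fixed number of decimals
#'
#' Table-style rounding for reported distances (kb) and enrichment folds:
#' 16.951 -> 17.0, 52.539 -> 52.5. Base `round()` rounds half to even, which
#' is not how the reported tables are formatted.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
roundHalfUp <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Format a P-value threshold to two significant figures
#'
#' @param p probability (may be NA).
#' @return character scalar like "3.8e-13".
#' @export
formatThreshold <- function(p) {
  if (is.na(p)) return("NA")
  format(signif(p, 2), scientific = TRUE)
}

# Seed helper: derive a stream of sub-seeds from one master seed so that
# independent stochastic stages don't share a stream. Kept below 2^31.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 69069 + 12345 * k) %% 2147483647)
}

withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}
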