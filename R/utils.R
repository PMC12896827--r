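# internal helpers shared across modules

# evaluate expr under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Round half away from zero
#'
#' Reports in this package round at 3 decimals with halves going up
#' (0.0005 -> 0.001), matching the convention of the diversity tables this
#' package reproduces; base \code{round()} rounds halves to even.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 3) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

# parse "a/b"-style genotype strings into an integer matrix of two allele
# indices per call; missing calls ("./.", ".") become NA rows
parseGT <- function(gt) {
  gt <- sub("\\|", "/", gt)
  a <- sub("/.*", "", gt)
  b <- sub(".*/", "", gt)
  a[a == "."] <- NA; b[b == "."] <- NA
  cbind(suppressWarnings(as.integer(a)), suppressWarnings(as.integer(b)))
}

# per-record genotype bookkeeping for biallelic sites: counts of hom-ref,
# het, hom-alt, missing, and minor allele frequency over typed genotypes
gtSiteStats <- function(gtRow) {
  al <- parseGT(gtRow)
  miss <- is.na(al[, 1]) | is.na(al[, 2])
  typed <- al[!miss, , drop = FALSE]
  n <- nrow(typed)
  if (n == 0)
    return(list(homRef = 0L, het = 0L, homAlt = 0L, nMissing = sum(miss),
                nTyped = 0L, maf = NA_real_, altFreq = NA_real_,
                multi = FALSE))
  multi <- any(typed > 1)
  homRef <- sum(typed[, 1] == 0 & typed[, 2] == 0)
  homAlt <- sum(typed[, 1] == 1 & typed[, 2] == 1)
  het <- sum(typed[, 1] != typed[, 2])
  if (multi) {
    # minor allele frequency = frequency of the second most common allele
    fr <- sort(table(c(typed)) / (2 * n), decreasing = TRUE)
    altFreq <- NA_real_
    maf <- if (length(fr) > 1) unname(fr[2]) else 0
  } else {
    altFreq <- sum(typed) / (2 * n)
    maf <- min(altFreq, 1 - altFreq)
  }
  list(homRef = homRef, het = het, homAlt = homAlt,
       nMissing = sum(miss), nTyped = n, maf = maf, altFreq = altFreq,
       multi = multi)
}
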