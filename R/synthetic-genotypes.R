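#' Simulate a population genotype matrix with known parameters
#'
#' Draws biallelic genotype calls for \code{nIndividuals} at \code{nLoci}
#' loci under an inbreeding-adjusted Hardy-Weinberg law. With major allele
#' frequency p = 1 - maf and inbreeding coefficient f, genotype
#' probabilities are p^2 + f p q (homozygous major), 2 p q (1 - f)
#' (heterozygous) and q^2 + f p q (homozygous minor), clipped at zero and
#' renormalized (negative cells can arise when f < 0). Missing calls are
#' inserted independently at \code{missingRate}. This emulates the kind of
#' genotype table produced by endpoint KASP genotyping of a natural
#' population (the validation cohort this mirrors was 30 individuals).
#'
#' @param nIndividuals number of diploid individuals (default 30).
#' @param maf minor allele frequency in (0, 0.5], scalar or one per locus.
#' @param f inbreeding coefficient in [-1, 1], scalar or per locus.
#' @param missingRate per-call missing probability in [0, 1).
#' @param nLoci number of loci (default length of \code{maf}).
#' @param seed integer seed; identical seeds give identical matrices.
#' @return a \linkS4class{GenotypeMatrix} coded as minor-allele dosage.
#' @examples
#' gm <- simulateGenotypeMatrix(30, maf = 0.3, nLoci = 5, seed = 1)
#' genotypeCalls(gm)[, 1:6]
#' @export
simulateGenotypeMatrix <- function(nIndividuals = 30, maf = 0.3, f = 0,
                                   missingRate = 0, nLoci = length(maf),
                                   seed = 1) {
  if (any(maf <= 0 | maf > 0.5)) stop("maf must be in (0, 0.5]")
  if (any(f < -1 | f > 1)) stop("f must be in [-1, 1]")
  if (missingRate < 0 || missingRate >= 1)
    stop("missingRate must be in [0, 1)")
  maf <- rep_len(maf, nLoci)
  f <- rep_len(f, nLoci)
  withSeed(seed, {
    calls <- t(vapply(seq_len(nLoci), function(i) {
      q <- maf[i]; p <- 1 - q
      pr <- c(p^2 + f[i] * p * q, 2 * p * q * (1 - f[i]),
              q^2 + f[i] * p * q)
      pr <- pmax(pr, 0); pr <- pr / sum(pr)
      g <- sample(0:2, nIndividuals, replace = TRUE, prob = pr)
      if (missingRate > 0)
        g[stats::runif(nIndividuals) < missingRate] <- NA_integer_
      as.integer(g)
    }, integer(nIndividuals)))
    rownames(calls) <- sprintf("Locus%02d", seq_len(nLoci))
    colnames(calls) <- sprintf("S%02d", seq_len(nIndividuals))
    genotypeMatrix(calls)
  })
}

#' Write a genotype matrix as TSV
#'
#' Rows are loci, columns samples; calls are 0/1/2 copies of the minor
#' allele, "." for missing. First column header is "locus".
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeGenotypeTsv <- function(gm, path) {
  m <- gm@calls
  out <- cbind(locus = rownames(m),
               apply(m, 2, function(col) ifelse(is.na(col), ".",
                                                as.character(col))))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from TSV
#'
#' @param path TSV path as written by \code{\link{writeGenotypeTsv}}.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
readGenotypeTsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  m[m == "."] <- NA
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  genotypeMatrix(m)
}

#' Extract the cohort genotype matrix of a VariantSet
#'
#' Converts per-sample "a/b" calls at biallelic sites into minor-allele
#' dosages, determining the minor allele per site from the cohort
#' frequencies.
#'
#' @param vset a biallelic \linkS4class{VariantSet}.
#' @return a \linkS4class{GenotypeMatrix}.
#' @export
cohortGenotypeMatrix <- function(vset) {
  v <- vset@variants
  if (any(grepl(",", v$alt, fixed = TRUE)))
    stop("cohortGenotypeMatrix requires biallelic records")
  calls <- t(apply(vset@geno, 1, function(g) {
    al <- parseGT(g)
    dos <- al[, 1] + al[, 2]
    altFreq <- mean(dos, na.rm = TRUE) / 2
    if (!is.nan(altFreq) && altFreq > 0.5) dos <- 2 - dos
    as.integer(dos)
  }))
  rownames(calls) <- v$id
  colnames(calls) <- colnames(vset@geno)
  genotypeMatrix(calls)
}
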