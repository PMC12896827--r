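#' Allele frequencies at one locus
#'
#' @param calls integer vector of minor-allele dosages (0/1/2, NA missing)
#'   for one biallelic locus.
#' @return list with \code{freqs} (named c(major, minor) frequencies over
#'   non-missing genotypes, summing to 1) and \code{nTyped}.
#' @examples
#' alleleFrequencies(c(rep(0, 13), rep(1, 9), rep(2, 8)))$freqs
#' @export
alleleFrequencies <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (!length(calls)) stop("locus has no non-missing calls")
  q <- sum(calls) / (2 * length(calls))
  list(freqs = c(major = 1 - q, minor = q), nTyped = length(calls))
}

#' Polymorphism information content (Botstein)
#'
#' PIC = 1 - sum(p_i^2) - sum_{i<j} 2 p_i^2 p_j^2 over allele frequencies;
#' for two alleles this is 1 - (p^2 + q^2) - 2 p^2 q^2.
#'
#' @param freqs allele frequency vector (sums to 1, any number of alleles).
#' @return PIC value.
#' @examples
#' picValue(c(0.85, 0.15))   # 0.222 at 3 dp
#' @export
picValue <- function(freqs) {
  if (any(freqs < 0)) stop("allele frequencies must be non-negative")
  s2 <- sum(freqs^2)
  cross <- (s2^2 - sum(freqs^4)) / 2   # sum_{i<j} p_i^2 p_j^2
  1 - s2 - 2 * cross
}

#' Effective number of alleles
#'
#' Ne = 1 / sum(p_i^2).
#'
#' @param freqs allele frequency vector.
#' @return Ne.
#' @export
effectiveAlleles <- function(freqs) 1 / sum(freqs^2)

#' Shannon-Wiener diversity index
#'
#' I = -sum(p_i ln p_i) in natural-log units (the GenAlEx convention);
#' zero frequencies contribute nothing.
#'
#' @param freqs allele frequency vector.
#' @return I in nats.
#' @export
shannonIndex <- function(freqs) {
  freqs <- freqs[freqs > 0]
  -sum(freqs * log(freqs))
}

#' Expected heterozygosity
#'
#' He = 1 - sum(p_i^2), without small-sample correction.
#'
#' @param freqs allele frequency vector.
#' @return He.
#' @export
expectedHet <- function(freqs) 1 - sum(freqs^2)

#' Hardy-Weinberg equilibrium test for a biallelic locus
#'
#' \code{method = "chi2"}: 1-df goodness of fit of observed genotype counts
#' against p^2, 2pq, q^2 expectations (no continuity correction).
#' \code{method = "exact"}: two-sided exact test — the distribution of the
#' heterozygote count conditional on the observed allele counts is
#' enumerated, and the p-value sums the probabilities of all configurations
#' no more probable than the observed one.
#'
#' @param homMajor,het,homMinor genotype counts.
#' @param method "chi2" or "exact".
#' @return p-value; a monomorphic locus returns 1 by convention.
#' @examples
#' hweTest(25, 50, 25)                 # perfect HWE, p = 1
#' hweTest(25, 1, 4, method = "chi2")  # strong heterozygote deficit
#' @export
hweTest <- function(homMajor, het, homMinor, method = c("exact", "chi2")) {
  method <- match.arg(method)
  if (any(c(homMajor, het, homMinor) < 0)) stop("counts must be >= 0")
  n <- homMajor + het + homMinor
  if (n < 1) stop("need at least one genotype")
  nMinor <- 2 * homMinor + het
  if (nMinor == 0 || nMinor == 2 * n) return(1)
  if (method == "chi2") {
    q <- nMinor / (2 * n); p <- 1 - q
    expd <- n * c(p^2, 2 * p * q, q^2)
    x2 <- sum((c(homMajor, het, homMinor) - expd)^2 / expd)
    return(stats::pchisq(x2, df = 1, lower.tail = FALSE))
  }
  hweExactP(homMajor, het, homMinor)
}

# exact conditional distribution of the heterozygote count given allele
# counts; p-value sums probabilities <= that of the observed configuration
hweExactP <- function(homMajor, het, homMinor) {
  n <- homMajor + het + homMinor
  rare <- min(2 * homMinor + het, 2 * homMajor + het)
  hets <- seq(rare %% 2, rare, by = 2)
  logw <- vapply(hets, function(h) {
    hr <- (rare - h) / 2            # rare-allele homozygotes
    hc <- n - h - hr                # common-allele homozygotes
    h * log(2) - lgamma(hr + 1) - lgamma(h + 1) - lgamma(hc + 1)
  }, 0)
  pr <- exp(logw - max(logw))
  pr <- pr / sum(pr)
  pObs <- pr[hets == het]
  sum(pr[pr <= pObs * (1 + 1e-9)])
}

#' Per-locus diversity summary
#'
#' Computes the standard per-locus diversity indices from biallelic calls:
#' Na (observed allele count), Ne = 1/sum(p^2), Shannon index I (nats),
#' observed heterozygosity Ho, expected heterozygosity He = 1 - sum(p^2)
#' (no small-sample correction), inbreeding coefficient
#' F_IS = (He - Ho)/He, MAF (major allele frequency, i.e. the frequency of
#' the most common allele), Botstein PIC, and an HWE p-value.
#'
#' @param calls integer minor-allele dosages (0/1/2, NA missing).
#' @param hweMethod "chi2" (default, matching common survey practice) or
#'   "exact".
#' @return one-row data.frame with columns na, ne, i, ho, he, fis, maf,
#'   pic, hweP, n.
#' @examples
#' locusSummary(c(rep(0, 13), rep(1, 9), rep(2, 8)))
#' @export
locusSummary <- function(calls, hweMethod = c("chi2", "exact")) {
  hweMethod <- match.arg(hweMethod)
  af <- alleleFrequencies(calls)
  fr <- af$freqs
  typed <- calls[!is.na(calls)]
  counts <- c(homMajor = sum(typed == 0), het = sum(typed == 1),
              homMinor = sum(typed == 2))
  ho <- counts[["het"]] / af$nTyped
  he <- expectedHet(fr)
  data.frame(
    na = sum(fr > 0),
    ne = effectiveAlleles(fr),
    i = shannonIndex(fr),
    ho = ho,
    he = he,
    fis = if (he > 0) (he - ho) / he else NA_real_,
    maf = max(fr),
    pic = picValue(fr),
    hweP = hweTest(counts[["homMajor"]], counts[["het"]],
                   counts[["homMinor"]], method = hweMethod),
    n = af$nTyped
  )
}

#' Panel-level diversity report
#'
#' Per-locus summaries for every locus of a genotype matrix plus unweighted
#' column means and ranges, the shape of a published marker-validation
#' table.
#'
#' @param gm a \linkS4class{GenotypeMatrix}.
#' @param hweMethod "chi2" or "exact".
#' @param alpha significance level for the HWE conformity flag ("*" when
#'   p < alpha, "NS" otherwise), default 0.05.
#' @return list with \code{perLocus} (data.frame, one row per locus, plus
#'   locus id and hweFlag columns), \code{means}, \code{mins}, \code{maxs}
#'   (named numeric vectors over the index columns).
#' @export
panelSummary <- function(gm, hweMethod = c("chi2", "exact"), alpha = 0.05) {
  hweMethod <- match.arg(hweMethod)
  m <- gm@calls
  if (!nrow(m)) stop("genotype matrix has no loci")
  rows <- lapply(seq_len(nrow(m)), function(i)
    locusSummary(m[i, ], hweMethod = hweMethod))
  per <- do.call(rbind, rows)
  per <- cbind(locus = rownames(m), per)
  per$hweFlag <- ifelse(per$hweP < alpha, "*", "NS")
  rownames(per) <- NULL
  idx <- c("na", "ne", "i", "ho", "he", "fis", "maf", "pic")
  list(perLocus = per,
       means = vapply(per[idx], mean, 0),
       mins = vapply(per[idx], min, 0),
       maxs = vapply(per[idx], max, 0))
}

#' Write a diversity report as TSV
#'
#' Serializes a \code{\link{panelSummary}} with 3-decimal half-up rounding
#' and a trailing Mean row.
#'
#' @param summary result of \code{\link{panelSummary}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeDiversityReport <- function(summary, path) {
  per <- summary$perLocus
  idx <- c("ne", "i", "ho", "he", "fis", "maf", "pic", "hweP")
  for (col in idx) per[[col]] <- roundHalfUp(per[[col]], 3)
  meanRow <- per[1, ]
  meanRow$locus <- "Mean"
  meanRow$na <- roundHalfUp(summary$means[["na"]], 3)
  for (col in c("ne", "i", "ho", "he", "fis", "maf", "pic"))
    meanRow[[col]] <- roundHalfUp(summary$means[[col]], 3)
  meanRow$hweP <- NA; meanRow$n <- NA; meanRow$hweFlag <- ""
  utils::write.table(rbind(per, meanRow), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Reconstruct genotype counts from a published summary row
#'
#' Given a printed observed heterozygosity, major allele frequency and
#' sample size, recovers the integer genotype counts they came from:
#' het = round(Ho * n), minor allele count = round((1 - MAF) * 2n),
#' hom-minor = (minor - het)/2 rounded to the nearest integer, and
#' hom-major as the remainder. Errors when no non-negative integer
#' configuration is consistent with the inputs.
#'
#' @param ho observed heterozygosity in [0, 1].
#' @param maf major allele frequency in [0.5, 1].
#' @param n individuals typed.
#' @return named integer vector (homMajor, het, homMinor).
#' @examples
#' countsFromSummary(0.033, 0.850, 30)   # c(25, 1, 4)
#' @export
countsFromSummary <- function(ho, maf, n) {
  if (ho < 0 || ho > 1) stop("ho must be in [0, 1]")
  if (maf < 0.5 || maf > 1) stop("maf (major allele frequency) must be in [0.5, 1]")
  het <- round(ho * n)
  minorCount <- round((1 - maf) * 2 * n)
  homMinor <- round((minorCount - het) / 2)
  if (homMinor < 0)
    stop("irreconcilable summary: heterozygotes (", het,
         ") exceed the minor allele count (", minorCount, ")")
  homMajor <- n - het - homMinor
  if (homMajor < 0)
    stop("irreconcilable summary: het + hom-minor exceed n = ", n)
  c(homMajor = as.integer(homMajor), het = as.integer(het),
    homMinor = as.integer(homMinor))
}
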