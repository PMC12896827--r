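#' Published diversity survey of the 19-marker KASP panel
#'
#' The per-locus diversity table reported for the validated 19-SNP KASP
#' panel genotyped in 30 Yangtze finless porpoises from the Poyang Lake
#' natural population: locus identifiers, genomic position (from the
#' chromosome-level assembly), the two alleles, and the printed indices
#' Na, Ne, I, Ho, He, F_IS, MAF (major allele frequency), PIC and the HWE
#' conformity flag at alpha = 0.05. The \code{n} column is the per-locus
#' number of individuals successfully typed, recovered from the printed Ho
#' values (Ho times n must be an integer heterozygote count): 29 at five
#' loci, 30 elsewhere.
#'
#' Each printed index is a deterministic function of the locus's allele
#' frequencies, so this table doubles as a reference fixture: recomputing
#' Ne, I, He and PIC from the MAF column reproduces the printed values at
#' 3 decimals (one locus, Snp35, prints a MAF inconsistent with any integer
#' allele count at its sample size; its printed value is kept as-is).
#'
#' @return data.frame with columns locus, chrom, pos, ref, alt, na, ne, i,
#'   ho, he, fis, maf, pic, hweFlag, n.
#' @examples
#' tab <- poyangPanel()
#' round(1 / (tab$maf^2 + (1 - tab$maf)^2), 3)  # reproduces tab$ne
#' @export
poyangPanel <- function() {
  tab <- read.table(header = TRUE, stringsAsFactors = FALSE, text = "
locus chrom pos ref alt na ne i ho he fis maf pic hweFlag n
Snp03 Chr02 3578746 C T 2 1.946 0.679 0.300 0.486 0.383 0.583 0.368 NS 30
Snp04 Chr02 90116171 A G 2 1.835 0.647 0.367 0.455 0.194 0.650 0.351 NS 30
Snp08 Chr04 6297226 A G 2 1.923 0.673 0.267 0.480 0.444 0.600 0.365 NS 30
Snp09 Chr04 71791661 T C 2 1.897 0.666 0.567 0.473 -0.199 0.617 0.361 NS 30
Snp12 Chr04 84395785 A G 2 1.684 0.596 0.300 0.406 0.261 0.717 0.324 NS 30
Snp14 Chr04 106682173 G A 2 1.991 0.691 0.586 0.498 -0.178 0.534 0.374 NS 29
Snp19 Chr07 50780006 G C 2 1.998 0.693 0.433 0.499 0.132 0.517 0.375 NS 30
Snp20 Chr07 85509514 C A 2 1.708 0.605 0.586 0.414 -0.415 0.707 0.329 NS 29
Snp25 Chr11 27764344 G A 2 1.980 0.688 0.367 0.495 0.259 0.550 0.372 NS 30
Snp29 Chr13 83891862 T C 2 1.684 0.596 0.233 0.406 0.425 0.717 0.324 NS 30
Snp30 Chr14 13332465 A G 2 1.471 0.500 0.333 0.320 -0.042 0.800 0.269 NS 30
Snp31 Chr15 1462494 T G 2 1.867 0.657 0.467 0.464 -0.005 0.633 0.357 NS 30
Snp32 Chr16 55868804 G A 2 1.557 0.543 0.333 0.358 0.068 0.767 0.294 NS 30
Snp34 Chr17 23473466 A C 2 1.859 0.655 0.448 0.462 0.030 0.638 0.355 NS 29
Snp35 Chr17 66317367 T G 2 1.989 0.690 0.333 0.497 0.330 0.537 0.374 NS 30
Snp36 Chr18 33806104 G A 2 1.918 0.672 0.448 0.479 0.063 0.603 0.364 NS 29
Snp46 ChrX 31038355 T C 2 1.342 0.423 0.033 0.255 0.869 0.850 0.222 * 30
Snp47 ChrX 33057094 C T 2 1.622 0.572 0.103 0.383 0.730 0.741 0.310 * 29
Snp48 ChrX 37770280 G T 2 1.763 0.624 0.167 0.433 0.615 0.683 0.339 * 30
")
  tab
}

#' Reconstruct the published panel's genotype matrix
#'
#' Builds a genotype matrix whose per-locus counts are recovered from the
#' published Ho/MAF/n values via \code{\link{countsFromSummary}} — a
#' deterministic stand-in for the raw KASP calls, sufficient to recompute
#' every per-locus index.
#'
#' @return a \linkS4class{GenotypeMatrix} with 19 loci; columns are padded
#'   with NA where a locus was typed in fewer individuals.
#' @export
poyangGenotypeMatrix <- function() {
  tab <- poyangPanel()
  nMax <- max(tab$n)
  calls <- t(vapply(seq_len(nrow(tab)), function(i) {
    ct <- countsFromSummary(tab$ho[i], tab$maf[i], tab$n[i])
    g <- rep(c(0L, 1L, 2L), ct)
    c(g, rep(NA_integer_, nMax - tab$n[i]))
  }, integer(nMax)))
  rownames(calls) <- tab$locus
  colnames(calls) <- sprintf("PY%02d", seq_len(nMax))
  genotypeMatrix(calls)
}
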