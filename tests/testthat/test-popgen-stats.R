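test_that("allele frequencies come from non-missing genotypes only", {
  fr <- alleleFrequencies(callsFromCounts(13, 9, 8))
  expect_equal(unname(fr$freqs["major"]), 35 / 60)
  expect_identical(fr$nTyped, 30L)

  expect_identical(unname(alleleFrequencies(rep(0L, 10))$freqs),
                   c(1, 0))

  withMissing <- c(callsFromCounts(4, 4, 2), NA, NA)
  frM <- alleleFrequencies(withMissing)
  expect_identical(frM$nTyped, 10L)
  expect_equal(unname(frM$freqs["minor"]), (4 + 2 * 2) / 20)

  expect_error(alleleFrequencies(c(NA_integer_, NA_integer_)),
               "no non-missing")
})

test_that("Botstein PIC matches published and hand-computed values", {
  expect_equal(roundHalfUp(picValue(c(0.850, 0.150)), 3), 0.222)
  expect_identical(picValue(1), 0)
  # four equifrequent alleles, full double-sum: 1 - 0.25 - 12 * 0.0625^2
  expect_equal(picValue(rep(0.25, 4)), 0.703125)
  expect_error(picValue(c(1.2, -0.2)), "non-negative")
})

test_that("chi-square HWE test matches hand computation; exact test matches full enumeration", {
  expect_equal(hweTest(25, 50, 25, method = "chi2"), 1)

  # counts (25, 1, 4): chi2 ~ 22.7
  p <- hweTest(25, 1, 4, method = "chi2")
  expect_lt(p, 1e-4)
  expect_equal(stats::qchisq(p, 1, lower.tail = FALSE), 22.7,
               tolerance = 0.01)

  expect_identical(hweTest(10, 0, 0), 1)  # monomorphic convention

  # exact test equals the multinomial-conditioning oracle for every
  # genotype configuration with n <= 10
  for (n in c(3, 6, 10)) {
    for (a in 0:n) for (h in 0:(n - a)) {
      b <- n - a - h
      if (2 * a + h == 0 || 2 * b + h == 0) next
      expect_equal(hweTest(a, h, b, method = "exact"),
                   hweEnumOracle(a, h, b),
                   tolerance = 1e-10,
                   label = sprintf("exact HWE at (%d,%d,%d)", a, h, b))
    }
  }
})

test_that("locus summaries reproduce a published survey row and the degenerate extremes", {
  s <- locusSummary(callsFromCounts(13, 9, 8))
  expect_identical(s$na, 2L)
  expect_equal(roundHalfUp(s$ne, 3), 1.946)
  expect_equal(roundHalfUp(s$i, 3), 0.679)
  expect_equal(roundHalfUp(s$ho, 3), 0.300)
  expect_equal(roundHalfUp(s$he, 3), 0.486)
  expect_equal(roundHalfUp(s$fis, 3), 0.383)
  expect_equal(roundHalfUp(s$maf, 3), 0.583)
  expect_equal(roundHalfUp(s$pic, 3), 0.368)
  expect_identical(s$n, 30L)

  allHet <- locusSummary(rep(1L, 10))
  expect_equal(allHet$ho, 1)
  expect_equal(allHet$he, 0.5)
  expect_equal(allHet$fis, -1)
})

test_that("every summary field matches a brute-force recomputation on random matrices", {
  set.seed(31)
  gm <- simulateGenotypeMatrix(40, maf = runif(12, 0.1, 0.5),
                               f = runif(12, -0.3, 0.5),
                               missingRate = 0.05, nLoci = 12, seed = 77)
  per <- panelSummary(gm)$perLocus
  for (i in seq_len(nrow(per))) {
    calls <- genotypeCalls(gm)[i, ]
    calls <- calls[!is.na(calls)]
    n <- length(calls)
    q <- sum(calls) / (2 * n); p <- 1 - q
    maj <- max(p, q)
    expect_equal(per$ne[i], 1 / (p^2 + q^2))
    iOra <- -sum(c(p, q)[c(p, q) > 0] * log(c(p, q)[c(p, q) > 0]))
    expect_equal(per$i[i], iOra)
    expect_equal(per$ho[i], mean(calls == 1))
    expect_equal(per$he[i], 2 * p * q)
    expect_equal(per$maf[i], maj)
    expect_equal(per$pic[i], 1 - (p^2 + q^2) - 2 * p^2 * q^2)
    # invariants for biallelic loci
    expect_lte(per$pic[i], per$he[i])
    expect_lte(per$he[i], 0.5)
    expect_equal(per$ne[i], 1 / (1 - per$he[i]))
  }
})

test_that("panel summaries average per-locus indices and a single locus is its own mean", {
  one <- genotypeMatrix(matrix(callsFromCounts(13, 9, 8), nrow = 1))
  ps <- panelSummary(one)
  expect_equal(unname(ps$means["ne"]), ps$perLocus$ne[1])

  gm <- simulateGenotypeMatrix(30, maf = c(0.2, 0.35, 0.5), nLoci = 3,
                               seed = 21)
  ps3 <- panelSummary(gm)
  expect_equal(unname(ps3$means["pic"]), mean(ps3$perLocus$pic))
  expect_equal(unname(ps3$mins["he"]), min(ps3$perLocus$he))
  expect_equal(unname(ps3$maxs["ho"]), max(ps3$perLocus$ho))
})

test_that("genotype counts are reconstructed from published summary rows", {
  expect_identical(unname(countsFromSummary(0.033, 0.850, 30)),
                   c(25L, 1L, 4L))
  expect_identical(unname(countsFromSummary(0.103, 0.741, 29)),
                   c(20L, 3L, 6L))
  expect_identical(unname(countsFromSummary(0, 1, 30)), c(30L, 0L, 0L))
  expect_error(countsFromSummary(0.9, 0.95, 30), "irreconcilable")
  expect_error(countsFromSummary(0.5, 0.3, 30), "major allele")
})

test_that("summary -> counts -> summary round trips at 3 decimals", {
  tab <- poyangPanel()
  consistent <- tab$locus != "Snp35"  # printed MAF inconsistent with n
  for (i in which(consistent)) {
    ct <- countsFromSummary(tab$ho[i], tab$maf[i], tab$n[i])
    s <- locusSummary(callsFromCounts(ct[1], ct[2], ct[3]))
    expect_equal(roundHalfUp(s$ho, 3), tab$ho[i], label = tab$locus[i])
    expect_equal(roundHalfUp(s$maf, 3), tab$maf[i], label = tab$locus[i])
  }
})

test_that("diversity reports serialize with 3-dp half-up rounding, a means row and HWE flags", {
  gm <- poyangGenotypeMatrix()
  p <- tempfile(fileext = ".tsv")
  writeDiversityReport(panelSummary(gm, hweMethod = "chi2"), p)
  rpt <- read.table(p, sep = "\t", header = TRUE)
  expect_identical(nrow(rpt), 20L)     # 19 loci + mean row
  expect_identical(rpt$locus[20], "Mean")
  expect_identical(rpt$hweFlag[rpt$locus == "Snp46"], "*")
  expect_equal(rpt$ne[rpt$locus == "Snp03"], 1.946)
})
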