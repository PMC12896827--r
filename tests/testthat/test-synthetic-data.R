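test_that("simulated references have requested shape, composition and determinism", {
  ref <- simulateReference(c(ChrA = 10000, ChrB = 10000), gc = 0.41,
                           seed = 1)
  expect_identical(unname(Biostrings::width(ref)), c(10000L, 10000L))
  expect_identical(names(ref), c("ChrA", "ChrB"))

  ref2 <- simulateReference(c(ChrA = 10000, ChrB = 10000), gc = 0.41,
                            seed = 1)
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  writeReferenceFasta(ref, f1); writeReferenceFasta(ref2, f2)
  expect_identical(readLines(f1), readLines(f2))

  # GC content: binomial 3-SD tolerance at L = 1e6 is ~0.0015; the spec of
  # the generator promises [gc - 0.01, gc + 0.01]
  big <- simulateReference(c(Chr = 1e6), gc = 0.40, seed = 2)
  comp <- Biostrings::alphabetFrequency(big)[1, c("C", "G")]
  expect_true(abs(sum(comp) / 1e6 - 0.40) < 0.01)

  expect_error(simulateReference(c(Chr = -5), seed = 1), "positive")
})

test_that("simulated cohorts have Poisson-scale record counts, full genotype rows and clean annotations", {
  ref <- simulateReference(c(Chr01 = 1e6), seed = 1)
  vs <- simulateCohortVcf(ref, nSamples = 12, snpDensity = 1 / 2000,
                          seed = 7)
  # E = 500, 3 SD of Binomial(1e6, 1/2000) ~ 67
  expect_true(abs(nVariants(vs) - 500) <= 3 * sqrt(500))
  expect_identical(ncol(genotypes(vs)), 12L)
  expect_true(all(genotypes(vs) %in% c("0/0", "0/1", "1/1")))

  # positions strictly increasing per chromosome
  v <- variantTable(vs)
  expect_true(all(diff(v$pos[v$chrom == "Chr01"]) > 0))
  # ref allele matches the reference sequence
  expect_identical(v$ref[1:20],
                   substring(as.character(ref[["Chr01"]]),
                             v$pos[1:20], v$pos[1:20]))

  # default annotation laws sit inside the stage-1 pass region
  hf <- evaluateHardFilter(vs, screenConfig(), stage = "initial")
  expect_true(all(hf$pass))
  expect_true(all(hardFilterOracle(v)))

  expect_error(simulateCohortVcf(ref, nSamples = 1, seed = 1), ">= 2")
  expect_error(
    simulateCohortVcf(simulateReference(c(C = 5000), seed = 1),
                      snpDensity = 0.5, seed = 1),
    "density")
})

test_that("cohort VCF writing is deterministic and round trips through a standard parser", {
  ref <- simulateReference(c(Chr01 = 2e5, Chr02 = 1e5), seed = 3)
  vs <- simulateCohortVcf(ref, seed = 9)
  p1 <- tempfile(fileext = ".vcf"); p2 <- tempfile(fileext = ".vcf")
  writeCohortVcf(vs, p1, ref)
  writeCohortVcf(simulateCohortVcf(ref, seed = 9), p2, ref)
  expect_identical(readLines(p1), readLines(p2))

  back <- readCohortVcf(p1)
  expect_equal(variantTable(back), variantTable(vs))
  expect_identical(unname(genotypes(back)), unname(genotypes(vs)))
})

test_that("planted violations are recovered exactly by screening, and an empty spec is the identity", {
  ref <- simulateReference(c(Chr01 = 4e5, Chr02 = 3e5), seed = 1)
  vs <- simulateCohortVcf(ref, seed = 7)

  none <- plantViolations(vs, list(), seed = 5)
  expect_identical(variantTable(none$variants), variantTable(vs))
  expect_identical(nrow(none$truth), 0L)

  pl <- plantViolations(vs, list(qd = 10), seed = 5)
  out <- screenCandidates(pl$variants)
  rejectedQD <- out$removed$id[out$removed$reasons == "QD"]
  expect_setequal(rejectedQD, pl$truth$id)
  expect_identical(length(rejectedQD), 10L)

  prox <- plantViolations(vs, list(proximity = 5), seed = 5)
  outP <- screenCandidates(prox$variants)
  isoRemoved <- outP$removed$id[outP$removed$reasons == "proximity"]
  expect_identical(length(isoRemoved), 10L)  # 5 pairs
  expect_setequal(isoRemoved, prox$truth$id)

  expect_error(plantViolations(vs, list(qd = nVariants(vs) + 1), seed = 1),
               "available")
})

test_that("planted-violation recall and precision are 1.0 across all criteria", {
  ref <- simulateReference(c(Chr01 = 4e5, Chr02 = 3e5), seed = 1)
  vs <- simulateCohortVcf(ref, seed = 7)
  spec <- list(qd = 3, qual = 3, fs = 3, mq = 3, mqRankSum = 3,
               readPosRankSum = 3, multiallelic = 3, proximity = 2,
               lowMaf = 3, missing = 3, hwe = 3, picOut = 3)
  pl <- plantViolations(vs, spec, seed = 11)
  out <- screenCandidates(pl$variants)

  # recall: every planted id was removed; precision: nothing else was
  expect_setequal(out$removed$id, pl$truth$id)
  expect_setequal(out$candidates$locus_id,
                  setdiff(variantTable(pl$variants)$id, pl$truth$id))

  # each planted record is removed at the stage its criterion targets
  stageOf <- c(qd = "hard_filter", qual = "hard_filter",
               fs = "hard_filter", mq = "hard_filter",
               mqRankSum = "hard_filter", readPosRankSum = "hard_filter",
               multiallelic = "biallelic_isolation",
               proximity = "biallelic_isolation",
               lowMaf = "popgen_prefilter", missing = "popgen_prefilter",
               hwe = "popgen_prefilter", picOut = "pic_band")
  m <- merge(pl$truth, out$removed, by = "id")
  expect_identical(unname(stageOf[m$criterion]), m$stage)
})

test_that("genotype matrices recover their simulation parameters and honour missingness", {
  gm0 <- simulateGenotypeMatrix(10000, maf = 0.3, f = 0, nLoci = 1,
                                seed = 4)
  s0 <- locusSummary(genotypeCalls(gm0)[1, ])
  expect_lt(abs((1 - s0$maf) - 0.3), 3 * sqrt(0.3 * 0.7 / 20000))
  # SE of F_IS approx sqrt(Ho(1-Ho)/n)/He at Ho = 2pq = 0.42
  expect_lt(abs(s0$fis - 0), 3 * sqrt(0.42 * 0.58 / 10000) / 0.42)

  gm5 <- simulateGenotypeMatrix(10000, maf = 0.3, f = 0.5, nLoci = 1,
                                seed = 4)
  s5 <- locusSummary(genotypeCalls(gm5)[1, ])
  expect_lt(abs(s5$fis - 0.5), 3 * sqrt(0.21 * 0.79 / 10000) / 0.42)

  expect_false(anyNA(genotypeCalls(
    simulateGenotypeMatrix(50, maf = 0.2, nLoci = 10, seed = 1))))
  gmM <- simulateGenotypeMatrix(200, maf = 0.2, missingRate = 0.2,
                                nLoci = 50, seed = 2)
  expect_lt(abs(mean(is.na(genotypeCalls(gmM))) - 0.2), 0.03)

  expect_error(simulateGenotypeMatrix(10, maf = 0.6, seed = 1), "maf")
  expect_error(simulateGenotypeMatrix(10, maf = 0.2, f = 2, seed = 1),
               "f must")
})

test_that("genotype TSV round trips and simulation is seed-deterministic", {
  gm <- simulateGenotypeMatrix(25, maf = c(0.1, 0.3, 0.5),
                               missingRate = 0.1, nLoci = 3, seed = 8)
  p <- tempfile(fileext = ".tsv")
  writeGenotypeTsv(gm, p)
  back <- readGenotypeTsv(p)
  expect_identical(genotypeCalls(back), genotypeCalls(gm))

  gm2 <- simulateGenotypeMatrix(25, maf = c(0.1, 0.3, 0.5),
                                missingRate = 0.1, nLoci = 3, seed = 8)
  expect_identical(genotypeCalls(gm), genotypeCalls(gm2))
})
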