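test_that("hard-filter boundaries are inclusive and failures are named", {
  cfg <- screenConfig()
  atBoundary <- cleanVariantSet(qual = 30.0, qd = 2.0, fs = 60.0, mq = 40.0,
                                mqRankSum = -12.5, readPosRankSum = -8.0)
  res <- evaluateHardFilter(atBoundary, cfg)
  expect_true(res$pass)
  expect_identical(res$reasons, "")

  justUnder <- cleanVariantSet(qd = 1.99)
  res2 <- evaluateHardFilter(justUnder, cfg)
  expect_false(res2$pass)
  expect_identical(res2$reasons, "QD")

  multi <- cleanVariantSet(n = 3, qd = c(1.0, 25, 25),
                           fs = c(1, 80, 1), mq = c(59, 59, 30))
  res3 <- evaluateHardFilter(multi, cfg)
  expect_identical(res3$reasons, c("QD", "FS", "MQ"))
})

test_that("absent annotations skip their criterion and are flagged", {
  v <- cleanVariantSet(mqRankSum = NA_real_, readPosRankSum = NA_real_)
  res <- evaluateHardFilter(v, screenConfig())
  expect_true(res$pass)
  expect_identical(res$missingAnnotations, "MQRankSum,ReadPosRankSum")
})

test_that("high-confidence tagging requires QUAL >= 1000 and never deletes records", {
  below <- cleanVariantSet(qual = 999.9)
  atLine <- cleanVariantSet(qual = 1000.0)
  expect_false(hasTag(tagHighConfidence(below)))
  expect_true(hasTag(tagHighConfidence(atLine)))
  expect_identical(nVariants(tagHighConfidence(below)), 1L)

  # tag count equals a brute-force count on a synthetic cohort
  ref <- simulateReference(c(Chr01 = 3e5), seed = 2)
  vs <- simulateCohortVcf(
    ref, seed = 3,
    annotationLaws = list(qual = function(n) runif(n, 500, 1500)))
  tagged <- tagHighConfidence(vs)
  expect_identical(sum(hasTag(tagged)),
                   sum(hardFilterOracle(variantTable(vs), qualMin = 1000)))
})

test_that("isolation boundary: distance 100 excludes, 101 retains; non-SNPs count as neighbours", {
  pair100 <- cleanVariantSet(n = 2, pos = c(1000, 1100))
  expect_identical(nVariants(selectIsolatedBiallelic(pair100)), 0L)
  pair101 <- cleanVariantSet(n = 2, pos = c(1000, 1101))
  expect_identical(nVariants(selectIsolatedBiallelic(pair101)), 2L)

  lone <- cleanVariantSet(pos = 5000)
  expect_identical(nVariants(selectIsolatedBiallelic(lone)), 1L)

  # an indel neighbour removes the SNP but is itself never selected
  withIndel <- cleanVariantSet(n = 2, pos = c(1000, 1050),
                               ref = c("A", "ATT"), alt = c("G", "A"))
  expect_identical(nVariants(selectIsolatedBiallelic(withIndel)), 0L)
})

test_that("isolation matches an all-pairs brute-force oracle on random instances", {
  set.seed(42)
  for (rep in 1:3) {
    n <- 300
    df <- data.frame(chrom = sample(c("C1", "C2"), n, TRUE),
                     pos = sample(1:30000, n))
    df <- df[!duplicated(df[c("chrom", "pos")]), ]
    vs <- cleanVariantSet(n = nrow(df), chrom = df$chrom, pos = df$pos)
    kept <- selectIsolatedBiallelic(vs, window = 100)
    ora <- variantTable(vs)$id[isolationOracle(variantTable(vs), 100)]
    expect_setequal(variantTable(kept)$id, ora)
  }
})

test_that("popgen prefilter applies MAF, missingness and HWE thresholds", {
  # any missing genotype is fatal at maxMissing = 0
  gMiss <- matrix(c("./.", rep("0/1", 11)), 1)
  expect_identical(nVariants(popgenPrefilter(cleanVariantSet(geno = gMiss))),
                   0L)

  # 12 diploids: minor allele count 1 (MAF 0.042) out, count 2 (0.083) in
  g1 <- matrix(c("0/1", rep("0/0", 11)), 1)
  g2 <- matrix(c("0/1", "0/1", rep("0/0", 10)), 1)
  expect_identical(nVariants(popgenPrefilter(cleanVariantSet(geno = g1))),
                   0L)
  expect_identical(nVariants(popgenPrefilter(cleanVariantSet(geno = g2))),
                   1L)

  # exact-test removal: counts (25, 1, 4) at n = 30 has p < 0.001
  g3 <- matrix(rep(c("0/0", "0/1", "1/1"), c(25, 1, 4)), 1)
  expect_lt(hweTest(25, 1, 4, method = "exact"), 0.001)
  expect_identical(
    nVariants(popgenPrefilter(cleanVariantSet(nSamples = 30, geno = g3))),
    0L)

  # an all-missing locus is removed rather than erroring
  gAll <- matrix(rep("./.", 12), 1)
  res <- popgenPrefilter(cleanVariantSet(geno = gAll), details = TRUE)
  expect_identical(res$decisions$reasons, "allMissing")
})

test_that("PIC band keeps [0.2, 0.5] inclusive and drops weakly informative sites", {
  cand <- data.frame(pic = c(picValue(c(0.5, 0.5)),        # 0.375
                             picValue(c(1, 0)),            # 0 (monomorphic)
                             picValue(c(0.917, 0.083)),    # ~0.141
                             0.2, 0.5))
  kept <- picBandFilter(cand, 0.2, 0.5)
  expect_identical(kept$pic, c(0.375, 0.2, 0.5))
  expect_equal(roundHalfUp(picValue(c(0.917, 0.083)), 3), 0.141)
})

test_that("screening a clean cohort is vacuous and screening is idempotent", {
  ref <- simulateReference(c(Chr01 = 4e5, Chr02 = 3e5), seed = 1)
  vs <- simulateCohortVcf(ref, seed = 7)
  out <- screenCandidates(vs)
  expect_identical(unname(out$counts[["pic_band"]]),
                   unname(out$counts[["input"]]))

  surv <- vs[variantTable(vs)$id %in% out$candidates$locus_id]
  again <- screenCandidates(surv)
  expect_identical(again$candidates$locus_id, out$candidates$locus_id)
})

test_that("screening output is sorted and independent of input record order", {
  ref <- simulateReference(c(Chr01 = 4e5, Chr02 = 3e5), seed = 1)
  vs <- simulateCohortVcf(ref, seed = 7)
  pl <- plantViolations(vs, list(qd = 5, proximity = 3, hwe = 2),
                        seed = 13)$variants
  out1 <- screenCandidates(pl)
  shuffled <- pl[sample(nVariants(pl))]
  out2 <- screenCandidates(shuffled)
  expect_identical(out1$candidates, out2$candidates)
  v <- out1$candidates
  expect_identical(order(v$chrom, v$pos), seq_len(nrow(v)))
})

test_that("relaxing a single threshold never shrinks the surviving set", {
  ref <- simulateReference(c(Chr01 = 4e5), seed = 5)
  vs <- simulateCohortVcf(
    ref, seed = 6, guaranteePass = FALSE,
    mafLaw = function(n) runif(n, 0.05, 0.5),
    annotationLaws = list(qd = function(n) runif(n, 0, 10),
                          qual = function(n) runif(n, 500, 1500)))
  base <- screenCandidates(vs)$candidates$locus_id
  relaxed <- list(screenConfig(qdMin = 1.0),
                  screenConfig(qualHighConf = 500),
                  screenConfig(picMin = 0.1),
                  screenConfig(mafMin = 0.01),
                  screenConfig(isolationWindow = 50))
  for (cfg in relaxed) {
    ids <- screenCandidates(vs, cfg)$candidates$locus_id
    expect_true(all(base %in% ids))
  }
})
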