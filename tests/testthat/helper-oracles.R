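# Independent brute-force oracles used across the suite.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Exact HWE oracle by multinomial conditioning: enumerate every genotype
# configuration of n individuals, weight by the HWE multinomial law (any
# allele frequency gives the same conditional law; 0.5 is used), condition
# on the observed allele count, and sum the probabilities of configurations
# no more probable than the observed one.
hweEnumOracle <- function(homMajor, het, homMinor) {
  n <- homMajor + het + homMinor
  cfgs <- expand.grid(a = 0:n, h = 0:n)
  cfgs$b <- n - cfgs$a - cfgs$h
  cfgs <- cfgs[cfgs$b >= 0, ]
  pr <- apply(cfgs, 1, function(r)
    stats::dmultinom(c(r["a"], r["h"], r["b"]),
                     prob = c(0.25, 0.5, 0.25)))
  minor <- 2 * cfgs$b + cfgs$h
  obsMinor <- 2 * homMinor + het
  sel <- minor == obsMinor
  pr <- pr[sel] / sum(pr[sel])
  cfg <- cfgs[sel, ]
  pObs <- pr[cfg$a == homMajor & cfg$h == het]
  sum(pr[pr <= pObs * (1 + 1e-9)])
}

# O(n^2) all-pairs isolation oracle: a record is isolated iff no other
# record on the same chromosome lies at distance <= window.
isolationOracle <- function(df, window = 100) {
  vapply(seq_len(nrow(df)), function(i) {
    d <- abs(df$pos - df$pos[i])
    !any(df$chrom == df$chrom[i] & d <= window & seq_len(nrow(df)) != i)
  }, TRUE)
}

# record-by-record hard-filter oracle, written directly from the filter
# expression with inclusive boundaries and skip-if-absent semantics
hardFilterOracle <- function(v, qualMin = 30) {
  ok <- function(x, cmp) is.na(x) | cmp(x)
  vapply(seq_len(nrow(v)), function(i) {
    ok(v$qd[i], function(x) x >= 2.0) &&
      v$qual[i] >= qualMin &&
      ok(v$fs[i], function(x) x <= 60.0) &&
      ok(v$mq[i], function(x) x >= 40.0) &&
      ok(v$mqRankSum[i], function(x) x >= -12.5) &&
      ok(v$readPosRankSum[i], function(x) x >= -8.0)
  }, TRUE)
}

# build a minimal one-or-more-record VariantSet with clean annotations;
# overrides are applied to the variants table
cleanVariantSet <- function(n = 1, nSamples = 12, chrom = "Chr01",
                            pos = seq(1000, by = 500, length.out = n),
                            geno = NULL, ...) {
  v <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                  qual = 2000, qd = 25, fs = 1, mq = 59, mqRankSum = 0,
                  readPosRankSum = 0, stringsAsFactors = FALSE)
  over <- list(...)
  for (nm in names(over)) v[[nm]] <- over[[nm]]
  if (is.null(geno))
    geno <- matrix(rep(rep(c("0/0", "0/1", "1/1"),
                           length.out = nSamples), n),
                   nrow = n, byrow = TRUE)
  VariantSet(v, geno)
}

# genotype calls (minor-allele dosage) from genotype class counts
callsFromCounts <- function(homMajor, het, homMinor)
  rep(c(0L, 1L, 2L), c(homMajor, het, homMinor))
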