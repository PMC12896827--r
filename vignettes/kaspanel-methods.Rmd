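---
title: "Methods: SNP screening, KASP design and diversity statistics in kaspanel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP screening, KASP design and diversity statistics in kaspanel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kaspanel)
```

# Scope and model

`kaspanel` turns a joint-genotyped cohort VCF plus a reference genome into
(i) a table of candidate SNPs that survive a fixed cascade of quality and
population-genetic filters, (ii) an evenly distributed subsample of those
candidates, (iii) KASP primer sets for the subsample, and (iv) per-locus
diversity statistics for a genotyped validation cohort. Everything upstream
of the VCF — read alignment, duplicate handling, haplotype-based calling —
is out of scope; the synthetic-data module emulates the *product* of those
steps instead.

# The screening cascade

`screenCandidates()` applies six stages in a fixed order, reporting the
record count after each:

1. **Hard filter.** Inclusive inequalities on site annotations:
   QD ≥ 2.0, QUAL ≥ 30.0, FS ≤ 60.0, MQ ≥ 40.0, MQRankSum ≥ −12.5,
   ReadPosRankSum ≥ −8.0. Boundary values pass. An *absent* annotation
   skips its criterion and is flagged rather than failed: rank-sum
   annotations are undefined at sites where only one allele is observed in
   reads, and a site should not be discarded for lack of a number. This
   mirrors how hard filtering behaves in practice in GATK-style pipelines.
2. **Biallelic + isolation.** Only single-base, single-alternate SNPs with
   no other variant record *of any type* at distance ≤ 100 bp on the same
   chromosome survive. "Within 100 bp" is read inclusively: a pair at
   distance exactly 100 is removed, at 101 retained. Isolation protects
   the ~20-bp primer-binding context and the 301-bp design window.
3. **High-confidence tag.** The same filter with QUAL ≥ 1000 sets the
   `FIRSTOK` tag; tagged records are *required* for candidacy (the tag
   stage exists to retain only high-quality loci, so an untagged record is
   dropped rather than merely annotated).
4. **Population-genetic prefilter** (VCFtools flag semantics): minor allele
   frequency ≥ 0.05 over non-missing genotypes, missing fraction ≤ 0
   (every cohort sample typed), and HWE p ≥ 0.001. The HWE default is the
   two-sided **exact** test — the conditional distribution of the
   heterozygote count given the allele counts is enumerated and all
   configurations no more probable than the observed one are summed — which
   is what the VCFtools `--hwe` filter computes; a chi-square alternative
   is provided. A locus with zero typed genotypes is removed and logged.
5. **Isolation re-check** among survivors, the same reusable operation as
   stage 2 (the original procedure applies the isolation rule both before
   and after the population filters).
6. **PIC band.** Cohort PIC, from allele frequencies over non-missing
   genotypes, must lie in [0.2, 0.5] inclusive. For a biallelic locus
   PIC = 1 − (p² + q²) − 2p²q², which is ≤ 0.375, so the upper bound only
   binds for multi-allelic inputs (already excluded) and acts as a guard.

Each removed record is attributed to the *first* stage that rejects it.
One consequence worth stating: a site with minor allele frequency below
0.05 necessarily has PIC below 0.2 as well (PIC is monotone in the minor
frequency below 0.5); such a site is reported as a frequency-filter
removal, because that is the stage that acts first.

The cascade is monotone in each threshold on spatially well-separated
inputs; note that relaxing an upstream filter can in principle re-introduce
a neighbour that crowds out a previously isolated SNP, so monotonicity of
the final set is a property of the data layout, not of the algorithm.

# Panel subsampling

"Evenly distributed across chromosomes" is not a precise algorithm, so the
package makes one: per-chromosome quotas by largest-remainder rounding of
chromosome-length weights (or equal weights), capped by per-chromosome
availability with deficits redistributed; then, within each chromosome, the
candidate span is cut into quota-many equal-width bins and one candidate is
drawn uniformly per bin, with empty bins backfilled from the nearest bins
that still hold unselected candidates. Both allocation modes are provided
because published panels rarely state whether "even" was by length or by
candidate density. The seed is a mandatory part of the specification so a
published panel can be regenerated exactly.

# KASP assay construction

For each panel SNP, 150 bp of flanking sequence per side is extracted
(truncated with a warning at chromosome ends; the SNP sits at position 151
of the 301-bp window when both flanks are full). The allele-specific body
is the last `bodyLength − 1` bases of the left flank followed by the
allele, putting the discriminating base at the 3′ terminus where a
mismatch blocks polymerase extension. F1 = FAM tail + body(allele 1),
F2 = VIC tail + body(allele 2); the first allele listed (the reference
base, plus strand) maps to FAM, deterministically recorded in the sheet.
The common reverse primer is the reverse complement of the window starting
`reverseOffset` bases 3′ of the SNP. Defaults (`bodyLength = 22`,
`reverseOffset = 30`, `reverseLength = 22`) are plain geometric
placeholders: the assays this mirrors were designed with commercial
software whose melting-temperature and secondary-structure optimisation is
deliberately *not* replicated — primer geometry here is configuration, not
thermodynamics.

# Diversity statistics

For a biallelic locus with allele frequencies p, q over non-missing
genotypes of n typed individuals:

* Na = observed allele count; Ne = 1/(p² + q²); I = −(p ln p + q ln q) in
  natural-log units (the GenAlEx convention); Ho = heterozygotes/n;
  He = 1 − (p² + q²) **without** the small-sample 2n/(2n−1) correction —
  this is the convention that reproduces the published survey exactly
  (e.g. He = 2pq = 0.486 at p = 0.583);
* F_IS = (He − Ho)/He (undefined when He = 0);
* MAF follows the survey's usage as the **major** allele frequency, the
  frequency of the most common allele — despite what the acronym usually
  means. The *screening* module's `mafMin`, by contrast, thresholds the
  minor allele, as the VCFtools flag does. Both conventions are kept
  because each matches its source tool;
* PIC per Botstein; HWE p-value by chi-square (report default) or exact
  test.

Reports round at 3 decimals, half away from zero, only at serialization;
all computation is full precision. HWE conformity flags use α = 0.05.
The chi-square and exact tests can disagree near the boundary at n ≈ 30 —
one reconstructed survey locus has chi-square p ≈ 0.02 but a printed
"not significant" flag, consistent with the original analysis having used
a different test — so flag-by-flag agreement with a published table is not
asserted anywhere.

`countsFromSummary()` inverts a published (Ho, MAF, n) row to integer
genotype counts (rounding the heterozygote and minor-allele counts, erroring
when no non-negative configuration exists). `poyangPanel()` ships the
19-locus published survey this package reproduces, with per-locus sample
sizes recovered from the printed Ho values (five loci at n = 29, the rest
at 30); one locus prints a MAF inconsistent with any integer allele count
at its sample size and is excluded from round-trip checks.

# The synthetic-data generator

The generator defines the conditions under which the pipeline is tested:

* **Reference**: i.i.d. bases at a target GC fraction (default 0.41, a
  typical mammalian value); no repeats, no N runs — isolated-SNP screening
  and primer construction do not depend on those features, so passing tests
  say nothing about repeat-induced design failures in real genomes.
* **Cohort VCF**: 12 diploid samples by default (the resequencing design
  this emulates); site count Binomial(L, density) with density 1/2000 by
  default; positions uniform with a minimum spacing of 301 bp so that the
  default output is comfortably inside the isolation-filter pass region and
  proximity violations can be planted without side effects. Annotation
  values are drawn from configurable laws whose defaults sit well inside
  the hard-filter pass region (the thresholds are published; the underlying
  distributions are not, so they are configuration, not science).
  Genotypes are drawn under HWE at each site's simulated frequency
  (default uniform on [0.2, 0.45]) and, by default, redrawn until the
  *realized* cohort frequencies also pass the frequency, HWE and PIC
  filters (`guaranteePass = TRUE`): with only 24 alleles, a site simulated
  near the band edge would otherwise drift outside it often enough that a
  "clean" cohort would not be a true negative set, and the
  planted-violation oracle requires recall *and precision* of exactly 1.0.
  The conditioning slightly distorts the per-site genotype law; disable it
  for unconditioned draws.
* **Planted violations** overwrite clean records so each fails exactly its
  intended criterion: annotations set just past their thresholds;
  a second alternate allele for multi-allelism; an inserted partner within
  100 bp for proximity (each pair removes two records); deterministic
  genotype configurations for the frequency (one heterozygote,
  MAF ≈ 0.042), missingness (one "./."), HWE and PIC criteria. The HWE
  plant uses the full heterozygote-*deficit* configuration (at 12 diploids,
  6/0/6), the only configuration whose exact-test p (≈ 3.4×10⁻⁴) clears
  the 0.001 cutoff — full heterozygote excess only reaches p ≈ 1.9×10⁻³
  and would pass the filter. The PIC plant uses 3 heterozygotes in 12
  (realized minor frequency 0.125: above the 0.05 frequency floor, exact
  HWE p = 1, PIC ≈ 0.169 < 0.2).
* **Genotype matrices**: per-locus multinomial draws from the
  inbreeding-adjusted HWE law p² + fpq, 2pq(1−f), q² + fpq (clipped at
  zero and renormalized, which matters only for strongly negative f),
  independent missingness, all seeded.

# Numerical and design choices

* All boundary comparisons are inclusive, exactly as the filter expressions
  print them.
* The exact HWE p-value includes ties via a relative tolerance of 1e−9
  when comparing configuration probabilities.
* Positions are resolved to strict increase by construction (spaced
  sampling), not by post-hoc de-duplication; an impossible density errors.
* Quota rounding breaks ties toward the first chromosome in name order;
  bin backfilling prefers the nearest donor bin.
* Problem sizes in the test suite: cohorts of 300–500 records on 0.3–1 Mb
  chromosomes, exact-HWE enumeration over all configurations at n ≤ 10,
  and parameter recovery at n = 10,000 individuals with 3-standard-error
  tolerances — sizes at which every oracle is exhaustive or the sampling
  error is well characterised.

# Limitations

* The generator does not simulate reads, mapping error, allele-specific
  dropout or repeat context; validation of primer specificity against a
  real genome (e.g. uniqueness genome-wide rather than within the 301-bp
  window) is out of scope.
* Primer design is geometric only; no Tm, GC-clamp or secondary-structure
  scoring.
* Multi-population statistics (F_ST, AMOVA), kinship and linkage pruning
  are not implemented.
* The discovery-scale counts of the original study (tens of thousands of
  candidates from real resequencing, wet-lab validation rates) depend on
  real accessions and laboratory outcomes and are not reproduced; what the
  package reproduces exactly are the per-locus and panel-mean diversity
  statistics, and the *behaviour* of every filter on data with known
  ground truth.
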