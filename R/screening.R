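#' Evaluate the GATK-style hard filter on every record
#'
#' Applies the inclusive inequalities QD >= qdMin, QUAL >= qualMin,
#' FS <= fsMax, MQ >= mqMin, MQRankSum >= mqRankSumMin and
#' ReadPosRankSum >= readPosRankSumMin. Boundary values pass. An absent
#' annotation (NA) skips that criterion — rank-sum annotations are
#' undefined at sites without both alleles in reads, and such sites should
#' not fail for lack of a value — and is flagged instead.
#'
#' @param vset a \linkS4class{VariantSet}.
#' @param config a \linkS4class{ScreenConfig}.
#' @param stage "initial" (QUAL >= qualMin) or "highconf"
#'   (QUAL >= qualHighConf, the FIRSTOK stage).
#' @return data.frame with columns id, pass, reasons (comma separated names
#'   of violated criteria, "" when passing), missingAnnotations.
#' @examples
#' cfg <- screenConfig()
#' v <- VariantSet(data.frame(chrom = "Chr01", pos = 500, ref = "A",
#'                            alt = "G", qual = 30, qd = 2, fs = 60,
#'                            mq = 40, mqRankSum = -12.5,
#'                            readPosRankSum = -8),
#'                 matrix("0/1", 1, 12))
#' evaluateHardFilter(v, cfg)$pass   # boundaries are inclusive
#' @export
evaluateHardFilter <- function(vset, config = screenConfig(),
                               stage = c("initial", "highconf")) {
  stage <- match.arg(stage)
  v <- vset@variants
  qualMin <- if (stage == "initial") config@qualMin else config@qualHighConf
  crit <- list(
    QD = v$qd < config@qdMin,
    QUAL = v$qual < qualMin,
    FS = v$fs > config@fsMax,
    MQ = v$mq < config@mqMin,
    MQRankSum = v$mqRankSum < config@mqRankSumMin,
    ReadPosRankSum = v$readPosRankSum < config@readPosRankSumMin
  )
  fails <- vapply(crit, function(x) !is.na(x) & x, logical(nrow(v)))
  missing <- vapply(crit, is.na, logical(nrow(v)))
  if (nrow(v) == 1) { fails <- t(fails); missing <- t(missing) }
  reasons <- apply(fails, 1, function(r)
    paste(names(crit)[r], collapse = ","))
  missAnn <- apply(missing, 1, function(r)
    paste(names(crit)[r], collapse = ","))
  data.frame(id = v$id, pass = !apply(fails, 1, any), reasons = reasons,
             missingAnnotations = missAnn, stringsAsFactors = FALSE)
}

#' Tag high-confidence records
#'
#' Adds the "FIRSTOK" tag to every record that passes the high-confidence
#' hard-filter stage (identical to the initial stage but QUAL >= 1000 by
#' default). Records are never removed by this step.
#'
#' @param vset a \linkS4class{VariantSet}.
#' @param config a \linkS4class{ScreenConfig}.
#' @return the \linkS4class{VariantSet} with tags updated.
#' @export
tagHighConfidence <- function(vset, config = screenConfig()) {
  res <- evaluateHardFilter(vset, config, stage = "highconf")
  v <- vset@variants
  add <- res$pass & !grepl("\\bFIRSTOK\\b", v$tags)
  v$tags[add] <- ifelse(nzchar(v$tags[add]),
                        paste(v$tags[add], "FIRSTOK", sep = ";"), "FIRSTOK")
  new("VariantSet", variants = v, geno = vset@geno)
}

#' Test whether records carry a tag
#'
#' @param vset a \linkS4class{VariantSet}.
#' @param tag tag name.
#' @return logical vector over records.
#' @export
hasTag <- function(vset, tag = "FIRSTOK")
  grepl(paste0("\\b", tag, "\\b"), vset@variants$tags)

# per-record flags used by the biallelic + isolation selection
flagBiallelicSnp <- function(vset) {
  v <- vset@variants
  nchar(v$ref) == 1 & !grepl(",", v$alt, fixed = TRUE) & nchar(v$alt) == 1
}

flagIsolated <- function(vset, window = 100) {
  v <- vset@variants
  keep <- rep(TRUE, nrow(v))
  for (ch in unique(v$chrom)) {
    i <- which(v$chrom == ch)
    if (length(i) < 2) next
    p <- sort(v$pos[i])
    o <- order(v$pos[i])
    gapL <- c(Inf, diff(p))
    gapR <- c(diff(p), Inf)
    crowded <- (gapL <= window) | (gapR <= window)
    keep[i[o]] <- !crowded
  }
  keep
}

#' Select isolated biallelic SNPs
#'
#' Keeps records that are single-base biallelic substitutions with no other
#' variant record of any type at distance <= \code{window} bp on the same
#' chromosome (strictly more than \code{window} bp of clearance is
#' required on both sides). Isolation protects the primer-binding context
#' of downstream assays. Records are sorted by (chromosome, position)
#' internally, so the result does not depend on input order.
#'
#' @param vset a \linkS4class{VariantSet}.
#' @param window exclusion distance in bp (default 100).
#' @return the retained \linkS4class{VariantSet}, sorted.
#' @export
selectIsolatedBiallelic <- function(vset, window = 100) {
  ord <- order(vset@variants$chrom, vset@variants$pos)
  vset <- vset[ord]
  vset[flagBiallelicSnp(vset) & flagIsolated(vset, window)]
}

#' Population-genetic prefilter
#'
#' The VCFtools-style locus filter: keeps biallelic records with minor
#' allele frequency >= \code{mafMin} (computed over non-missing genotypes),
#' missing-genotype fraction <= \code{maxMissing}, and an HWE test p-value
#' >= \code{hweAlpha}. Loci with no non-missing genotypes are removed.
#'
#' @param vset a \linkS4class{VariantSet}.
#' @param mafMin minimum minor allele frequency (inclusive), default 0.05.
#' @param maxMissing maximum missing fraction, default 0 (every sample must
#'   be typed, i.e. \code{--max-missing 1}).
#' @param hweAlpha HWE exclusion level, default 0.001.
#' @param hweMethod "exact" (default; matches the behaviour of the
#'   VCFtools \code{--hwe} filter) or "chi2".
#' @param details if TRUE, return a list with the subset and a per-record
#'   decision table instead of just the subset.
#' @return the retained \linkS4class{VariantSet} (or a list, see
#'   \code{details}).
#' @export
popgenPrefilter <- function(vset, mafMin = 0.05, maxMissing = 0,
                            hweAlpha = 0.001,
                            hweMethod = c("exact", "chi2"),
                            details = FALSE) {
  hweMethod <- match.arg(hweMethod)
  v <- vset@variants
  stats <- apply(vset@geno, 1, gtSiteStats)
  dec <- do.call(rbind, lapply(seq_along(stats), function(i) {
    s <- stats[[i]]
    reasons <- character()
    if (s$nTyped == 0) reasons <- "allMissing"
    else {
      missFrac <- s$nMissing / (s$nMissing + s$nTyped)
      if (missFrac > maxMissing) reasons <- c(reasons, "missing")
      if (is.na(s$maf) || s$maf < mafMin) reasons <- c(reasons, "maf")
      if (!s$multi) {
        p <- hweTest(s$homRef, s$het, s$homAlt, method = hweMethod)
        # orientation does not matter: the test is symmetric in alleles
        if (p < hweAlpha) reasons <- c(reasons, "hwe")
      }
    }
    data.frame(id = v$id[i], keep = !length(reasons),
               reasons = paste(reasons, collapse = ","),
               stringsAsFactors = FALSE)
  }))
  kept <- vset[dec$keep]
  if (details) list(vset = kept, decisions = dec) else kept
}

#' PIC band filter on a candidate table
#'
#' Keeps candidates whose cohort polymorphism information content lies in
#' the inclusive band [low, high]. The published pipeline used 0.2-0.5,
#' targeting moderately informative markers while excluding sites so
#' variable they suggest artefacts.
#'
#' @param candidates data.frame with a \code{pic} column (see
#'   \code{\link{screenCandidates}}).
#' @param low,high inclusive PIC bounds.
#' @return the retained rows.
#' @export
picBandFilter <- function(candidates, low = 0.2, high = 0.5)
  candidates[candidates$pic >= low & candidates$pic <= high, , drop = FALSE]

#' Screen a cohort VCF for candidate SNPs
#'
#' Runs the full selection pipeline in the order of the published
#' procedure: (1) GATK-style hard filter; (2) biallelic + 100 bp isolation
#' selection; (3) high-confidence tagging (QUAL >= 1000), with tagged
#' records required for candidacy; (4) population-genetic prefilter
#' (MAF, missingness, HWE); (5) biallelic + isolation re-check among the
#' survivors; (6) PIC band selection. The isolation rule is applied twice
#' as one reusable operation.
#'
#' @param vset a \linkS4class{VariantSet} or path to a cohort VCF.
#' @param config a \linkS4class{ScreenConfig}.
#' @return list with \code{candidates} (data.frame: locus_id, chrom, pos,
#'   ref, alt, maf, pic, flags), \code{counts} (named record counts after
#'   each stage, first entry the input), and \code{removed} (data.frame:
#'   id, stage, reasons).
#' @examples
#' ref <- simulateReference(c(Chr01 = 2e5), seed = 1)
#' vs <- simulateCohortVcf(ref, seed = 7)
#' out <- screenCandidates(vs)
#' out$counts
#' @export
screenCandidates <- function(vset, config = screenConfig()) {
  if (is.character(vset)) vset <- readCohortVcf(vset)
  removed <- list()
  note <- function(ids, stage, reasons) {
    if (length(ids))
      removed[[length(removed) + 1L]] <<- data.frame(
        id = ids, stage = stage, reasons = reasons,
        stringsAsFactors = FALSE)
  }
  counts <- c(input = nVariants(vset))

  hf <- evaluateHardFilter(vset, config, stage = "initial")
  note(hf$id[!hf$pass], "hard_filter", hf$reasons[!hf$pass])
  vset <- vset[hf$pass]
  counts["hard_filter"] <- nVariants(vset)

  ord <- order(vset@variants$chrom, vset@variants$pos)
  vset <- vset[ord]
  bi <- flagBiallelicSnp(vset)
  iso <- flagIsolated(vset, config@isolationWindow)
  drop <- !(bi & iso)
  note(vset@variants$id[drop], "biallelic_isolation",
       ifelse(!bi[drop], "multiallelic_or_not_snp", "proximity"))
  vset <- vset[!drop]
  counts["biallelic_isolation"] <- nVariants(vset)

  vset <- tagHighConfidence(vset, config)
  ok <- hasTag(vset, "FIRSTOK")
  hc <- evaluateHardFilter(vset, config, stage = "highconf")
  note(vset@variants$id[!ok], "high_confidence", hc$reasons[!ok])
  vset <- vset[ok]
  counts["high_confidence"] <- nVariants(vset)

  pf <- popgenPrefilter(vset, config@mafMin, config@maxMissing,
                        config@hweAlpha, config@hweMethod, details = TRUE)
  bad <- !pf$decisions$keep
  note(pf$decisions$id[bad], "popgen_prefilter", pf$decisions$reasons[bad])
  vset <- pf$vset
  counts["popgen_prefilter"] <- nVariants(vset)

  iso2 <- flagIsolated(vset, config@isolationWindow)
  note(vset@variants$id[!iso2], "isolation_recheck", "proximity")
  vset <- vset[iso2]
  counts["isolation_recheck"] <- nVariants(vset)

  v <- vset@variants
  siteStats <- apply(vset@geno, 1, gtSiteStats)
  maf <- vapply(siteStats, `[[`, 0, "maf")
  pic <- vapply(maf, function(q) picValue(c(1 - q, q)), 0)
  cand <- data.frame(
    locus_id = paste(v$chrom, v$pos, sep = "_"),
    chrom = v$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
    maf = maf, pic = pic, flags = v$tags, stringsAsFactors = FALSE)
  keepPic <- cand$pic >= config@picMin & cand$pic <= config@picMax
  note(v$id[!keepPic], "pic_band", "picOut")
  cand <- cand[keepPic, , drop = FALSE]
  rownames(cand) <- NULL
  counts["pic_band"] <- nrow(cand)

  if (!nrow(cand)) warning("no candidate SNPs survived screening")
  removed <- if (length(removed)) do.call(rbind, removed) else
    data.frame(id = character(), stage = character(),
               reasons = character())
  list(candidates = cand, counts = counts, removed = removed)
}

#' Write a candidate table as TSV
#'
#' @param candidates candidate data.frame from
#'   \code{\link{screenCandidates}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCandidateTable <- function(candidates, path) {
  utils::write.table(candidates, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a candidate table
#'
#' @param path TSV path written by \code{\link{writeCandidateTable}}.
#' @return data.frame.
#' @export
readCandidateTable <- function(path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
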