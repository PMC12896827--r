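#' Default annotation laws for simulated cohort VCFs
#'
#' Each law is a function of \code{n} returning \code{n} draws. Defaults sit
#' comfortably inside the hard-filter pass region (QD >= 2, QUAL >= 30 and
#' >= 1000 for the high-confidence stage, FS <= 60, MQ >= 40,
#' MQRankSum >= -12.5, ReadPosRankSum >= -8), so an unmodified simulated
#' cohort passes both hard-filter stages in full.
#'
#' @return named list of draw functions for qual, qd, fs, mq, mqRankSum and
#'   readPosRankSum.
#' @export
defaultAnnotationLaws <- function() {
  list(
    qual = function(n) round(stats::runif(n, 1200, 3000), 2),
    qd = function(n) round(pmin(40, pmax(5, stats::rnorm(n, 25, 5))), 2),
    fs = function(n) round(pmin(50, abs(stats::rnorm(n, 2, 3))), 3),
    mq = function(n) round(pmax(45, pmin(60, stats::rnorm(n, 59, 1))), 2),
    mqRankSum = function(n) round(pmax(-4, pmin(4, stats::rnorm(n))), 3),
    readPosRankSum = function(n) round(pmax(-4, pmin(4, stats::rnorm(n))), 3)
  )
}

# positions with a guaranteed minimum gap: draw from a shrunken range and
# re-expand, so coordinates are strictly increasing with gap > minSpacing
spacedPositions <- function(n, length, minSpacing) {
  if (n == 0) return(integer())
  slack <- length - (n - 1) * minSpacing
  if (slack < n)
    stop("variant density too high: ", n, " sites with spacing ",
         minSpacing, " do not fit in ", length, " bp")
  sort(sample.int(slack, n)) + (seq_len(n) - 1) * minSpacing
}

#' Simulate a joint-genotyped cohort of SNP calls
#'
#' Emulates the output of joint genotyping a resequenced cohort against a
#' reference: biallelic SNPs at random (strictly increasing) positions, with
#' QUAL and the INFO annotations QD, FS, MQ, MQRankSum and ReadPosRankSum
#' drawn from configurable laws, and per-sample genotypes drawn under
#' Hardy-Weinberg equilibrium at each site's simulated allele frequency.
#'
#' @param reference a \link[Biostrings]{DNAStringSet}.
#' @param nSamples cohort size (>= 2); the study design this mirrors used 12
#'   resequenced individuals.
#' @param snpDensity expected variants per bp (default 1/2000).
#' @param mafLaw function of n returning simulated minor allele frequencies;
#'   default uniform on [0.2, 0.45], inside both the frequency and PIC
#'   selection bands.
#' @param annotationLaws list of draw functions, see
#'   \code{\link{defaultAnnotationLaws}}.
#' @param minSpacing minimum distance between simulated sites in bp
#'   (default 301, beyond the 100 bp isolation window).
#' @param guaranteePass if TRUE (default), genotypes at each site are
#'   redrawn until the realized cohort frequencies also satisfy the default
#'   screening thresholds (minor allele frequency >= 0.05, exact HWE
#'   p >= 0.001, PIC within [0.2, 0.5]). In a cohort of 12 the realized
#'   frequency of a site simulated at the edge of the PIC band otherwise
#'   drifts outside it often enough that a "clean" cohort would not be a
#'   true negative set for every filter, which is what the planted-violation
#'   oracle requires. Disable for unconditioned Hardy-Weinberg draws.
#' @param seed integer seed.
#' @return a \linkS4class{VariantSet}.
#' @examples
#' ref <- simulateReference(c(Chr01 = 2e5), seed = 1)
#' vs <- simulateCohortVcf(ref, nSamples = 12, seed = 7)
#' vs
#' @export
simulateCohortVcf <- function(reference, nSamples = 12,
                              snpDensity = 1 / 2000,
                              mafLaw = function(n) stats::runif(n, 0.2, 0.45),
                              annotationLaws = defaultAnnotationLaws(),
                              minSpacing = 301, guaranteePass = TRUE,
                              seed = 1) {
  if (nSamples < 2) stop("nSamples must be >= 2")
  laws <- utils::modifyList(defaultAnnotationLaws(), annotationLaws)
  bases <- c("A", "C", "G", "T")
  withSeed(seed, {
    recs <- lapply(seq_along(reference), function(ci) {
      L <- Biostrings::width(reference)[ci]
      n <- stats::rbinom(1, L, min(1, snpDensity))
      pos <- spacedPositions(n, L, minSpacing)
      if (n == 0) return(NULL)
      chromSeq <- as.character(reference[[ci]])
      ref <- substring(chromSeq, pos, pos)
      alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
      data.frame(chrom = names(reference)[ci], pos = pos,
                 ref = unname(ref), alt = unname(alt),
                 stringsAsFactors = FALSE)
    })
    v <- do.call(rbind, recs)
    if (is.null(v)) stop("no variants simulated; increase snpDensity")
    n <- nrow(v)
    v$id <- paste(v$chrom, v$pos, sep = "_")
    v$qual <- laws$qual(n)
    v$qd <- laws$qd(n)
    v$fs <- laws$fs(n)
    v$mq <- laws$mq(n)
    v$mqRankSum <- laws$mqRankSum(n)
    v$readPosRankSum <- laws$readPosRankSum(n)
    v$tags <- ""
    af <- mafLaw(n)
    cfg <- screenConfig()
    inPassRegion <- function(dos) {
      q <- sum(dos) / (2 * length(dos))
      q <- min(q, 1 - q)
      if (q < cfg@mafMin) return(FALSE)
      pic <- picValue(c(1 - q, q))
      if (pic < cfg@picMin || pic > cfg@picMax) return(FALSE)
      hweTest(sum(dos == 0), sum(dos == 1), sum(dos == 2),
              method = "exact") >= cfg@hweAlpha
    }
    geno <- t(vapply(af, function(q) {
      dos <- stats::rbinom(nSamples, 2, q)
      if (guaranteePass) {
        tries <- 1
        while (!inPassRegion(dos) && tries < 1000) {
          dos <- stats::rbinom(nSamples, 2, q)
          tries <- tries + 1
        }
        if (!inPassRegion(dos))
          stop("could not realize in-band genotypes at frequency ", q,
               "; widen mafLaw or set guaranteePass = FALSE")
      }
      c("0/0", "0/1", "1/1")[dos + 1]
    }, character(nSamples)))
    colnames(geno) <- sprintf("S%02d", seq_len(nSamples))
    VariantSet(v[, c("id", "chrom", "pos", "ref", "alt", "qual", "qd",
                     "fs", "mq", "mqRankSum", "readPosRankSum", "tags")],
               geno)
  })
}

#' Plant known filter violations into a clean variant set
#'
#' Overwrites (or, for proximity, inserts partners next to) clean records so
#' that a known number of records fail each screening criterion, and returns
#' a truth table naming them. This provides an exact oracle for the
#' screening pipeline: recall and precision of every filter can be asserted
#' to be 1.0.
#'
#' Supported criteria (counts of records to plant): \code{qd}, \code{qual},
#' \code{fs}, \code{mq}, \code{mqRankSum}, \code{readPosRankSum}
#' (annotation set just past its threshold), \code{multiallelic} (a second
#' alternate allele is added), \code{proximity} (pairs: a partner variant is
#' inserted within 100 bp, so each planted pair removes two records),
#' \code{lowMaf} (genotypes rewritten to a single heterozygote; note a
#' site this rare is also uninformative, so it would fail the PIC band too
#' — it is removed at the frequency filter, which is the criterion
#' recorded), \code{missing} (one genotype set to "./."), \code{hwe}
#' (full heterozygote deficit, the most extreme exact-test configuration),
#' and \code{picOut} (frequency set so PIC < 0.2 while passing all other
#' filters).
#'
#' @param vset a clean \linkS4class{VariantSet} (e.g. from
#'   \code{\link{simulateCohortVcf}}).
#' @param spec named list/vector of non-negative counts per criterion.
#' @param seed integer seed for choosing which records to modify.
#' @return list with elements \code{variants} (the modified
#'   \linkS4class{VariantSet}) and \code{truth} (data.frame id, criterion).
#' @examples
#' ref <- simulateReference(c(Chr01 = 2e5), seed = 1)
#' vs <- simulateCohortVcf(ref, seed = 7)
#' pl <- plantViolations(vs, list(qd = 3, proximity = 2), seed = 11)
#' pl$truth
#' @export
plantViolations <- function(vset, spec = list(), seed = 1) {
  spec <- as.list(spec)
  known <- c("qd", "qual", "fs", "mq", "mqRankSum", "readPosRankSum",
             "multiallelic", "proximity", "lowMaf", "missing", "hwe",
             "picOut")
  bad <- setdiff(names(spec), known)
  if (length(bad)) stop("unknown criteria: ", paste(bad, collapse = ", "))
  counts <- vapply(known, function(k) as.integer(spec[[k]] %||% 0L), 0L)
  nTargets <- sum(counts)
  if (nTargets == 0)
    return(list(variants = vset, truth = data.frame(
      id = character(), criterion = character())))
  v <- vset@variants
  geno <- vset@geno
  ns <- ncol(geno)
  if (nTargets > nrow(v))
    stop("requested ", nTargets, " planted records but only ", nrow(v),
         " are available")
  truth <- list()
  withSeed(seed, {
    targets <- sample.int(nrow(v), nTargets)
    idx <- split(targets, rep(known, counts))
    setGeno <- function(i, calls) geno[i, ] <<- calls

    for (i in idx$qd) v$qd[i] <- 1.0
    for (i in idx$qual) v$qual[i] <- 25.0
    for (i in idx$fs) v$fs[i] <- 80.0
    for (i in idx$mq) v$mq[i] <- 30.0
    for (i in idx$mqRankSum) v$mqRankSum[i] <- -20.0
    for (i in idx$readPosRankSum) v$readPosRankSum[i] <- -10.0
    for (k in c("qd", "qual", "fs", "mq", "mqRankSum", "readPosRankSum"))
      for (i in idx[[k]])
        truth[[length(truth) + 1L]] <- c(v$id[i], k)

    bases <- c("A", "C", "G", "T")
    for (i in idx$multiallelic) {
      alt2 <- setdiff(bases, c(v$ref[i], v$alt[i]))[1]
      v$alt[i] <- paste(v$alt[i], alt2, sep = ",")
      g <- geno[i, ]
      g[match("0/1", g, nomatch = 1)] <- "1/2"
      setGeno(i, g)
      truth[[length(truth) + 1L]] <- c(v$id[i], "multiallelic")
    }

    if (ns >= 12) {
      lowMafCalls <- c("0/1", rep("0/0", ns - 1))
      hweCalls <- c(rep("0/0", ceiling(ns / 2)), rep("1/1", floor(ns / 2)))
      picCalls <- c(rep("0/1", 3), rep("0/0", ns - 3))
      missCalls <- c("./.", rep("0/0", 4), rep("0/1", 4),
                     rep("1/1", ns - 9))
    } else {
      lowMafCalls <- c("0/1", rep("0/0", ns - 1))
      hweCalls <- c(rep("0/0", ceiling(ns / 2)), rep("1/1", floor(ns / 2)))
      picCalls <- c("0/1", rep("0/0", ns - 1))
      missCalls <- c("./.", rep("0/1", ns - 1))
    }
    for (i in idx$lowMaf) { setGeno(i, lowMafCalls)
      truth[[length(truth) + 1L]] <- c(v$id[i], "lowMaf") }
    for (i in idx$hwe) { setGeno(i, hweCalls)
      truth[[length(truth) + 1L]] <- c(v$id[i], "hwe") }
    for (i in idx$picOut) { setGeno(i, picCalls)
      truth[[length(truth) + 1L]] <- c(v$id[i], "picOut") }
    for (i in idx$missing) { setGeno(i, missCalls)
      truth[[length(truth) + 1L]] <- c(v$id[i], "missing") }

    # proximity partners: new records within the isolation window of the
    # target but > 100 bp from everything else
    newRows <- list(); newGeno <- list()
    for (i in idx$proximity) {
      sameChrom <- v$pos[v$chrom == v$chrom[i]]
      above <- sameChrom[sameChrom > v$pos[i]]
      gap <- if (length(above)) min(above) - v$pos[i] else Inf
      dmax <- min(100, gap - 101)
      if (dmax < 1)
        stop("cannot plant a proximity partner near ", v$id[i],
             ": neighbouring variant too close")
      d <- sample.int(dmax, 1)
      partner <- v[i, , drop = FALSE]
      partner$pos <- v$pos[i] + d
      partner$id <- paste(partner$chrom, partner$pos, sep = "_")
      newRows[[length(newRows) + 1L]] <- partner
      newGeno[[length(newGeno) + 1L]] <- geno[i, ]
      truth[[length(truth) + 1L]] <- c(v$id[i], "proximity")
      truth[[length(truth) + 1L]] <- c(partner$id, "proximity")
    }
    if (length(newRows)) {
      v <- rbind(v, do.call(rbind, newRows))
      geno <- rbind(geno, do.call(rbind, newGeno))
    }
  })
  ord <- order(v$chrom, v$pos)
  v <- v[ord, , drop = FALSE]; rownames(v) <- NULL
  geno <- geno[ord, , drop = FALSE]
  truth <- do.call(rbind, lapply(truth, function(x)
    data.frame(id = x[1], criterion = x[2])))
  list(variants = new("VariantSet", variants = v, geno = geno),
       truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a VariantSet as a minimal VCF v4.2 file
#'
#' Emits an unphased ("/" separator) VCF with contig lines taken from
#' \code{reference} (or from the records), INFO definitions for QD, FS, MQ,
#' MQRankSum and ReadPosRankSum, and a GT-only FORMAT. Filter tags (e.g.
#' FIRSTOK) go to the FILTER column.
#'
#' @param vset a \linkS4class{VariantSet}.
#' @param path output path (".gz" suffix gzips).
#' @param reference optional \link[Biostrings]{DNAStringSet} for contig
#'   header lines with lengths.
#' @return \code{path}, invisibly.
#' @export
writeCohortVcf <- function(vset, path, reference = NULL) {
  v <- vset@variants
  contigs <- if (!is.null(reference)) {
    sprintf("##contig=<ID=%s,length=%d>", names(reference),
            Biostrings::width(reference))
  } else sprintf("##contig=<ID=%s>", unique(v$chrom))
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=kaspanel-synthetic-cohort",
    contigs,
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Phred strand bias\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"RMS mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"Mapping quality rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", colnames(vset@geno)), collapse = "\t")
  )
  fmtNum <- function(x) ifelse(is.na(x), NA, format(x, trim = TRUE,
                                                    scientific = FALSE))
  info <- apply(cbind(QD = v$qd, FS = v$fs, MQ = v$mq,
                      MQRankSum = v$mqRankSum,
                      ReadPosRankSum = v$readPosRankSum), 1, function(r) {
    keep <- !is.na(r)
    if (!any(keep)) return(".")
    paste(paste0(names(r)[keep], "=", fmtNum(r[keep])), collapse = ";")
  })
  filt <- ifelse(nzchar(v$tags), v$tags, ".")
  body <- paste(v$chrom, v$pos, v$id, v$ref, v$alt, fmtNum(v$qual), filt,
                info, "GT",
                apply(vset@geno, 1, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(hdr, body), con)
  invisible(path)
}

#' Read a cohort VCF into a VariantSet
#'
#' Parses a (possibly bgzipped) multi-sample VCF and extracts position,
#' alleles, QUAL, FILTER tags, the hard-filter INFO annotations and the GT
#' field of every sample.
#'
#' @param path VCF path.
#' @return a \linkS4class{VariantSet}.
#' @export
readCohortVcf <- function(path) {
  x <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(x@fix, stringsAsFactors = FALSE)
  getInfo <- function(key) suppressWarnings(
    as.numeric(vcfR::extract.info(x, element = key)))
  gt <- vcfR::extract.gt(x, element = "GT")
  gt[is.na(gt)] <- "./."
  tags <- ifelse(is.na(fix$FILTER) | fix$FILTER %in% c(".", "PASS"),
                 "", fix$FILTER)
  v <- data.frame(
    id = ifelse(is.na(fix$ID) | fix$ID == ".",
                paste(fix$CHROM, fix$POS, sep = "_"), fix$ID),
    chrom = fix$CHROM, pos = as.integer(fix$POS),
    ref = fix$REF, alt = fix$ALT,
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    qd = getInfo("QD"), fs = getInfo("FS"), mq = getInfo("MQ"),
    mqRankSum = getInfo("MQRankSum"),
    readPosRankSum = getInfo("ReadPosRankSum"),
    tags = tags, stringsAsFactors = FALSE)
  rownames(gt) <- NULL
  new("VariantSet", variants = v, geno = gt)
}

#' Write a planted-violation truth table as JSON
#'
#' @param truth data.frame (id, criterion) from
#'   \code{\link{plantViolations}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeTruthTable <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", pretty = TRUE)
  invisible(path)
}
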